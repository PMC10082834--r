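# Internal array utilities shared by the phantom generator and the
# segmentation engine. All volumes use axis order (z, y, x), 1-based voxel
# indices, voxel-center physical coordinates in mm.

# Normalized 1D Gaussian kernel sampled at integer voxel offsets.
.gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# Dense n x n 1D convolution operator with symmetric (reflect) boundary
# padding. Reflection keeps a constant background exactly constant, so the
# total image mass is conserved for lesions kept away from the grid edge.
.conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq.int(-r, r)) {
      idx <- i + j
      while (idx < 1L || idx > n) {
        if (idx < 1L) idx <- 2L - idx
        if (idx > n) idx <- 2L * n - idx
      }
      A[i, idx] <- A[i, idx] + kernel[j + r + 1L]
    }
  }
  A
}

# Separable isotropic Gaussian blur of a 3D array; sigma in mm, per-axis
# voxel spacing in mm. Each axis pass is a dense matrix product, which is
# fast for grid sizes in the hundreds.
.blur3d <- function(vol, sigma_mm, spacing) {
  if (sigma_mm <= 0) return(vol)
  d <- dim(vol)
  for (ax in 1:3) {
    k <- .gauss_kernel(sigma_mm / spacing[ax])
    if (length(k) == 1L) next
    A <- .conv_matrix(d[ax], k)
    perm <- c(ax, setdiff(1:3, ax))
    v <- if (ax == 1L) vol else aperm(vol, perm)
    dd <- dim(v)
    v <- A %*% matrix(v, dd[1])
    dim(v) <- dd
    vol <- if (ax == 1L) v else aperm(v, order(perm))
  }
  vol
}

# One 6-connected binary dilation step realized as three axis passes
# (equivalent to dilation by a 3x3x3 box when the three passes compose).
.dilate_box1 <- function(m) {
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    x <- aperm(m, perm)
    dd <- dim(x)
    x2 <- x
    x2[-1, , ] <- x2[-1, , ] | x[-dd[1], , ]
    x2[-dd[1], , ] <- x2[-dd[1], , ] | x[-1, , ]
    m <- aperm(x2, order(perm))
  }
  m
}

.dilate_box <- function(m, steps) {
  for (i in seq_len(steps)) m <- .dilate_box1(m)
  m
}

# Sum of the 3x3x3 neighborhood (including center) at every voxel,
# separable accumulation along the three axes.
.boxsum27 <- function(m) {
  v <- m * 1
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    x <- aperm(v, perm)
    dd <- dim(x)
    x2 <- x
    x2[-1, , ] <- x2[-1, , ] + x[-dd[1], , ]
    x2[-dd[1], , ] <- x2[-dd[1], , ] + x[-1, , ]
    v <- aperm(x2, order(perm))
  }
  v
}

# 26-connected component of `mask` containing voxel `seed` (length-3 index).
# Iterated box dilation restricted to the mask; deterministic.
.component26 <- function(mask, seed) {
  stopifnot(length(seed) == 3L)
  cur <- array(FALSE, dim(mask))
  if (!mask[seed[1], seed[2], seed[3]]) return(cur)
  cur[seed[1], seed[2], seed[3]] <- TRUE
  repeat {
    grown <- .dilate_box1(cur) & mask
    if (identical(grown, cur)) return(cur)
    cur <- grown
  }
}

# Number of 26-connected components of a 3D logical array.
.count_components26 <- function(mask) {
  n <- 0L
  rem <- mask
  while (any(rem)) {
    seed <- which(rem, arr.ind = TRUE)[1, ]
    rem <- rem & !.component26(rem, seed)
    n <- n + 1L
  }
  n
}

# 4-connected component of a 2D logical mask containing `seed` (length-2).
.component4_2d <- function(mask, seed) {
  cur <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!mask[seed[1], seed[2]]) return(cur)
  cur[seed[1], seed[2]] <- TRUE
  repeat {
    g <- cur
    g[-1, ] <- g[-1, ] | cur[-nrow(cur), ]
    g[-nrow(cur), ] <- g[-nrow(cur), ] | cur[-1, ]
    g[, -1] <- g[, -1] | cur[, -ncol(cur)]
    g[, -ncol(cur)] <- g[, -ncol(cur)] | cur[, -1]
    g <- g & mask
    if (identical(g, cur)) return(cur)
    cur <- g
  }
}

# Radial profile of a unit-amplitude sphere of radius R (mm) convolved with
# an isotropic Gaussian of standard deviation s (mm), evaluated at radius r.
# Closed form; s = 0 degenerates to the crisp indicator.
.blurred_sphere_profile <- function(r, R, s) {
  if (s <= 0) return(as.numeric(r <= R))
  if (r < 1e-8) {
    return(2 * stats::pnorm(R / s) - 1 -
             sqrt(2 / pi) * (R / s) * exp(-R^2 / (2 * s^2)))
  }
  stats::pnorm((R - r) / s) - stats::pnorm(-(R + r) / s) +
    (s / (r * sqrt(2 * pi))) *
      (exp(-(R + r)^2 / (2 * s^2)) - exp(-(R - r)^2 / (2 * s^2)))
}

# Factory for forward-model calibration of the active surface: returns a
# memoized function of candidate radius R that voxelizes a unit-amplitude
# sphere on the given grid spacing at the given sub-voxel offset, blurs it
# with the same discrete Gaussian kernel as the assumed scanner PSF, and
# summarizes it with the same statistics used on the measured image:
#   cum     - normalized cumulative radial mass of the box-smoothed
#             calibration, sampled at `n_q` radii up to the cut radius,
#   m_cut   - its total smoothed mass within the cut ball (voxel units),
#   thr_mid - the intensity midpoint between the k-th and (k+1)-th largest
#             blurred value, k being the sphere's own voxel count: the
#             threshold that recovers exactly the true voxelization.
.sphere_calibration <- function(r_cut, sigma, sp, off_frac, n_q = 40L) {
  cache <- new.env(parent = emptyenv())
  Rg <- r_cut + 4 * sigma + max(sp)
  n <- 2L * as.integer(ceiling(Rg / sp)) + 3L
  c0 <- (n + 1L) %/% 2L
  center <- (c0 - 1 + off_frac) * sp
  co <- lapply(1:3, function(i) (seq_len(n[i]) - 1) * sp[i] - center[i])
  r2 <- outer(outer(co[[1]]^2, co[[2]]^2, "+"), co[[3]]^2, "+")
  sel <- r2 <= r_cut^2
  denom <- .boxsum27(array(1, n))
  rs <- sqrt(r2[sel])
  o <- order(rs)
  rso <- rs[o]
  q_radii <- seq(r_cut / n_q, r_cut, length.out = n_q)
  function(R) {
    key <- sprintf("%.6f", R)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    crisp <- (r2 <= R^2) * 1
    k <- sum(crisp)
    out <- if (k == 0) {
      list(cum = numeric(n_q), m_cut = .Machine$double.eps, thr_mid = 1,
           k = 0L)
    } else {
      cal <- .blur3d(crisp, sigma, sp)
      smc <- .boxsum27(cal) / denom
      cw <- cumsum(smc[sel][o])
      Mc <- cw[length(cw)]
      cum <- c(0, cw)[findInterval(q_radii, rso) + 1L] / Mc
      sv <- sort(cal, decreasing = TRUE)
      thr_mid <- if (k < length(sv)) (sv[k] + sv[k + 1]) / 2 else sv[k]
      list(cum = cum, m_cut = Mc, thr_mid = thr_mid, k = k)
    }
    cache[[key]] <- out
    out
  }
}

# Voxel indices (arr.ind) of the maximum of a 3D array, ties broken toward
# the lowest (z, y, x) in lexicographic order.
.argmax_lex <- function(vol) {
  mx <- max(vol)
  cand <- which(vol == mx, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2], cand[, 3]), , drop = FALSE]
  as.integer(cand[1, ])
}

# Deterministic fingerprint of an arbitrary R object: md5 of a canonical
# text serialization (no R-version header, stable across sessions).
.fingerprint <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x, control = "exact"), collapse = "\n"), f)
  unname(tools::md5sum(f))
}
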