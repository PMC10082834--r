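#' @title Lesion admissibility checks
#' @name lesion_qc
#' @description
#' Two admissibility checks gate the partial-volume correction: the lesion
#' must be close to spherical (the relative difference between its largest
#' and smallest principal diameter below 50 percent) and its uptake must be
#' uniform (a single peak in the in-lesion SUV histogram). Recovery
#' coefficients are tabulated for uniform spheres, so they are only applied
#' to lesions that resemble one.
NULL

#' Principal diameters of a lesion
#'
#' The lesion's voxel-center coordinate cloud (mm) is decomposed along the
#' eigenvectors of its coordinate covariance; the extent along each
#' principal axis is the peak-to-peak projection plus the projection width
#' of one voxel onto that axis (so a single voxel has extent one voxel
#' edge). Principal-axis extents are rotation-tolerant, unlike axis-aligned
#' bounding boxes.
#'
#' @param mask a non-empty [lesion_mask()].
#' @return Named numeric `c(d_max = , d_min = )` in mm.
#' @export
principal_diameters <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  idx <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty")
  xyz <- sweep(idx - 1, 2, mask$spacing, "*")
  if (nrow(idx) == 1) {
    edge <- mean(mask$spacing)
    return(c(d_max = edge, d_min = edge))
  }
  cc <- stats::cov(xyz)
  ev <- eigen(cc, symmetric = TRUE)$vectors
  ext <- numeric(3)
  for (i in 1:3) {
    proj <- xyz %*% ev[, i]
    # one-voxel width projected onto this axis
    ext[i] <- diff(range(proj)) + sum(abs(ev[, i]) * mask$spacing)
  }
  c(d_max = max(ext), d_min = min(ext))
}

#' Sphericity percentage
#'
#' `100 * (d_max - d_min) / d_max`: 0 for a perfect sphere, approaching 100
#' for a needle. The gate is strict: a lesion passes only when the
#' percentage is below 50; exactly 50 fails.
#'
#' @param mask a [lesion_mask()]; ignored when `diameters` is given.
#' @param diameters optional numeric `c(d_max, d_min)` to evaluate the rule
#'   on externally measured diameters.
#' @return A list with `sphericity_pct` and logical `is_spherical`.
#' @export
sphericity_check <- function(mask = NULL, diameters = NULL) {
  if (is.null(diameters)) diameters <- principal_diameters(mask)
  d_max <- max(diameters)
  d_min <- min(diameters)
  if (d_min <= 0 || d_max <= 0) stop("diameters must be positive")
  pct <- 100 * (d_max - d_min) / d_max
  list(sphericity_pct = pct, is_spherical = pct < 50)
}

# Peaks of a 1D histogram with a prominence floor. The count vector is
# conceptually padded with zero bins at both ends, so boundary modes count.
# A peak is a maximal plateau strictly above its neighbors; its prominence
# is its height minus the higher of the two bases, where each base is the
# minimum count between the plateau and the nearest strictly higher bin (or
# the zero pad if none).
.histogram_peaks <- function(h, min_prominence) {
  n <- length(h)
  hp <- c(0, h, 0)
  peaks <- integer(0)
  i <- 2L
  while (i <= n + 1L) {
    j <- i
    while (j < n + 1L && hp[j + 1L] == hp[i]) j <- j + 1L
    if (hp[i] > 0 && hp[i - 1L] < hp[i] && hp[j + 1L] < hp[i]) {
      # prominence of the plateau [i, j]
      lmin <- hp[i]
      k <- i - 1L
      while (k >= 1L && hp[k] < hp[i]) { lmin <- min(lmin, hp[k]); k <- k - 1L }
      rmin <- hp[j]
      k <- j + 1L
      while (k <= n + 2L && hp[k] < hp[i]) { rmin <- min(rmin, hp[k]); k <- k + 1L }
      if (hp[i] - max(lmin, rmin) >= min_prominence)
        peaks <- c(peaks, i - 1L)
    }
    i <- j + 1L
  }
  peaks
}

# Local maxima of a density curve above a height floor, then iterative
# merging of adjacent modes whose connecting valley stays above
# `valley_frac` of the lower mode: separated uptake populations show a deep
# interior valley, while the flat or U-shaped continuum of a blurred
# uniform lesion does not.
.density_modes <- function(y, height_floor_frac, valley_frac) {
  n <- length(y)
  ypad <- c(-Inf, y, -Inf)
  peaks <- integer(0)
  i <- 2L
  while (i <= n + 1L) {
    j <- i
    while (j < n + 1L && ypad[j + 1L] == ypad[i]) j <- j + 1L
    if (ypad[i - 1L] < ypad[i] && ypad[j + 1L] < ypad[i])
      peaks <- c(peaks, i - 1L)
    i <- j + 1L
  }
  peaks <- peaks[y[peaks] >= height_floor_frac * max(y)]
  while (length(peaks) > 1) {
    merged <- FALSE
    for (k in seq_len(length(peaks) - 1L)) {
      valley <- min(y[peaks[k]:peaks[k + 1L]])
      lower <- min(y[peaks[k]], y[peaks[k + 1L]])
      if (valley >= valley_frac * lower) {
        drop <- if (y[peaks[k]] >= y[peaks[k + 1L]]) k + 1L else k
        peaks <- peaks[-drop]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  peaks
}

#' Uptake uniformity check
#'
#' Counts the distinct uptake populations within the lesion and calls the
#' lesion uniform when exactly one exists; a constant-valued lesion counts
#' as one. The verdict is invariant under affine rescaling of the SUVs.
#'
#' The default `"density"` method counts modes of a kernel density estimate
#' of the in-mask SUVs, keeping modes of height at least
#' `min_prominence_frac` of the tallest and merging adjacent modes unless
#' the valley between them falls below half the lower mode. Merging is what
#' makes the check behave like a reader's qualitative judgement: resolution
#' blur smears a uniform lesion into a broad, flat, even U-shaped intensity
#' continuum that a literal bin-level peak count would call multimodal,
#' whereas genuinely heterogeneous uptake (necrotic core, two-compartment
#' lesion) shows a deep interior valley between populations.
#'
#' The `"histogram"` method is the literal operationalization: `n_bins`
#' equal-width bins over the in-mask range, counting local maxima with
#' prominence at least `min_prominence_frac` of the tallest bin. It is
#' appropriate for crisp (unblurred) data.
#'
#' @param img an [suv_image()].
#' @param mask a non-empty [lesion_mask()] on the same grid.
#' @param n_bins number of histogram bins (`"histogram"` method).
#' @param min_prominence_frac prominence/height floor as a fraction of the
#'   tallest bin or mode.
#' @param method `"density"` (default) or `"histogram"`.
#' @return A list with integer `peak_count` and logical `is_uniform`.
#' @export
uniformity_check <- function(img, mask, n_bins = 16,
                             min_prominence_frac = 0.10,
                             method = c("density", "histogram")) {
  method <- match.arg(method)
  stopifnot(inherits(img, "suv_image"), inherits(mask, "lesion_mask"))
  if (!identical(dim(img$voxels), dim(mask$voxels)))
    stop("image and mask grids differ")
  v <- img$voxels[mask$voxels]
  if (length(v) == 0) stop("mask is empty")
  rng <- range(v)
  if (diff(rng) == 0)
    return(list(peak_count = 1L, is_uniform = TRUE))
  if (method == "density") {
    den <- stats::density(v, n = 512)
    pk <- .density_modes(den$y, min_prominence_frac, valley_frac = 0.5)
  } else {
    br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    h <- tabulate(pmin(findInterval(v, br, rightmost.closed = TRUE), n_bins),
                  nbins = n_bins)
    pk <- .histogram_peaks(h, min_prominence_frac * max(h))
  }
  list(peak_count = length(pk), is_uniform = length(pk) == 1L)
}

#' Assemble the lesion QC report
#'
#' Runs the sphericity and uniformity checks; the lesion is eligible for
#' partial-volume correction only when both pass.
#'
#' @param img an [suv_image()].
#' @param mask a [lesion_mask()].
#' @param n_bins,min_prominence_frac forwarded to [uniformity_check()].
#' @return A list of class `lesion_qc_report` with fields `d_max`, `d_min`,
#'   `sphericity_pct`, `is_spherical`, `peak_count`, `is_uniform`,
#'   `pve_eligible`.
#' @export
qc_report <- function(img, mask, n_bins = 16, min_prominence_frac = 0.10) {
  dd <- principal_diameters(mask)
  sph <- sphericity_check(diameters = dd)
  uni <- uniformity_check(img, mask, n_bins, min_prominence_frac)
  structure(list(d_max = unname(dd["d_max"]), d_min = unname(dd["d_min"]),
                 sphericity_pct = sph$sphericity_pct,
                 is_spherical = sph$is_spherical,
                 peak_count = uni$peak_count, is_uniform = uni$is_uniform,
                 pve_eligible = sph$is_spherical && uni$is_uniform),
            class = "lesion_qc_report")
}

#' @export
print.lesion_qc_report <- function(x, ...) {
  cat("<lesion_qc_report>\n",
      sprintf("  diameters: %.2f / %.2f mm, sphericity %.1f%% -> %s\n",
              x$d_max, x$d_min, x$sphericity_pct,
              if (x$is_spherical) "spherical" else "NOT spherical"),
      sprintf("  histogram peaks: %d -> %s\n", x$peak_count,
              if (x$is_uniform) "uniform" else "NOT uniform"),
      sprintf("  PVE-correction eligible: %s\n", x$pve_eligible), sep = "")
  invisible(x)
}
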