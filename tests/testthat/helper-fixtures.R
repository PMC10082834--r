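# Shared fixtures: all synthetic, built in code at test time.

# Small SUV image with given voxel array (z, y, x), 0.5 mm isotropic.
suv_from_array <- function(a, spacing = c(0.5, 0.5, 0.5)) {
  suv_image(a, spacing = spacing)
}

# Voxelized sphere mask on an n^3 grid (center/radius in mm).
sphere_mask <- function(n = 48, spacing = c(0.5, 0.5, 0.5),
                        center = (n - 1) * spacing / 2, radius = 4) {
  dz2 <- ((seq_len(n) - 1) * spacing[1] - center[1])^2
  dy2 <- ((seq_len(n) - 1) * spacing[2] - center[2])^2
  dx2 <- ((seq_len(n) - 1) * spacing[3] - center[3])^2
  m <- outer(outer(dz2, dy2, "+"), dx2, "+") <= radius^2
  lesion_mask(m, spacing = spacing)
}

# Axis-aligned ellipsoid mask (semi-axes mm, order z/y/x).
ellipsoid_mask <- function(n = 64, spacing = c(0.5, 0.5, 0.5),
                           center = (n - 1) * spacing / 2,
                           semi = c(6, 3, 3)) {
  dz2 <- (((seq_len(n) - 1) * spacing[1] - center[1]) / semi[1])^2
  dy2 <- (((seq_len(n) - 1) * spacing[2] - center[2]) / semi[2])^2
  dx2 <- (((seq_len(n) - 1) * spacing[3] - center[3]) / semi[3])^2
  m <- outer(outer(dz2, dy2, "+"), dx2, "+") <= 1
  lesion_mask(m, spacing = spacing)
}

# Ellipsoid mask rotated by `theta` about the x axis (voxel-center test in
# rotated coordinates; used for rotation-invariance checks).
rotated_ellipsoid_mask <- function(n = 64, spacing = c(0.5, 0.5, 0.5),
                                   center = (n - 1) * spacing / 2,
                                   semi = c(6, 3, 3), theta = pi / 6) {
  zc <- (seq_len(n) - 1) * spacing[1] - center[1]
  yc <- (seq_len(n) - 1) * spacing[2] - center[2]
  xc <- (seq_len(n) - 1) * spacing[3] - center[3]
  g <- expand.grid(z = zc, y = yc, x = xc)
  zr <- cos(theta) * g$z - sin(theta) * g$y
  yr <- sin(theta) * g$z + cos(theta) * g$y
  inside <- (zr / semi[1])^2 + (yr / semi[2])^2 + (g$x / semi[3])^2 <= 1
  lesion_mask(array(inside, c(n, n, n)), spacing = spacing)
}

# Default small phantom spec used across segmentation tests.
small_spec <- function(radius = 2.5, suv = 2, n = 64, seed = 1L, ...) {
  phantom_spec(shape = c(n, n, n),
               lesions = list(list(center_mm = c(16, 16, 16),
                                   radius_mm = radius, suv = suv)),
               seed = seed, ...)
}

small_bbox <- function() bbox3d(c(10, 55), c(10, 55), c(10, 55))
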