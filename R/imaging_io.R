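#' @title Volumetric containers and SUV conversion
#' @name imaging_io
#' @description
#' Containers for reconstructed PET activity volumes and their standardized
#' uptake value (SUV) counterparts, NIfTI input/output, and the SUV
#' conversion itself. All volumes use axis order (z, y, x), 1-based voxel
#' indices and voxel-center physical coordinates; spacing and origin are in
#' millimetres.
NULL

#' Physical half-life of fluorine-18 in minutes
#'
#' Used for optional decay correction of the injected activity between
#' injection and scan start.
#' @export
F18_HALF_LIFE_MIN <- 109.77

#' Construct an activity volume
#'
#' A 3D grid of activity concentration in Bq/mL with voxel geometry.
#'
#' @param voxels 3D numeric array, axis order (z, y, x); all values must be
#'   finite and non-negative (Bq/mL).
#' @param spacing numeric length-3, per-axis voxel edge length in mm
#'   (z, y, x); all components positive. Anisotropy is allowed.
#' @param origin numeric length-3, physical position (mm) of the center of
#'   voxel (1, 1, 1).
#' @return An object of class `activity_volume`.
#' @examples
#' av <- activity_volume(array(1000, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
#' @export
activity_volume <- function(voxels, spacing = c(0.5, 0.5, 0.5),
                            origin = c(0, 0, 0)) {
  .check_grid(voxels, spacing, origin)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "activity_volume")
}

#' Acquisition metadata for SUV conversion
#'
#' @param injected_activity_bq injected activity in Bq (> 0).
#' @param body_weight_g animal body weight in g (> 0).
#' @param injection_time,scan_time optional `POSIXct` timestamps; required
#'   only when decay correction is requested. `scan_time` must not precede
#'   `injection_time`.
#' @param half_life_min radionuclide half-life in minutes; defaults to
#'   fluorine-18 ([F18_HALF_LIFE_MIN]).
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(injected_activity_bq, body_weight_g,
                             injection_time = NULL, scan_time = NULL,
                             half_life_min = F18_HALF_LIFE_MIN) {
  if (!is.numeric(injected_activity_bq) || length(injected_activity_bq) != 1 ||
      !is.finite(injected_activity_bq) || injected_activity_bq <= 0)
    stop("injected_activity_bq must be a single positive number (Bq)")
  if (!is.numeric(body_weight_g) || length(body_weight_g) != 1 ||
      !is.finite(body_weight_g) || body_weight_g <= 0)
    stop("body_weight_g must be a single positive number (g)")
  if (!is.null(injection_time) && !is.null(scan_time) &&
      as.numeric(scan_time) < as.numeric(injection_time))
    stop("scan_time must not precede injection_time")
  if (!is.numeric(half_life_min) || half_life_min <= 0)
    stop("half_life_min must be positive")
  structure(list(injected_activity_bq = injected_activity_bq,
                 body_weight_g = body_weight_g,
                 injection_time = injection_time, scan_time = scan_time,
                 half_life_min = half_life_min),
            class = "acquisition_meta")
}

#' Construct an SUV image
#'
#' Normally produced by [to_suv()] or [make_phantom()]; the constructor is
#' exported so synthetic images can be assembled directly.
#'
#' @param voxels 3D numeric array of SUV (dimensionless, conventional g/mL
#'   scale), axis order (z, y, x); finite and non-negative.
#' @param spacing,origin voxel geometry as in [activity_volume()].
#' @param meta an [acquisition_meta()] object, or `NULL`.
#' @return An object of class `suv_image`.
#' @export
suv_image <- function(voxels, spacing = c(0.5, 0.5, 0.5), origin = c(0, 0, 0),
                      meta = NULL) {
  .check_grid(voxels, spacing, origin)
  if (!is.null(meta) && !inherits(meta, "acquisition_meta"))
    stop("meta must be an acquisition_meta object or NULL")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), meta = meta),
            class = "suv_image")
}

#' Construct a lesion mask
#'
#' A binary 3D volume aligned to its source image, marking the metabolic
#' tumor volume.
#'
#' @param voxels 3D logical array, axis order (z, y, x).
#' @param spacing,origin geometry copied from the source image (mm).
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(voxels, spacing = c(0.5, 0.5, 0.5),
                        origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("voxels must be a 3D array")
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("mask may not contain NA")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing components must be positive")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "lesion_mask")
}

.check_grid <- function(voxels, spacing, origin) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("voxels must be a 3D array with axis order (z, y, x)")
  if (any(dim(voxels) < 1)) stop("grid must have at least 1 voxel per axis")
  if (!is.numeric(spacing) || length(spacing) != 3 ||
      any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing components must be positive and finite")
  if (!is.numeric(origin) || length(origin) != 3 || any(!is.finite(origin)))
    stop("origin must be a finite length-3 numeric")
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("all voxel values must be finite")
  if (any(voxels < 0))
    stop("all voxel values must be non-negative")
  invisible(TRUE)
}

#' @export
print.activity_volume <- function(x, ...) {
  cat("<activity_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels (z,y,x), spacing ", paste(x$spacing, collapse = "/"),
      " mm, range [", signif(min(x$voxels), 4), ", ",
      signif(max(x$voxels), 4), "] Bq/mL\n", sep = "")
  invisible(x)
}

#' @export
print.suv_image <- function(x, ...) {
  cat("<suv_image> ", paste(dim(x$voxels), collapse = " x "),
      " voxels (z,y,x), spacing ", paste(x$spacing, collapse = "/"),
      " mm, SUV range [", signif(min(x$voxels), 4), ", ",
      signif(max(x$voxels), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("<lesion_mask> ", paste(dim(x$voxels), collapse = " x "),
      " voxels (z,y,x), ", sum(x$voxels), " in mask (",
      signif(sum(x$voxels) * prod(x$spacing), 5), " mm^3)\n", sep = "")
  invisible(x)
}

#' Read a volumetric scan
#'
#' Reads a NIfTI-1 volume into an [activity_volume()]. On-disk NIfTI stores
#' axes as (x, y, z); they are permuted to the package convention (z, y, x),
#' and the per-axis spacing is taken from the file header. DICOM series
#' import is not provided by this build; convert series to NIfTI upstream.
#'
#' @param path path to an existing file.
#' @param format `"nifti"` (canonical) or `"dicom_series"` (unsupported,
#'   raises an error).
#' @return An [activity_volume()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, format = c("nifti", "dicom_series")) {
  format <- match.arg(format)
  if (format == "dicom_series")
    stop("DICOM series import is not available in this build; ",
         "convert the series to NIfTI and use format = \"nifti\"")
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  a <- as.array(img)
  if (length(dim(a)) != 3)
    stop("NIfTI field 'dim': expected a 3D volume, got ",
         length(dim(a)), " dimensions")
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3 || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop("NIfTI field 'pixdim': spacing must be positive, got ",
         paste(sp, collapse = ", "))
  vox <- aperm(a, c(3, 2, 1))        # (x,y,z) on disk -> (z,y,x)
  activity_volume(vox, spacing = rev(sp[1:3]))
}

#' Write a volume to NIfTI
#'
#' Scalar volumes (activity, SUV) are written as double-precision floats;
#' masks as unsigned 8-bit. Round trip through [read_volume()] reproduces
#' masks bit-identically and scalar volumes within float representation.
#'
#' @param vol an `activity_volume`, `suv_image` or `lesion_mask`.
#' @param path output path; the parent directory must exist.
#' @param format only `"nifti"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = "nifti") {
  format <- match.arg(format, "nifti")
  if (!inherits(vol, c("activity_volume", "suv_image", "lesion_mask")))
    stop("vol must be an activity_volume, suv_image or lesion_mask")
  if (!dir.exists(dirname(path)))
    stop("cannot write '", path, "': parent directory does not exist")
  is_mask <- inherits(vol, "lesion_mask")
  a <- vol$voxels
  if (is_mask) storage.mode(a) <- "integer"
  img <- RNifti::asNifti(aperm(a, c(3, 2, 1)))   # (z,y,x) -> (x,y,z) on disk
  RNifti::pixdim(img) <- rev(vol$spacing)
  RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "double")
  invisible(path)
}

#' Read a lesion mask from NIfTI
#'
#' @param path path to a NIfTI file holding a binary volume.
#' @return A [lesion_mask()].
#' @export
read_mask <- function(path) {
  av <- read_volume(path, "nifti")
  if (!all(av$voxels %in% c(0, 1)))
    stop("file does not hold a binary mask: ", path)
  lesion_mask(array(av$voxels > 0.5, dim(av$voxels)), spacing = av$spacing,
              origin = av$origin)
}

#' Convert an activity volume to an SUV image
#'
#' The standardized uptake value of each voxel is
#' \deqn{SUV = \frac{C}{A_{inj}} \times w}
#' with `C` the activity concentration (Bq/mL), `A_inj` the injected
#' activity (Bq) and `w` the body weight (g), which makes the result
#' dimensionless on the conventional g/mL scale. When `decay_correct` is
#' `TRUE`, the injected activity is first decayed from injection time to
#' scan start using the radionuclide half-life, which raises the SUV for a
#' given concentration.
#'
#' @param vol an [activity_volume()].
#' @param meta an [acquisition_meta()].
#' @param decay_correct logical; decay-correct the injected activity.
#'   Default `FALSE`: the conversion is applied exactly as written above,
#'   with no decay term.
#' @return An [suv_image()] on the same grid.
#' @examples
#' av <- activity_volume(array(1000, c(4, 4, 4)))
#' m <- acquisition_meta(injected_activity_bq = 4e6, body_weight_g = 20)
#' suv <- to_suv(av, m)          # uniform SUV 0.005
#' @export
to_suv <- function(vol, meta, decay_correct = FALSE) {
  if (!inherits(vol, "activity_volume"))
    stop("vol must be an activity_volume")
  if (!inherits(meta, "acquisition_meta"))
    stop("meta must be an acquisition_meta")
  a_inj <- meta$injected_activity_bq
  if (isTRUE(decay_correct)) {
    if (is.null(meta$injection_time) || is.null(meta$scan_time))
      stop("decay correction requires both injection_time and scan_time")
    dt_min <- as.numeric(difftime(meta$scan_time, meta$injection_time,
                                  units = "mins"))
    a_inj <- a_inj * 2^(-dt_min / meta$half_life_min)
  }
  suv_image(vol$voxels / a_inj * meta$body_weight_g,
            spacing = vol$spacing, origin = vol$origin, meta = meta)
}
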