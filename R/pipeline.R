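#' @title Per-animal analysis pipeline
#' @name pipeline_cli
#' @description
#' Orchestrates the full per-animal workflow — SUV conversion, MTV
#' segmentation, lesion QC, partial-volume-corrected quantification and
#' response classification — with a reproducible run manifest. A thin
#' command-line wrapper over these functions ships in `inst/cli/quant.R`.
NULL

#' Pipeline configuration
#'
#' One object governs all stage parameters.
#'
#' @param segmentation a [segmentation_config()].
#' @param rc an [rc_table()].
#' @param use_corrected_for_tlg forwarded to [quantify()].
#' @param n_bins,min_prominence_frac forwarded to [qc_report()].
#' @param decay_correct forwarded to [to_suv()] when inputs are activity
#'   volumes.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(segmentation = segmentation_config(),
                            rc = rc_table(), use_corrected_for_tlg = TRUE,
                            n_bins = 16, min_prominence_frac = 0.10,
                            decay_correct = FALSE) {
  structure(list(segmentation = segmentation, rc = rc,
                 use_corrected_for_tlg = use_corrected_for_tlg,
                 n_bins = n_bins, min_prominence_frac = min_prominence_frac,
                 decay_correct = decay_correct),
            class = "pipeline_config")
}

.stage <- function(name, expr, warnings_env) {
  withCallingHandlers(
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      warnings_env$w <- c(warnings_env$w,
                          paste0("[", name, "] ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
}

# Resolve one scan input: an suv_image passes through; an activity_volume or
# a NIfTI path is converted with the supplied acquisition metadata.
.resolve_scan <- function(x, meta, cfg, name, wenv) {
  if (inherits(x, "suv_image")) {
    list(img = x, hash = .fingerprint(list(x$voxels, x$spacing)))
  } else if (inherits(x, "activity_volume")) {
    if (is.null(meta)) stop("stage 'suv': activity input '", name,
                            "' requires acquisition metadata", call. = FALSE)
    img <- .stage("suv", to_suv(x, meta, cfg$decay_correct), wenv)
    list(img = img, hash = .fingerprint(list(x$voxels, x$spacing)))
  } else if (is.character(x) && length(x) == 1) {
    hash <- unname(tools::md5sum(x))
    vol <- .stage("suv", read_volume(x, "nifti"), wenv)
    if (is.null(meta)) stop("stage 'suv': file input '", name,
                            "' requires acquisition metadata", call. = FALSE)
    img <- .stage("suv", to_suv(vol, meta, cfg$decay_correct), wenv)
    list(img = img, hash = hash)
  } else stop("stage 'suv': input '", name,
              "' must be an suv_image, activity_volume or NIfTI path",
              call. = FALSE)
}

.metrics_json <- function(m) {
  m <- unclass(m)
  m[vapply(m, function(v) is.numeric(v) || is.logical(v), logical(1))]
}

#' Run the full per-animal workflow on a pre/post scan pair
#'
#' Executes SUV conversion (when needed), segmentation, QC, quantification
#' and response assessment in order. A QC failure does not abort the run: it
#' gates the partial-volume correction exactly as in [quantify()] and is
#' recorded in the manifest. Re-running with identical inputs and
#' configuration reproduces identical outputs.
#'
#' @param pre,post baseline and follow-up scans: [suv_image()] objects,
#'   [activity_volume()] objects, or NIfTI file paths (the latter two
#'   require `meta_pre`/`meta_post`).
#' @param bbox_pre,bbox_post coarse [bbox3d()] boxes containing the tumor.
#' @param config a [pipeline_config()].
#' @param meta_pre,meta_post [acquisition_meta()] for activity inputs.
#' @param outdir optional directory; when given, masks (NIfTI), the QC
#'   report, both metric sets, the response and the manifest (JSON) are
#'   written there.
#' @return A list with `response` (a `response_assessment`), `metrics_pre`,
#'   `metrics_post`, `qc_pre`, `qc_post`, `mask_pre`, `mask_post` and
#'   `manifest`.
#' @export
run_pipeline <- function(pre, post, bbox_pre, bbox_post,
                         config = pipeline_config(),
                         meta_pre = NULL, meta_post = NULL, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  wenv <- new.env()
  wenv$w <- character(0)

  rs_pre <- .resolve_scan(pre, meta_pre, config, "pre", wenv)
  rs_post <- .resolve_scan(post, meta_post, config, "post", wenv)

  mask_pre <- .stage("segment", segment_mtv(rs_pre$img, bbox_pre,
                                            config$segmentation), wenv)
  mask_post <- .stage("segment", segment_mtv(rs_post$img, bbox_post,
                                             config$segmentation), wenv)
  qc_pre <- .stage("qc", qc_report(rs_pre$img, mask_pre, config$n_bins,
                                   config$min_prominence_frac), wenv)
  qc_post <- .stage("qc", qc_report(rs_post$img, mask_post, config$n_bins,
                                    config$min_prominence_frac), wenv)
  met_pre <- .stage("metrics", quantify(rs_pre$img, mask_pre, qc_pre,
                                        config$rc,
                                        config$use_corrected_for_tlg), wenv)
  met_post <- .stage("metrics", quantify(rs_post$img, mask_post, qc_post,
                                         config$rc,
                                         config$use_corrected_for_tlg), wenv)
  resp <- .stage("respond", assess(met_pre, met_post), wenv)

  manifest <- list(
    software = paste0("petquant ",
                      as.character(utils::packageVersion("petquant"))),
    inputs = list(pre = rs_pre$hash, post = rs_post$hash,
                  bbox_pre = unclass(bbox_pre), bbox_post = unclass(bbox_post)),
    config = list(segmentation = unclass(config$segmentation),
                  rc = as.data.frame(config$rc),
                  use_corrected_for_tlg = config$use_corrected_for_tlg,
                  n_bins = config$n_bins,
                  min_prominence_frac = config$min_prominence_frac,
                  decay_correct = config$decay_correct),
    stages = list(
      segment = list(pre_voxels = sum(mask_pre$voxels),
                     post_voxels = sum(mask_post$voxels)),
      qc = list(pre = unclass(qc_pre), post = unclass(qc_post)),
      metrics = list(pre = .metrics_json(met_pre),
                     post = .metrics_json(met_post)),
      respond = unclass(resp)),
    warnings = wenv$w)

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_volume(mask_pre, file.path(outdir, "mask_pre.nii"))
    write_volume(mask_post, file.path(outdir, "mask_post.nii"))
    wj <- function(x, f) jsonlite::write_json(x, file.path(outdir, f),
                                              auto_unbox = TRUE, digits = NA,
                                              pretty = TRUE)
    wj(unclass(qc_pre), "qc_pre.json")
    wj(unclass(qc_post), "qc_post.json")
    wj(.metrics_json(met_pre), "metrics_pre.json")
    wj(.metrics_json(met_post), "metrics_post.json")
    wj(unclass(resp), "response.json")
    wj(manifest, "manifest.json")
  }

  list(response = resp, metrics_pre = met_pre, metrics_post = met_post,
       qc_pre = qc_pre, qc_post = qc_post, mask_pre = mask_pre,
       mask_post = mask_post, manifest = manifest)
}
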