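#' @title Semi-quantitative immunohistochemistry scoring
#' @name histo_scoring
#' @description
#' The caspase scoring scheme: a staining intensity score (IS, 0-3: none,
#' weak, moderate, strong), an extent score (ES, 0-4) binned from the
#' percentage of immunopositive cells, and their product, the
#' immunoreactivity score (IRS, 0-12). Counts of mitotic, apoptotic and
#' Ki67-positive cells are summarized per 10 high power fields (HPF).
#' Scoring operates on counted tables; the counting itself is manual
#' microscopy and is not modeled.
NULL

#' Extent score from percent immunopositivity
#'
#' The five printed categories are anchored at integer percentages
#' (<5, 5-30, 31-50, 51-75, >75), which leaves real-valued gaps between
#' them; half-integer cut points close the gaps so that every percentage in
#' \[0, 100\] maps to exactly one bin while all printed integer anchors fall
#' in their printed bins: \[0,5) -> 0, \[5,30.5) -> 1, \[30.5,50.5) -> 2,
#' \[50.5,75.5) -> 3, \[75.5,100\] -> 4.
#'
#' @param pct_positive percentage of immunopositive cells in \[0, 100\].
#' @return Integer extent score 0-4.
#' @export
extent_bin <- function(pct_positive) {
  if (!is.numeric(pct_positive) || length(pct_positive) != 1 ||
      !is.finite(pct_positive) || pct_positive < 0 || pct_positive > 100)
    stop("pct_positive must be a single percentage in [0, 100]")
  cuts <- c(5, 30.5, 50.5, 75.5)
  as.integer(findInterval(pct_positive, cuts))
}

#' Immunoreactivity score
#'
#' Product of the intensity score and the extent score.
#'
#' @param is_score integer intensity score in 0-3.
#' @param es_score integer extent score in 0-4.
#' @return Integer IRS in 0-12.
#' @export
irs <- function(is_score, es_score) {
  if (!is.numeric(is_score) || length(is_score) != 1 ||
      is.na(is_score) || is_score != as.integer(is_score) ||
      is_score < 0 || is_score > 3)
    stop("is_score must be an integer in 0..3")
  if (!is.numeric(es_score) || length(es_score) != 1 ||
      is.na(es_score) || es_score != as.integer(es_score) ||
      es_score < 0 || es_score > 4)
    stop("es_score must be an integer in 0..4")
  as.integer(is_score) * as.integer(es_score)
}

#' Summarize per-field cell counts per 10 high power fields
#'
#' Counts are assessed per 10 HPF at 40x magnification. With at least ten
#' field rows, the first ten are summed (or, with `average = TRUE`, all
#' fields are averaged and scaled to ten). With fewer than ten fields the
#' counts are extrapolated by `10 / n` with a warning, and the result is
#' flagged.
#'
#' @param cell_table data frame with a `field_id` column and one or more
#'   non-negative integer count columns (e.g. `mitotic`, `apoptotic`,
#'   `ki67_pos`).
#' @param average logical; average over all fields and scale to 10 instead
#'   of summing the first 10.
#' @return A list with `counts_per_10hpf` (named numeric), `n_fields_used`
#'   and logical `extrapolated`.
#' @export
per_hpf_summary <- function(cell_table, average = FALSE) {
  if (!is.data.frame(cell_table) || !"field_id" %in% names(cell_table))
    stop("cell_table must be a data frame with a field_id column")
  count_cols <- setdiff(names(cell_table), "field_id")
  if (length(count_cols) == 0) stop("cell_table has no count columns")
  counts <- cell_table[count_cols]
  if (any(vapply(counts, function(v) any(!is.finite(v)) || any(v < 0) ||
                   any(v != round(v)), logical(1))))
    stop("counts must be non-negative integers")
  n <- nrow(cell_table)
  if (n == 0) stop("cell_table is empty")
  extrapolated <- FALSE
  if (n < 10) {
    warning("only ", n, " fields provided; counts extrapolated to 10 HPF")
    out <- colSums(counts) * 10 / n
    extrapolated <- TRUE
    used <- n
  } else if (isTRUE(average)) {
    out <- colMeans(counts) * 10
    used <- n
  } else {
    out <- colSums(counts[seq_len(10), , drop = FALSE])
    used <- 10L
  }
  list(counts_per_10hpf = out, n_fields_used = used,
       extrapolated = extrapolated)
}

#' Full histopathology score
#'
#' Convenience wrapper assembling the per-10-HPF counts and the IS/ES/IRS
#' scores for one specimen.
#'
#' @param cell_table per-field counts, see [per_hpf_summary()].
#' @param is_score staining intensity score 0-3.
#' @param pct_positive percentage of immunopositive cells.
#' @param average forwarded to [per_hpf_summary()].
#' @return A list of class `histo_score` with `intensity_score`,
#'   `extent_score`, `irs`, `counts_per_10hpf`, `extrapolated`.
#' @export
histo_score <- function(cell_table, is_score, pct_positive, average = FALSE) {
  es <- extent_bin(pct_positive)
  s <- per_hpf_summary(cell_table, average = average)
  structure(list(intensity_score = as.integer(is_score), extent_score = es,
                 irs = irs(is_score, es),
                 counts_per_10hpf = s$counts_per_10hpf,
                 n_fields_used = s$n_fields_used,
                 extrapolated = s$extrapolated),
            class = "histo_score")
}

#' @export
print.histo_score <- function(x, ...) {
  cat(sprintf("<histo_score> IS %d x ES %d = IRS %d%s\n", x$intensity_score,
              x$extent_score, x$irs,
              if (x$extrapolated) " (counts extrapolated)" else ""))
  cat("  per 10 HPF:", paste(names(x$counts_per_10hpf),
                             x$counts_per_10hpf, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
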