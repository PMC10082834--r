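#' @title Longitudinal response assessment and cohort statistics
#' @name response_assessment
#' @description
#' Percentage change of SUV, MTV and TLG between a baseline and a follow-up
#' scan, the EORTC-style response category driven by the SUV change, and the
#' group-comparison decision tree used for cohort tables.
NULL

#' Percentage change from baseline
#'
#' `100 * (post - pre) / pre`.
#'
#' @param pre baseline value (> 0).
#' @param post follow-up value.
#' @return Percent change.
#' @export
delta_metric <- function(pre, post) {
  if (!is.numeric(pre) || !is.numeric(post) || !is.finite(pre) || !is.finite(post))
    stop("pre and post must be finite numbers")
  if (pre <= 0) stop("baseline value must be positive")
  100 * (post - pre) / pre
}

#' EORTC-style metabolic response category
#'
#' Progressive disease when the SUV change exceeds +25 percent, partial
#' response below -15 percent, stable disease in between. The printed rules
#' are strict inequalities on all branches, which leaves the two boundary
#' values unassigned; they are assigned to stable disease (closed-interval
#' convention), so exactly +25 and exactly -15 are stable.
#'
#' @param delta_suv percent change of SUV (finite).
#' @return One of `"progressive"`, `"stable"`, `"partial_response"`.
#' @export
classify_eortc <- function(delta_suv) {
  if (!is.numeric(delta_suv) || length(delta_suv) != 1 || !is.finite(delta_suv))
    stop("delta_suv must be a single finite number")
  if (delta_suv > 25) "progressive"
  else if (delta_suv < -15) "partial_response"
  else "stable"
}

#' Assess response between two scans
#'
#' Computes the percentage change of SUV, MTV and TLG and classifies the
#' response. The SUV change is evaluated on the corrected SUVmean (which
#' equals the uncorrected one when no correction was applied).
#'
#' @param pre,post `lesion_metrics` from [quantify()].
#' @return A list of class `response_assessment` with `delta_suv`,
#'   `delta_mtv`, `delta_tlg` (percent) and `category`.
#' @export
assess <- function(pre, post) {
  stopifnot(inherits(pre, "lesion_metrics"), inherits(post, "lesion_metrics"))
  d_suv <- delta_metric(pre$suv_mean_corrected, post$suv_mean_corrected)
  d_mtv <- delta_metric(pre$mtv_mm3, post$mtv_mm3)
  d_tlg <- delta_metric(pre$tlg, post$tlg)
  structure(list(delta_suv = d_suv, delta_mtv = d_mtv, delta_tlg = d_tlg,
                 category = classify_eortc(d_suv)),
            class = "response_assessment")
}

#' @export
print.response_assessment <- function(x, ...) {
  cat(sprintf("<response_assessment> dSUV %+.1f%%, dMTV %+.1f%%, dTLG %+.1f%% -> %s\n",
              x$delta_suv, x$delta_mtv, x$delta_tlg, x$category))
  invisible(x)
}

# Holm-Sidak step-down adjustment of a vector of p-values.
.holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- 1 - (1 - p[o[i]])^(m - i + 1)
    running <- max(running, val)
    adj[o[i]] <- min(1, running)
  }
  adj
}

#' Compare metric values across cohort groups
#'
#' Implements the group-comparison decision tree: every group is tested for
#' normality with a Shapiro-Wilk test, and the groups jointly for
#' homogeneity of variance (Levene-type test on absolute deviations from
#' the group medians). When both pass at `alpha`, a two-tailed unpaired
#' Student's t test compares two groups, or a one-way ANOVA with Holm-Sidak
#' adjusted pairwise comparisons compares more than two. Otherwise a
#' Kruskal-Wallis test is used. Groups with fewer than three observations
#' cannot be tested for normality; the comparison then falls to the
#' nonparametric branch with a warning.
#'
#' @param tbl a data frame with columns `group` and `value` (one row per
#'   animal). At least two groups with at least two observations each.
#' @param metric optional column name to use instead of `value`.
#' @param alpha significance level of the assumption checks (default 0.05).
#' @return A list of class `group_comparison`: `branch` (`"parametric"` or
#'   `"nonparametric"`), `test` (name of the test run), `statistic`,
#'   `p_value`, `normality_p` (per group), `variance_p`, and for the ANOVA
#'   branch a data frame `pairwise` of Holm-Sidak adjusted p-values.
#' @export
compare_groups <- function(tbl, metric = "value", alpha = 0.05) {
  if (!is.data.frame(tbl) || !"group" %in% names(tbl) || !metric %in% names(tbl))
    stop("tbl must be a data frame with columns 'group' and '", metric, "'")
  g <- factor(tbl$group)
  y <- tbl[[metric]]
  if (anyNA(y) || any(!is.finite(y))) stop("metric values must be finite")
  ng <- nlevels(g)
  if (ng < 2) stop("need at least two groups")
  sizes <- table(g)
  if (any(sizes < 2)) stop("every group needs at least two observations")

  normality_p <- rep(NA_real_, ng)
  names(normality_p) <- levels(g)
  testable <- all(sizes >= 3)
  constant <- tapply(y, g, function(v) diff(range(v)) == 0)
  if (testable && !any(constant)) {
    for (i in seq_len(ng))
      normality_p[i] <- stats::shapiro.test(y[g == levels(g)[i]])$p.value
  }

  if (!testable) {
    warning("a group has fewer than 3 observations: normality untestable, ",
            "falling to the nonparametric branch")
    parametric <- FALSE
    variance_p <- NA_real_
  } else if (any(constant)) {
    # a constant group defeats both assumption tests; treat distributionally
    parametric <- FALSE
    variance_p <- NA_real_
  } else {
    lev <- car::leveneTest(y, g)
    variance_p <- lev[["Pr(>F)"]][1]
    parametric <- all(normality_p > alpha) && variance_p > alpha
  }

  pairwise <- NULL
  if (parametric) {
    if (ng == 2) {
      tt <- stats::t.test(y ~ g, var.equal = TRUE)
      res <- list(branch = "parametric", test = "Student t (two-tailed, unpaired)",
                  statistic = unname(tt$statistic), p_value = tt$p.value)
    } else {
      fit <- stats::aov(y ~ g)
      sm <- summary(fit)[[1]]
      combs <- utils::combn(levels(g), 2)
      praw <- apply(combs, 2, function(pair) {
        stats::t.test(y[g == pair[1]], y[g == pair[2]], var.equal = TRUE)$p.value
      })
      pairwise <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                             p_raw = praw, p_adjusted = .holm_sidak(praw))
      res <- list(branch = "parametric",
                  test = "one-way ANOVA + Holm-Sidak pairwise",
                  statistic = sm[["F value"]][1], p_value = sm[["Pr(>F)"]][1])
    }
  } else {
    kw <- stats::kruskal.test(y ~ g)
    res <- list(branch = "nonparametric", test = "Kruskal-Wallis",
                statistic = unname(kw$statistic), p_value = kw$p.value)
  }
  structure(c(res, list(normality_p = normality_p, variance_p = variance_p,
                        alpha = alpha, pairwise = pairwise)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s branch: %s, statistic %.4g, p = %.4g\n",
              x$branch, x$test, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("  Holm-Sidak adjusted pairwise p-values:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
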