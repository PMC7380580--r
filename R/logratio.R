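#' Define a numerator/denominator feature-set pair
#'
#' A log ratio is taken between the summed counts of two disjoint,
#' non-empty feature sets. Pairs either come from differential rankings
#' ([select_extreme_features()]), from curated lists, or from random draws
#' ([random_pair()]).
#'
#' @param numerator,denominator Character vectors of feature IDs.
#' @param provenance One of `"ranked"`, `"curated"`, `"random"`.
#' @param note Free-text source note.
#' @return A `feature_set_pair`.
#' @export
feature_set_pair <- function(numerator, denominator,
                             provenance = c("curated", "ranked", "random"),
                             note = "") {
  provenance <- match.arg(provenance)
  numerator <- as.character(numerator)
  denominator <- as.character(denominator)
  if (length(numerator) == 0 || length(denominator) == 0) {
    stop("numerator and denominator must be non-empty")
  }
  if (length(intersect(numerator, denominator)) > 0) {
    stop("numerator and denominator must be disjoint")
  }
  structure(list(numerator = numerator, denominator = denominator,
                 provenance = provenance, note = note),
            class = "feature_set_pair")
}

#' @export
print.feature_set_pair <- function(x, ...) {
  cat(sprintf("Feature-set pair (%s): %d numerator / %d denominator features\n",
              x$provenance, length(x$numerator), length(x$denominator)))
  invisible(x)
}

#' Per-sample log ratio of two feature sets
#'
#' For each sample, the natural log of the summed numerator counts over
#' the summed denominator counts. Samples where either sum is zero are
#' excluded with a recorded reason, never imputed; the ratio of sums is
#' invariant to any per-sample total scaling, which is the point of using
#' it on compositional data.
#'
#' @param table Samples x features count matrix.
#' @param pair A [feature_set_pair()].
#' @param groups Optional per-sample group labels (named by sample, or in
#'   row order of `table`).
#' @return A `log_ratio_series`: list with `values` (named numeric),
#'   `group` (factor or `NULL`, aligned to `values`), `excluded`
#'   (data frame of sample ID and reason), and the `pair`.
#' @export
compute_log_ratio <- function(table, pair, groups = NULL) {
  .check_count_table(table)
  stopifnot(inherits(pair, "feature_set_pair"))
  missing <- setdiff(c(pair$numerator, pair$denominator), colnames(table))
  if (length(missing) > 0) {
    stop("features absent from the table: ", paste(missing, collapse = ", "))
  }
  num <- rowSums(table[, pair$numerator, drop = FALSE])
  den <- rowSums(table[, pair$denominator, drop = FALSE])
  reason <- character(nrow(table))
  reason[num == 0] <- "zero numerator"
  reason[den == 0] <- "zero denominator"
  reason[num == 0 & den == 0] <- "zero numerator and denominator"
  keep <- num > 0 & den > 0
  if (!any(keep)) stop("all samples excluded: every sample has a zero side")
  values <- log(num[keep] / den[keep])
  names(values) <- rownames(table)[keep]
  group <- NULL
  if (!is.null(groups)) {
    group <- .align_groups(groups, table)[keep]
    names(group) <- names(values)
  }
  structure(list(
    values = values,
    group = group,
    excluded = data.frame(sample_id = rownames(table)[!keep],
                          reason = reason[!keep]),
    pair = pair
  ), class = "log_ratio_series")
}

#' @export
print.log_ratio_series <- function(x, ...) {
  cat(sprintf("Log-ratio series: %d samples (%d excluded)\n",
              length(x$values), nrow(x$excluded)))
  invisible(x)
}

.two_group_values <- function(x, y, what = "welch_t") {
  if (inherits(x, "log_ratio_series")) {
    if (is.null(x$group)) stop("series carries no group labels")
    g <- droplevels(x$group)
    if (nlevels(g) != 2) stop("exactly two groups are required")
    list(x = x$values[g == levels(g)[1]],
         y = x$values[g == levels(g)[2]],
         labels = levels(g))
  } else {
    if (is.null(y)) stop(what, " needs either a grouped series or two vectors")
    list(x = as.numeric(x), y = as.numeric(y), labels = c("x", "y"))
  }
}

#' Welch two-sample t test with Cohen's D
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value, plus Cohen's D computed with the
#' pooled standard deviation (the conventional effect-size definition,
#' even though the test itself does not pool). The difference is taken as
#' first group minus second group.
#'
#' @param x A grouped `log_ratio_series`, or a numeric vector.
#' @param y Second numeric vector when `x` is a vector.
#' @return List with `t`, `df`, `p`, `cohens_d`, and per-group `n`.
#' @export
welch_t <- function(x, y = NULL) {
  v <- .two_group_values(x, y, "welch_t")
  n1 <- length(v$x); n2 <- length(v$y)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  s1 <- stats::var(v$x); s2 <- stats::var(v$y)
  if (s1 == 0 && s2 == 0) {
    if (mean(v$x) == mean(v$y)) {
      return(list(t = 0, df = n1 + n2 - 2, p = 1, cohens_d = 0,
                  n = c(n1, n2)))
    }
    stop("both groups are constant with different means: t is undefined")
  }
  if (s1 == 0 || s2 == 0) {
    stop("one group has zero variance: Cohen's D is not defined here")
  }
  tt <- stats::t.test(v$x, v$y, var.equal = FALSE)
  sp <- sqrt(((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = (mean(v$x) - mean(v$y)) / sp,
       n = c(n1, n2))
}

#' Two-sided Wilcoxon/Mann-Whitney rank-sum test
#'
#' Uses exact enumeration when both groups have fewer than 20 observations
#' and there are no ties, and the tie-corrected normal approximation (with
#' continuity correction) otherwise.
#'
#' @param x A grouped `log_ratio_series`, or a numeric vector.
#' @param y Second numeric vector when `x` is a vector.
#' @return List with `statistic` (Mann-Whitney U for the first group) and
#'   `p`.
#' @export
rank_sum <- function(x, y = NULL) {
  v <- .two_group_values(x, y, "rank_sum")
  if (length(v$x) < 1 || length(v$y) < 1) {
    stop("each group needs at least 1 sample")
  }
  has_ties <- anyDuplicated(c(v$x, v$y)) > 0
  exact <- length(v$x) < 20 && length(v$y) < 20 && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(v$x, v$y, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction,
#' `df = (rows - 1) * (cols - 1)`.
#'
#' @param tab Matrix of nonnegative integer counts, at least 2 x 2.
#' @return List with `chi2`, `df`, `p`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need at least a 2 x 2 table")
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab))) {
    stop("contingency table must hold nonnegative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("a zero row or column marginal makes the test undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Benjamini-Hochberg adjustment utility
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, provided so
#' multi-panel comparisons can correct for multiple testing.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
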