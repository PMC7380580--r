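#' Pair consecutive usable time points within subjects
#'
#' Turns a per-sample statistic (typically a log-ratio series) into
#' (value at t, value at the next usable t) pairs within each subject.
#' Samples excluded upstream (e.g. by zero-ratio handling) create gaps;
#' pairs are formed only between adjacent *usable* time points, and
#' `gap_bridged` records whether the pair spans a missing time point. A
#' subject with up to 4 weekly samples contributes up to 3 pairs.
#'
#' @param series A `log_ratio_series`, or a numeric vector named by
#'   sample ID.
#' @param meta Sample metadata with subject and time-point columns.
#' @param subject_col,time_col,id_col Metadata column names.
#' @return Data frame with `subject`, `group` (if the series carries
#'   groups), `time_from`, `time_to`, `x`, `y`, `gap_bridged`.
#' @export
consecutive_pairs <- function(series, meta, subject_col = "subject",
                              time_col = "timepoint", id_col = "SampleID") {
  values <- if (inherits(series, "log_ratio_series")) series$values else series
  if (is.null(names(values))) stop("series values must be named by sample ID")
  groups <- if (inherits(series, "log_ratio_series")) series$group else NULL
  meta <- .meta_by_sample(meta, id_col)
  missing_cols <- setdiff(c(subject_col, time_col), colnames(meta))
  if (length(missing_cols) > 0) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  missing <- setdiff(names(values), rownames(meta))
  if (length(missing) > 0) {
    stop("metadata missing for samples: ", paste(missing, collapse = ", "))
  }
  sub <- meta[names(values), , drop = FALSE]
  out <- list()
  for (s in unique(sub[[subject_col]])) {
    idx <- which(sub[[subject_col]] == s)
    if (length(idx) < 2) next
    times <- sub[[time_col]][idx]
    if (anyDuplicated(times)) {
      stop("subject '", s, "' has duplicate time points; deduplicate first")
    }
    ord <- idx[order(times)]
    t_ord <- sort(times)
    for (i in seq_len(length(ord) - 1L)) {
      out[[length(out) + 1L]] <- data.frame(
        subject = s,
        group = if (is.null(groups)) NA_character_ else
          as.character(groups[ord[i]]),
        time_from = t_ord[i], time_to = t_ord[i + 1L],
        x = unname(values[ord[i]]), y = unname(values[ord[i + 1L]]),
        gap_bridged = (t_ord[i + 1L] - t_ord[i]) > 1,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    stop("no subject contributes two usable time points")
  }
  do.call(rbind, out)
}

#' Stability of a per-sample statistic across consecutive time points
#'
#' Pools the (t, t+1) pairs of all subjects into a single Spearman rank
#' correlation (tie-corrected) plus an ordinary least-squares fit of the
#' later value on the earlier one. With `by = "group"` the correlation is
#' computed within each group separately, mirroring per-group stability
#' panels.
#'
#' @param pairs Output of [consecutive_pairs()] (needs `x` and `y`).
#' @param by Optional column of `pairs` to stratify by (e.g. `"group"`).
#' @return Data frame with one row per stratum: `group`, `n_pairs`,
#'   `spearman_rho`, `p`, `ols_slope`, `ols_intercept`.
#' @export
stability_correlation <- function(pairs, by = NULL) {
  one <- function(df, label) {
    if (nrow(df) < 3) stop("need at least 3 pairs for a correlation")
    if (stats::sd(df$x) == 0 || stats::sd(df$y) == 0) {
      stop("constant values: correlation undefined")
    }
    ct <- suppressWarnings(
      stats::cor.test(df$x, df$y, method = "spearman", exact = FALSE))
    fit <- stats::lm(y ~ x, data = df)
    data.frame(group = label, n_pairs = nrow(df),
               spearman_rho = unname(ct$estimate), p = ct$p.value,
               ols_slope = unname(stats::coef(fit)[2]),
               ols_intercept = unname(stats::coef(fit)[1]),
               stringsAsFactors = FALSE)
  }
  if (is.null(by)) return(one(pairs, "all"))
  if (!by %in% colnames(pairs)) stop("no column '", by, "' in pairs")
  res <- lapply(split(pairs, pairs[[by]]), function(df) {
    one(df, as.character(df[[by]][1]))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
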