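#' Add-one permutation p-value and its 4-decimal display form
#'
#' The permutation p-value is `rank / (B + 1)`, where `rank` is 1 plus the
#' number of null statistics at least as extreme as the observed one, so
#' the observed statistic counts as one member of the null ensemble and
#' the p-value can never be zero (its minimum is `1 / (B + 1)`). For
#' display the full-precision value is truncated (not rounded) to four
#' decimals: rank 16 among B = 1000 draws gives 16/1001 = 0.015984,
#' displayed as 0.0159, and rank 2 gives 2/1001 = 0.001998, displayed as
#' 0.0019.
#'
#' @param rank Integer rank of the observed statistic, in `[1, B + 1]`.
#' @param B Number of permutations.
#' @return `permutation_pvalue()`: the full-precision p-value.
#' @export
permutation_pvalue <- function(rank, B) {
  if (B < 1) stop("B must be >= 1")
  if (rank < 1 || rank > B + 1) stop("rank must lie in [1, B + 1]")
  rank / (B + 1)
}

#' @rdname permutation_pvalue
#' @param p A p-value in (0, 1].
#' @return `format_p_display()`: the truncated 4-decimal display string.
#' @export
format_p_display <- function(p) {
  sprintf("%.4f", floor(p * 1e4 + 1e-9) / 1e4)
}

#' Draw a random nonoverlapping feature-set pair
#'
#' Uniform draw without replacement of `k_num + k_den` distinct features
#' from the pool; the first `k_num` form the numerator. Uses the current
#' RNG stream.
#'
#' @param feature_pool Character vector of candidate feature IDs.
#' @param k_num,k_den Numerator and denominator sizes.
#' @return A [feature_set_pair()] with provenance `"random"`.
#' @export
random_pair <- function(feature_pool, k_num = 20, k_den = 20) {
  feature_pool <- as.character(feature_pool)
  if (k_num + k_den > length(feature_pool)) {
    stop("feature pool too small for the requested set sizes")
  }
  draw <- sample(feature_pool, k_num + k_den)
  feature_set_pair(draw[seq_len(k_num)], draw[k_num + seq_len(k_den)],
                   provenance = "random")
}

#' Assemble a permutation result from observed and null statistics
#'
#' @param observed_stat Observed (two-sided, absolute) group statistic.
#' @param null_stats Numeric vector of B null statistics.
#' @param k_num,k_den Feature-set sizes used (bookkeeping).
#' @param seed Seed used (bookkeeping).
#' @param n_redraws Number of degenerate null draws that were redrawn.
#' @return A `permutation_result` with `rank`, full-precision `p_value`,
#'   and 4-decimal `p_display`.
#' @export
permutation_result <- function(observed_stat, null_stats,
                               k_num = NA_integer_, k_den = NA_integer_,
                               seed = NA_integer_, n_redraws = 0L) {
  B <- length(null_stats)
  rank <- 1L + sum(null_stats >= observed_stat)
  p <- permutation_pvalue(rank, B)
  structure(list(
    observed_stat = observed_stat,
    null_stats = null_stats,
    rank = rank,
    p_value = p,
    p_display = format_p_display(p),
    B = B,
    k_num = k_num, k_den = k_den,
    seed = seed, n_redraws = n_redraws
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed |stat| = %.4f, rank %d of %d permutations, p = %s\n",
    x$observed_stat, x$rank, x$B, x$p_display))
  invisible(x)
}

#' Random-feature-set permutation test for a selected log ratio
#'
#' Validates a chosen feature-set log ratio against a null of random
#' selections: for each of `B` random nonoverlapping pairs (same set sizes
#' as the observed pair unless overridden), the log-ratio series is
#' computed and the absolute Welch t between groups recorded. The rank of
#' the observed statistic within this ensemble gives the add-one
#' permutation p-value. Null draws where the statistic is degenerate
#' (all samples excluded, a group left with fewer than two samples, or a
#' zero-variance group) are redrawn and counted.
#'
#' Note the null reuses features across draws; with small feature pools
#' the null statistics are therefore dependent. This is a property of the
#' method, not a defect of the implementation.
#'
#' @param table Samples x features count matrix.
#' @param groups Per-sample two-level group labels (named by sample, or in
#'   row order).
#' @param observed_pair The selected [feature_set_pair()].
#' @param B Number of random permutations.
#' @param stat Null statistic; only `"welch_t_abs"` is implemented.
#' @param seed Integer seed.
#' @param k_num,k_den Null set sizes (default: sizes of `observed_pair`).
#' @param max_redraw_factor Error out after `max_redraw_factor * B`
#'   degenerate redraws.
#' @return A [permutation_result()].
#' @export
permutation_test <- function(table, groups, observed_pair, B = 1000,
                             stat = "welch_t_abs", seed = 1,
                             k_num = NULL, k_den = NULL,
                             max_redraw_factor = 100) {
  stat <- match.arg(stat, "welch_t_abs")
  .check_count_table(table)
  if (B < 1) stop("B must be >= 1")
  if (is.null(k_num)) k_num <- length(observed_pair$numerator)
  if (is.null(k_den)) k_den <- length(observed_pair$denominator)
  groups <- .align_groups(groups, table)

  stat_for_pair <- function(pair) {
    series <- compute_log_ratio(table, pair, groups = groups)
    abs(welch_t(series)$t)
  }
  observed <- stat_for_pair(observed_pair)

  pool <- colnames(table)
  .with_seed(seed, {
    null_stats <- numeric(B)
    redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        val <- tryCatch(stat_for_pair(random_pair(pool, k_num, k_den)),
                        error = function(e) NA_real_)
        if (!is.na(val)) break
        redraws <- redraws + 1L
        if (redraws > max_redraw_factor * B) {
          stop("too many degenerate null draws; table too sparse for the null")
        }
      }
      null_stats[b] <- val
    }
  })
  permutation_result(observed, null_stats, k_num = k_num, k_den = k_den,
                     seed = seed, n_redraws = redraws)
}
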