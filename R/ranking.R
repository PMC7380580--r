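#' Specification of the multinomial differential-ranking regression
#'
#' Counts are modeled as `counts_i ~ Multinomial(n_i, softmax(X_i B))`
#' with an independent normal(0, `prior_sd^2`) penalty on every
#' coefficient, fitted by stochastic first-order gradient ascent (Adam)
#' in additive-log-ratio coordinates against a reference feature. The
#' published configuration (5000 epochs, minibatches of 5, learning rate
#' 1e-4, 10 random held-out test samples, minimum sample count 1000, no
#' feature-count gate) is the default.
#'
#' @param covariates Character vector of metadata column names; the
#'   binary consumption indicator is the primary use. Factor or character
#'   columns enter through treatment contrasts; pass a 0/1 numeric for an
#'   explicit direction.
#' @param epochs Training epochs (full passes over the samples).
#' @param batch_size Minibatch size; values >= the number of samples give
#'   full-batch training.
#' @param learning_rate Adam base learning rate.
#' @param prior_sd Standard deviation of the normal coefficient prior.
#' @param n_test_samples Held-out samples for [evaluate_q2()].
#' @param min_sample_count Samples with fewer total counts are dropped
#'   before fitting.
#' @param min_feature_count Features observed (nonzero) in at most this
#'   many samples are dropped before fitting.
#' @param seed Integer seed (minibatch shuffling and test-set choice).
#' @return A `regression_spec`.
#' @export
regression_spec <- function(covariates = "consumer",
                            epochs = 5000,
                            batch_size = 5,
                            learning_rate = 1e-4,
                            prior_sd = 1,
                            n_test_samples = 10,
                            min_sample_count = 1000,
                            min_feature_count = 0,
                            seed = 1) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (prior_sd <= 0) stop("prior_sd must be > 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(covariates = as.character(covariates),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 prior_sd = prior_sd,
                 n_test_samples = as.integer(n_test_samples),
                 min_sample_count = min_sample_count,
                 min_feature_count = min_feature_count,
                 seed = as.integer(seed)),
            class = "regression_spec")
}

# Build the design matrix (Intercept first) from metadata columns.
.design_matrix <- function(meta, covariates) {
  missing <- setdiff(covariates, colnames(meta))
  if (length(missing) > 0) {
    stop("metadata is missing covariate column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- meta[, covariates, drop = FALSE]
  for (cl in covariates) {
    if (is.character(df[[cl]]) || is.logical(df[[cl]])) {
      df[[cl]] <- factor(df[[cl]])
    }
    v <- df[[cl]]
    if ((is.factor(v) && nlevels(droplevels(v)) < 2) ||
        (is.numeric(v) && stats::var(v) == 0)) {
      stop("covariate '", cl, "' is constant")
    }
  }
  X <- stats::model.matrix(~ ., data = df)
  colnames(X)[1] <- "Intercept"
  X
}

# Align table and metadata, apply the pre-fit count gates, pick the ALR
# reference (most prevalent feature, ties by ID), and return the pieces
# the optimizer needs.
.prepare_fit <- function(table, meta, spec, reference = NULL) {
  .check_count_table(table)
  meta <- .meta_by_sample(meta)
  missing <- setdiff(rownames(table), rownames(meta))
  if (length(missing) > 0) {
    stop("metadata missing for samples: ", paste(missing, collapse = ", "))
  }
  keep <- rowSums(table) >= spec$min_sample_count
  table <- table[keep, , drop = FALSE]
  if (nrow(table) < 2) stop("fewer than 2 samples pass min_sample_count")
  prevalence <- colSums(table > 0)
  table <- table[, prevalence > spec$min_feature_count & prevalence > 0,
                 drop = FALSE]
  if (ncol(table) < 2) stop("fewer than 2 features pass min_feature_count")
  meta <- meta[rownames(table), , drop = FALSE]
  X <- .design_matrix(meta, spec$covariates)
  if (is.null(reference)) {
    prevalence <- colSums(table > 0)
    ord <- order(-prevalence, colnames(table))
    reference <- colnames(table)[ord[1]]
  } else if (!reference %in% colnames(table)) {
    stop("reference feature '", reference, "' not in the (filtered) table")
  }
  list(table = table, X = X, reference = reference)
}

# Adam-optimized MAP fit of the multinomial logit model in ALR
# coordinates. Returns the p x D logit coefficient matrix (reference
# column fixed at zero) and the per-epoch penalized mean log-likelihood.
.fit_multinomial <- function(Y, X, reference_idx, spec) {
  n <- nrow(Y); D <- ncol(Y); p <- ncol(X)
  lib <- rowSums(Y)
  free <- setdiff(seq_len(D), reference_idx)
  B <- matrix(0, p, D)   # reference column stays 0
  m <- v <- matrix(0, p, length(free))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- spec$learning_rate
  lambda <- 1 / spec$prior_sd^2
  step <- 0L
  batch <- min(spec$batch_size, n)
  loss <- numeric(spec$epochs)
  for (epoch in seq_len(spec$epochs)) {
    ord <- if (batch < n) sample.int(n) else seq_len(n)
    starts <- seq(1L, n, by = batch)
    ll_epoch <- 0
    for (s in starts) {
      idx <- ord[s:min(s + batch - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      eta <- Xb %*% B
      P <- .softmax_rows(eta)
      ll_epoch <- ll_epoch + sum(Yb * log(pmax(P, 1e-300)))
      G <- Yb - lib[idx] * P
      grad <- (n / length(idx)) * crossprod(Xb, G[, free, drop = FALSE]) -
        lambda * B[, free, drop = FALSE]
      step <- step + 1L
      m <- b1 * m + (1 - b1) * grad
      v <- b2 * v + (1 - b2) * grad^2
      mhat <- m / (1 - b1^step)
      vhat <- v / (1 - b2^step)
      B[, free] <- B[, free] + lr * mhat / (sqrt(vhat) + eps)
    }
    loss[epoch] <- (ll_epoch - 0.5 * lambda * sum(B^2)) / n
    if (!is.finite(loss[epoch])) {
      stop(sprintf(
        "optimization diverged at epoch %d (non-finite penalized log-likelihood); last finite value: %.4g",
        epoch, if (epoch > 1) loss[epoch - 1] else NA_real_))
    }
  }
  rownames(B) <- colnames(X)
  colnames(B) <- colnames(Y)
  list(coef = B, loss = loss)
}

#' Fit per-feature differentials by regularized multinomial regression
#'
#' Maximizes the penalized multinomial log-likelihood of the counts given
#' the design built from `spec$covariates`, in additive-log-ratio (ALR)
#' coordinates against a reference feature (by default the most prevalent
#' feature), then recenters each covariate's coefficients across features
#' to centered-log-ratio (CLR) differentials. Only the ordering of
#' differentials (or ratios between them) is interpretable; absolute
#' abundances are unidentifiable from compositions. Deterministic given
#' `spec$seed`.
#'
#' @param table Samples x features count matrix.
#' @param meta Sample metadata (matched by `SampleID` column or row
#'   names).
#' @param spec A [regression_spec()].
#' @param reference Optional ALR reference feature ID.
#' @return A `differential_ranks` object: `differentials` (features x
#'   covariates matrix, each column summing to zero; includes
#'   `Intercept`), the ALR `coef_logit` matrix used for prediction,
#'   `reference`, per-epoch `loss`, and the `spec`.
#' @export
fit_differentials <- function(table, meta, spec = regression_spec(),
                              reference = NULL) {
  prep <- .prepare_fit(table, meta, spec, reference)
  Y <- prep$table
  ref_idx <- match(prep$reference, colnames(Y))
  fit <- .with_seed(spec$seed,
                    .fit_multinomial(Y, prep$X, ref_idx, spec))
  clr <- fit$coef - rowMeans(fit$coef)
  structure(list(
    differentials = t(clr),
    coef_logit = fit$coef,
    reference = prep$reference,
    loss = fit$loss,
    spec = spec,
    samples = rownames(Y),
    features = colnames(Y)
  ), class = "differential_ranks")
}

#' @export
print.differential_ranks <- function(x, ...) {
  cat(sprintf(
    "Differential ranks: %d features x %d covariates (ALR reference: %s)\n",
    nrow(x$differentials), ncol(x$differentials), x$reference))
  cat(sprintf("Final penalized mean log-likelihood: %.4f after %d epochs\n",
              x$loss[length(x$loss)], length(x$loss)))
  invisible(x)
}

# Predicted counts for samples in `table` under a fitted logit matrix.
.predict_counts <- function(coef_logit, X, lib) {
  P <- .softmax_rows(X %*% coef_logit)
  lib * P
}

#' Predictive Q2 of the ranking model against an intercept-only baseline
#'
#' Holds out `spec$n_test_samples` samples (chosen once by `spec$seed`),
#' fits the covariate model and an intercept-only baseline on the
#' remainder, and scores held-out predicted counts by mean absolute
#' error: `Q2 = 1 - MAE(model) / MAE(baseline)`. Values at or below zero
#' indicate no predictive gain over the baseline (possible overfitting);
#' a perfect model reaches 1.
#'
#' @inheritParams fit_differentials
#' @return List with `q2`, `mae_model`, `mae_baseline`, `test_samples`.
#' @export
evaluate_q2 <- function(table, meta, spec = regression_spec()) {
  prep <- .prepare_fit(table, meta, spec)
  Y <- prep$table
  n <- nrow(Y)
  if (spec$n_test_samples < 1) stop("held-out set must have >= 1 sample")
  if (spec$n_test_samples >= n) stop("held-out set leaves no training samples")
  test <- .with_seed(spec$seed, sort(sample.int(n, spec$n_test_samples)))
  train <- setdiff(seq_len(n), test)

  ref_idx <- match(prep$reference, colnames(Y))
  fit_on <- function(Xtr) {
    .with_seed(spec$seed,
               .fit_multinomial(Y[train, , drop = FALSE], Xtr, ref_idx, spec))
  }
  full <- fit_on(prep$X[train, , drop = FALSE])
  base <- fit_on(prep$X[train, "Intercept", drop = FALSE])

  lib <- rowSums(Y[test, , drop = FALSE])
  Xte <- prep$X[test, , drop = FALSE]
  pred_full <- .predict_counts(full$coef, Xte, lib)
  pred_base <- .predict_counts(
    base$coef, Xte[, "Intercept", drop = FALSE], lib)
  obs <- Y[test, , drop = FALSE]
  mae_model <- mean(abs(pred_full - obs))
  mae_base <- mean(abs(pred_base - obs))
  list(q2 = 1 - mae_model / mae_base,
       mae_model = mae_model, mae_baseline = mae_base,
       test_samples = rownames(Y)[test])
}

#' Select the k highest- and k lowest-ranked features as a log-ratio pair
#'
#' The numerator takes the `k` largest differentials for the covariate and
#' the denominator the `k` smallest; ties are broken by lexicographically
#' smaller feature ID.
#'
#' @param ranks A `differential_ranks` object.
#' @param covariate Covariate column of the differential matrix.
#' @param k Features per side; `2 * k` must not exceed the feature count.
#' @return A [feature_set_pair()] with provenance `"ranked"`.
#' @export
select_extreme_features <- function(ranks, covariate, k = 20) {
  stopifnot(inherits(ranks, "differential_ranks"))
  if (!covariate %in% colnames(ranks$differentials)) {
    stop("unknown covariate '", covariate, "'")
  }
  d <- ranks$differentials[, covariate]
  ids <- rownames(ranks$differentials)
  if (2 * k > length(d)) stop("2 * k exceeds the number of features")
  num <- ids[order(-d, ids)][seq_len(k)]
  den_order <- ids[order(d, ids)]
  den <- setdiff(den_order, num)[seq_len(k)]
  feature_set_pair(num, den, provenance = "ranked",
                   note = sprintf("top/bottom %d by '%s' differential", k,
                                  covariate))
}
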