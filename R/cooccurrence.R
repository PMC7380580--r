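#' Fit a microbe-metabolite cooccurrence model
#'
#' Estimates, for every microbe, the conditional probability distribution
#' over metabolites: the probability of observing each metabolite given a
#' randomly drawn read of that microbe. The metabolite distribution for
#' microbe `i` is `softmax(U_i . V' + bias)`, a low-rank (`d`-dimensional)
#' factorization fitted by full-batch first-order gradient ascent (Adam)
#' on the cooccurrence likelihood, with a weak normal prior on the latent
#' matrices for identifiability. The sufficient statistic is the
#' sample-normalized microbe-by-metabolite cross-product, so permuting
#' sample order leaves the fit unchanged.
#'
#' Both tables are aligned on their shared samples (with a warning when
#' samples are dropped).
#'
#' @param microbes Samples x microbes count matrix.
#' @param metabolites Samples x metabolites count matrix.
#' @param d Latent dimension; must be below `min(#microbes, #metabolites)`.
#' @param epochs Gradient-ascent epochs.
#' @param learning_rate Adam base learning rate.
#' @param prior_sd Standard deviation of the normal prior on `U` and `V`.
#' @param seed Integer seed (latent initialization).
#' @return A `cooccurrence_model`: `U` (microbes x d), `V`
#'   (metabolites x d), `metabolite_bias`, `conditional` (microbes x
#'   metabolites, rows summing to one), per-epoch `loglik`, and `d`.
#' @export
fit_cooccurrence <- function(microbes, metabolites, d = 2,
                             epochs = 1500, learning_rate = 0.05,
                             prior_sd = 1, seed = 1) {
  .check_count_table(microbes, "microbes")
  .check_count_table(metabolites, "metabolites")
  shared <- intersect(rownames(microbes), rownames(metabolites))
  dropped <- length(union(rownames(microbes), rownames(metabolites))) -
    length(shared)
  if (length(shared) < 2) stop("need at least 2 shared samples")
  if (dropped > 0) {
    warning(sprintf("dropping %d sample(s) absent from one of the tables",
                    dropped))
  }
  Dm <- ncol(microbes); Dt <- ncol(metabolites)
  if (d >= min(Dm, Dt)) {
    stop("latent dimension d must be smaller than both feature counts")
  }
  Xm <- microbes[shared, , drop = FALSE]
  Xt <- metabolites[shared, , drop = FALSE]
  relt <- Xt / pmax(1, rowSums(Xt))
  # Expected (microbe read, metabolite draw) cooccurrence mass: every
  # microbe read observes its sample's metabolite distribution. Keeping
  # read units makes the likelihood dominate the weak normal prior.
  M <- crossprod(Xm, relt)
  r <- rowSums(M)

  .with_seed(seed, {
    U <- matrix(stats::rnorm(Dm * d, 0, 0.1), Dm, d)
    V <- matrix(stats::rnorm(Dt * d, 0, 0.1), Dt, d)
    bias <- numeric(Dt)
    mu <- list(U = U * 0, V = V * 0, b = bias * 0)
    vu <- mu
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    lambda <- 1 / prior_sd^2
    loglik <- numeric(epochs)
    for (epoch in seq_len(epochs)) {
      eta <- U %*% t(V) + matrix(bias, Dm, Dt, byrow = TRUE)
      P <- .softmax_rows(eta)
      loglik[epoch] <- sum(M * log(pmax(P, 1e-300))) -
        0.5 * lambda * (sum(U^2) + sum(V^2))
      if (!is.finite(loglik[epoch])) {
        stop(sprintf("cooccurrence fit diverged at epoch %d", epoch))
      }
      G <- M - r * P
      grads <- list(U = G %*% V - lambda * U,
                    V = crossprod(G, U) - lambda * V,
                    b = colSums(G))
      for (nm in names(grads)) {
        mu[[nm]] <- b1 * mu[[nm]] + (1 - b1) * grads[[nm]]
        vu[[nm]] <- b2 * vu[[nm]] + (1 - b2) * grads[[nm]]^2
        upd <- learning_rate * (mu[[nm]] / (1 - b1^epoch)) /
          (sqrt(vu[[nm]] / (1 - b2^epoch)) + eps)
        if (nm == "U") U <- U + upd
        if (nm == "V") V <- V + upd
        if (nm == "b") bias <- bias + upd
      }
    }
    eta <- U %*% t(V) + matrix(bias, Dm, Dt, byrow = TRUE)
    P <- .softmax_rows(eta)
    dimnames(P) <- list(colnames(Xm), colnames(Xt))
    rownames(U) <- colnames(Xm)
    rownames(V) <- colnames(Xt)
    names(bias) <- colnames(Xt)
    structure(list(U = U, V = V, metabolite_bias = bias,
                   conditional = P, d = d, loglik = loglik,
                   samples = shared),
              class = "cooccurrence_model")
  })
}

#' @export
print.cooccurrence_model <- function(x, ...) {
  cat(sprintf(
    "Cooccurrence model: %d microbes x %d metabolites, d = %d (%d samples)\n",
    nrow(x$conditional), ncol(x$conditional), x$d, length(x$samples)))
  invisible(x)
}

#' Biplot ordination of the log conditional-probability matrix
#'
#' Singular value decomposition of the column-centered log conditional
#' matrix. Microbe scores are `U_svd %*% diag(s)` and metabolite loadings
#' `V_svd`; the per-axis proportion of variance is `s^2 / sum(s^2)`. Each
#' axis is oriented canonically so that the metabolite loading of largest
#' magnitude is positive; an SVD axis sign is otherwise arbitrary, so when
#' a correlation sign against some external gradient matters, anchor the
#' orientation with `orient_by` (each axis is then flipped so the named
#' metabolite's loading is nonnegative, i.e. the axis "points toward"
#' that metabolite's arrow).
#'
#' @param model A fitted `cooccurrence_model`.
#' @param n_axes Number of axes to return (at most 3 by default).
#' @param orient_by Optional metabolite ID used to anchor axis signs.
#' @return A `biplot_coordinates`: `scores` (microbes x axes),
#'   `loadings` (metabolites x axes), `proportion_explained`,
#'   `eigenvalues`.
#' @export
cooccurrence_biplot <- function(model, n_axes = 3, orient_by = NULL) {
  stopifnot(inherits(model, "cooccurrence_model"))
  if (!is.null(orient_by) && !orient_by %in% colnames(model$conditional)) {
    stop("unknown metabolite '", orient_by, "'")
  }
  L <- log(model$conditional)
  L <- sweep(L, 2, colMeans(L))
  if (all(abs(L) < 1e-12)) stop("degenerate conditional matrix: zero variance")
  sv <- svd(L)
  k <- min(n_axes, sum(sv$d > 1e-10 * sv$d[1]))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  anchor <- if (is.null(orient_by)) NULL else
    match(orient_by, colnames(model$conditional))
  for (j in seq_len(k)) {
    flip <- if (is.null(anchor)) {
      loadings[which.max(abs(loadings[, j])), j] < 0
    } else {
      loadings[anchor, j] < 0
    }
    if (flip) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(model$conditional),
                           paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(model$conditional),
                             paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 proportion_explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
                 eigenvalues = (sv$d^2)[seq_len(k)]),
            class = "biplot_coordinates")
}

#' Rank microbes by their probability of cooccurring with a metabolite
#'
#' @param model A fitted `cooccurrence_model`.
#' @param metabolite_id Target metabolite.
#' @param top_n How many microbes to return (default all).
#' @return Data frame with `feature`, `rank`, `conditional_prob`, sorted
#'   by descending conditional probability (ties by feature ID).
#' @export
rank_cooccurring_microbes <- function(model, metabolite_id, top_n = NULL) {
  stopifnot(inherits(model, "cooccurrence_model"))
  if (!metabolite_id %in% colnames(model$conditional)) {
    stop("unknown metabolite '", metabolite_id, "'")
  }
  p <- model$conditional[, metabolite_id]
  ids <- rownames(model$conditional)
  ord <- order(-p, ids)
  if (is.null(top_n)) top_n <- length(ord)
  if (top_n > length(ord)) stop("top_n exceeds the number of microbes")
  sel <- ord[seq_len(top_n)]
  data.frame(feature = ids[sel], rank = seq_len(top_n),
             conditional_prob = unname(p[sel]), stringsAsFactors = FALSE)
}

#' Correlate biplot axis-1 microbe scores with fitted differentials
#'
#' Pearson correlation between the microbes' first-axis biplot scores and
#' their differentials for a covariate, over the shared microbe set. A
#' strong correlation indicates that the cooccurrence structure is
#' organized along the same gradient as the group association.
#'
#' @param coords A `biplot_coordinates`.
#' @param ranks A `differential_ranks`.
#' @param covariate Covariate column of the differential matrix.
#' @param axis Which biplot axis to use (default 1).
#' @return List with `r`, `p`, `n`.
#' @export
axis_vs_differentials <- function(coords, ranks, covariate, axis = 1) {
  stopifnot(inherits(coords, "biplot_coordinates"),
            inherits(ranks, "differential_ranks"))
  if (!covariate %in% colnames(ranks$differentials)) {
    stop("unknown covariate '", covariate, "'")
  }
  shared <- intersect(rownames(coords$scores), rownames(ranks$differentials))
  if (length(shared) < 3) stop("need at least 3 shared microbes")
  x <- coords$scores[shared, axis]
  y <- ranks$differentials[shared, covariate]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}
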