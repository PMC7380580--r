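#' Configuration for the synthetic multi-omics cohort generator
#'
#' Bundles every knob of the generator into one validated object. The
#' defaults emulate the structure of a two-group fermented-food cohort
#' sampled weekly: two groups of subjects, up to four weekly time points
#' per subject, multinomial sequencing counts at lognormal library sizes,
#' a log-linear group effect on the latent composition, and a subject
#' random effect that decays geometrically between time points.
#'
#' @param n_subjects_per_group Subjects in each of the two groups.
#' @param n_timepoints Time points per subject (weekly samples).
#' @param n_microbes Number of microbial features.
#' @param n_metabolites Number of metabolite features (used by
#'   [simulate_metabolites()]).
#' @param effect_scale Standard deviation of the planted per-microbe group
#'   differential on the log-composition scale. `0` plants no effect.
#' @param library_size_log_mean,library_size_log_sd Meanlog and sdlog of the
#'   lognormal per-sample library size.
#' @param subject_stability Fraction of subject-level log-composition
#'   variance retained from one time point to the next, in `[0, 1]`.
#'   `1` keeps each subject's latent profile fixed; `0` redraws it fully.
#' @param subject_sd Standard deviation of the subject random effect on the
#'   log-composition scale.
#' @param timepoint_sd Standard deviation of the per-sample (time point)
#'   log-composition noise.
#' @param n_latent Shared latent dimensions coupling microbes and
#'   metabolites in [simulate_metabolites()].
#' @param latent_fraction Fraction of the subject-level variance carried
#'   by the shared latent factors (the remainder is microbe-independent
#'   noise), in `[0, 1]`. The shared factors are what couples microbial
#'   and metabolite variation.
#' @param transient_latent_sd Standard deviation of the transient
#'   (day-to-day, not carried forward) component of the shared latent
#'   state, emulating short-term influences such as diet. This is what
#'   keeps consecutive-time-point log-ratio correlations away from 1.
#' @param planted_metabolite_effect Log-intensity enrichment of the
#'   designated CLA-like metabolite in group 1.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A `simulation_config` list.
#' @seealso [simulate_cohort()], [simulate_metabolites()],
#'   [preset_16s()], [preset_metagenome()]
#' @export
simulation_config <- function(n_subjects_per_group = 50,
                              n_timepoints = 4,
                              n_microbes = 200,
                              n_metabolites = 100,
                              effect_scale = 1,
                              library_size_log_mean = log(5000),
                              library_size_log_sd = 0.5,
                              subject_stability = 0.9,
                              subject_sd = 1,
                              timepoint_sd = 0.3,
                              n_latent = 2,
                              latent_fraction = 0.75,
                              transient_latent_sd = 0.8,
                              planted_metabolite_effect = 2,
                              seed = 1) {
  counts <- c(n_subjects_per_group = n_subjects_per_group,
              n_timepoints = n_timepoints, n_microbes = n_microbes,
              n_metabolites = n_metabolites, n_latent = n_latent)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("all size parameters must be integers >= 1")
  }
  if (n_microbes < 2) stop("n_microbes must be at least 2")
  if (effect_scale < 0) stop("effect_scale must be >= 0")
  if (subject_stability < 0 || subject_stability > 1) {
    stop("subject_stability must lie in [0, 1]")
  }
  if (subject_sd < 0 || timepoint_sd < 0) stop("noise scales must be >= 0")
  if (latent_fraction < 0 || latent_fraction > 1) {
    stop("latent_fraction must lie in [0, 1]")
  }
  if (transient_latent_sd < 0) stop("noise scales must be >= 0")
  structure(list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_timepoints = as.integer(n_timepoints),
    n_microbes = as.integer(n_microbes),
    n_metabolites = as.integer(n_metabolites),
    effect_scale = effect_scale,
    library_size_log_mean = library_size_log_mean,
    library_size_log_sd = library_size_log_sd,
    subject_stability = subject_stability,
    subject_sd = subject_sd,
    timepoint_sd = timepoint_sd,
    n_latent = as.integer(n_latent),
    latent_fraction = latent_fraction,
    transient_latent_sd = transient_latent_sd,
    planted_metabolite_effect = planted_metabolite_effect,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Generator presets matching the two marker-gene feature-pool sizes
#'
#' `preset_16s()` uses a 3,100-feature pool (amplicon-like);
#' `preset_metagenome()` uses a 153-feature pool (genome-hit-like).
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `simulation_config`.
#' @export
preset_16s <- function(seed = 1, ...) {
  args <- list(n_microbes = 3100, seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(simulation_config, args)
}

#' @rdname preset_16s
#' @export
preset_metagenome <- function(seed = 1, ...) {
  args <- list(n_microbes = 153, seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(simulation_config, args)
}

#' Simulate a two-group longitudinal microbial count cohort
#'
#' Draws, per sample, a composition `softmax(base_logits + group * beta +
#' subject_effect + timepoint_noise)` and multinomial counts at a lognormal
#' library size. Base logits are drawn once per simulation from a normal
#' with standard deviation 2, giving the heavy-tailed abundance skew that
#' rank-based downstream methods expect. The planted group differential
#' `beta` is centered across microbes, so it lives on the same
#' centered-log-ratio scale as fitted differentials.
#'
#' The subject effect has a factor structure: a fraction
#' `latent_fraction` of its variance is carried by `n_latent` shared
#' latent factors through microbe loadings `U` (so microbes co-vary in a
#' low-dimensional way), the remainder is microbe-independent noise. The
#' same per-sample latent state drives the paired metabolite table in
#' [simulate_metabolites()], which is what plants recoverable
#' microbe-metabolite cooccurrence. Microbe loading magnitudes are
#' bounded away from zero so every microbe has an identifiable
#' cooccurrence profile, and the first loading dimension is signed by the
#' planted group differential, emulating the empirical coupling between
#' consumption-associated microbes and consumption-enriched metabolites.
#' Both the latent state and the independent part evolve as a stationary
#' AR(1) across time points:
#' `e_t = sqrt(s) * e_{t-1} + sqrt(1 - s) * fresh`, where
#' `s = subject_stability`.
#'
#' Metadata carries subject, time point, group, a fermented-plant
#' consumption frequency consistent with the group, and plausible
#' demographic covariates (age, BMI, height, weight, antibiotic use) so
#' that filtering rules can be exercised on generated cohorts.
#'
#' @param config A [simulation_config()].
#' @return A list of class `cohort_simulation` with elements
#'   \describe{
#'     \item{counts}{samples x microbes integer matrix.}
#'     \item{metadata}{per-sample data frame (`SampleID`, `subject`,
#'       `timepoint`, `group`, `fermented_plant_frequency`, demographics,
#'       `read_count`).}
#'     \item{truth}{planted ground truth: centered `beta_true`,
#'       `group_assignment` per subject, `base_logits`, the microbe
#'       loadings `microbe_latent`, the realized per-sample latent states
#'       `sample_latent`, and the config.}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_microbes < 2) stop("n_microbes must be at least 2")
  if (config$n_timepoints < 1) stop("n_timepoints must be at least 1")
  .with_seed(config$seed, {
    D <- config$n_microbes
    S <- 2L * config$n_subjects_per_group
    Tn <- config$n_timepoints
    microbes <- sprintf("mic_%04d", seq_len(D))
    subjects <- sprintf("S%03d", seq_len(S))
    group <- rep(c(0L, 1L), each = config$n_subjects_per_group)
    names(group) <- subjects

    base_logits <- stats::rnorm(D, 0, 2)
    beta <- stats::rnorm(D, 0, config$effect_scale)
    beta <- beta - mean(beta)
    names(beta) <- names(base_logits) <- microbes

    # Microbe loadings on the shared latent factors: magnitudes bounded
    # away from zero, first dimension signed by the planted differential
    # (random signs when no effect is planted).
    d_lat <- config$n_latent
    sign1 <- if (stats::sd(beta) > 0) {
      sign(beta + stats::rnorm(D, 0, 0.3 * stats::sd(beta)))
    } else {
      sample(c(-1, 1), D, replace = TRUE)
    }
    sign1[sign1 == 0] <- 1
    U <- matrix(stats::rnorm(D * d_lat, 0, 0.8), D, d_lat)
    U[, 1] <- sign1 * (1 + abs(stats::rnorm(D, 0, 0.5)))
    rownames(U) <- microbes
    u_scale <- sqrt(mean(rowSums(U^2)))
    w_lat <- config$latent_fraction

    # Consumption frequency consistent with group membership.
    freq_pool <- list(`0` = c("never", "rarely"),
                      `1` = c("occasionally", "regularly", "daily"))
    frequency <- vapply(as.character(group), function(g) {
      sample(freq_pool[[g]], 1L)
    }, character(1))

    age <- round(stats::runif(S, 25, 65))
    bmi <- round(stats::runif(S, 18.5, 32), 1)
    height <- round(stats::rnorm(S, 170, 9))
    weight <- round(bmi * (height / 100)^2, 1)

    n_samples <- S * Tn
    counts <- matrix(0L, n_samples, D,
                     dimnames = list(character(n_samples), microbes))
    meta <- vector("list", n_samples)
    latent <- matrix(0, n_samples, d_lat)
    k <- 0L
    tau <- config$transient_latent_sd
    z_norm <- sqrt(1 + tau^2)
    for (si in seq_len(S)) {
      h <- stats::rnorm(d_lat)                  # persistent latent state
      eps <- stats::rnorm(D)                    # independent part
      for (t in seq_len(Tn)) {
        if (t > 1L) {
          s <- config$subject_stability
          h <- sqrt(s) * h + sqrt(1 - s) * stats::rnorm(d_lat)
          eps <- sqrt(s) * eps + sqrt(1 - s) * stats::rnorm(D)
        }
        # Realized latent state = persistent subject state + transient
        # (day-to-day) fluctuation; normalized to unit marginal variance.
        z <- (h + tau * stats::rnorm(d_lat)) / z_norm
        subj_effect <- config$subject_sd *
          (sqrt(w_lat) * drop(U %*% z) / u_scale + sqrt(1 - w_lat) * eps)
        eta <- base_logits + group[si] * beta + subj_effect +
          stats::rnorm(D, 0, config$timepoint_sd)
        comp <- exp(eta - max(eta))
        comp <- comp / sum(comp)
        lib <- max(1, round(stats::rlnorm(1, config$library_size_log_mean,
                                          config$library_size_log_sd)))
        k <- k + 1L
        sample_id <- sprintf("%s.T%d", subjects[si], t)
        counts[k, ] <- as.integer(stats::rmultinom(1, lib, comp))
        rownames(counts)[k] <- sample_id
        latent[k, ] <- z
        meta[[k]] <- data.frame(
          SampleID = sample_id,
          subject = subjects[si],
          timepoint = t,
          group = group[si],
          fermented_plant_frequency = frequency[si],
          age_years = age[si],
          bmi = bmi[si],
          height_cm = height[si],
          weight_kg = weight[si],
          antibiotic_past_year = "No",
          stringsAsFactors = FALSE
        )
      }
    }
    metadata <- do.call(rbind, meta)
    metadata$read_count <- rowSums(counts)
    rownames(metadata) <- metadata$SampleID
    rownames(latent) <- metadata$SampleID
    structure(list(
      counts = counts,
      metadata = metadata,
      truth = list(beta_true = beta,
                   group_assignment = group,
                   base_logits = base_logits,
                   microbe_latent = U,
                   sample_latent = latent,
                   config = config)
    ), class = "cohort_simulation")
  })
}

#' @export
print.cohort_simulation <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples x %d microbes (%d subjects, %d time points)\n",
              nrow(x$counts), ncol(x$counts),
              length(x$truth$group_assignment),
              x$truth$config$n_timepoints))
  invisible(x)
}

#' Simulate a paired metabolite table with planted cooccurrence
#'
#' Given a simulated microbial cohort, draws a metabolite intensity table
#' coupled to the microbes through the cohort's shared latent factors:
#' each metabolite carries a loading vector `v`, and a sample's expected
#' log intensity of metabolite `j` is the sample's latent state dotted
#' with `v_j`, plus the planted group enrichment for the designated
#' CLA-like metabolite, plus multiplicative lognormal noise. Because the
#' same latent state shifts microbial log abundances through the microbe
#' loadings `U` (see [simulate_cohort()]), the matrix `U V'` is the
#' planted microbe-metabolite affinity: it is what a cooccurrence model
#' fitted on the two tables should recover. Intensities are scaled and
#' rounded to nonnegative integers so the table flows through the same
#' count-table machinery as microbial counts.
#'
#' The first metabolite, named `"CLA_like"`, is given a strong positive
#' first-axis loading (the axis whose microbe loadings are signed by the
#' planted group differential) and receives the planted group enrichment.
#'
#' @param cohort A `cohort_simulation` from [simulate_cohort()], or a
#'   samples x microbes count matrix (then `truth` must be supplied).
#' @param truth Planted truth list (defaults to `cohort$truth`).
#' @param config A [simulation_config()] (defaults to the cohort's).
#' @param noise_sd Lognormal noise standard deviation on the log-intensity
#'   scale.
#' @param intensity_scale Multiplier applied before rounding to integers.
#' @return A list of class `metabolite_simulation` with elements `counts`
#'   (samples x metabolites integer matrix), `cooccurrence_true`
#'   (microbes x metabolites latent affinity matrix `U V'`),
#'   `enriched_metabolite_id`, `microbe_latent`, `metabolite_latent`.
#' @export
simulate_metabolites <- function(cohort, truth = NULL, config = NULL,
                                 noise_sd = 0.5, intensity_scale = 1000) {
  if (inherits(cohort, "cohort_simulation")) {
    table <- cohort$counts
    if (is.null(truth)) truth <- cohort$truth
  } else {
    table <- cohort
  }
  if (is.null(truth)) stop("'truth' is required when 'cohort' is a matrix")
  if (is.null(config)) config <- truth$config
  .check_count_table(table)
  beta <- truth$beta_true
  if (!identical(colnames(table), names(beta))) {
    stop("count table features do not match the supplied truth")
  }
  subj <- sub("\\.T\\d+$", "", rownames(table))
  if (!all(subj %in% names(truth$group_assignment)) ||
      !all(rownames(table) %in% rownames(truth$sample_latent))) {
    stop("count table samples do not match the supplied truth")
  }
  .with_seed(config$seed + 1L, {
    M <- config$n_metabolites
    d <- config$n_latent
    metabolites <- c("CLA_like", sprintf("met_%04d", seq_len(M - 1L)))

    U <- truth$microbe_latent
    V <- matrix(stats::rnorm(M * d, 0, 1), M, d)
    V[1, 1] <- 1.5  # CLA-like metabolite loads on the group-linked axis
    rownames(V) <- metabolites

    z <- truth$sample_latent[rownames(table), , drop = FALSE]
    log_signal <- z %*% t(V)
    # Calibrate per-metabolite offsets so every metabolite has the same
    # average relative intensity: the planted affinity then shapes which
    # metabolites a microbe co-occurs with without confounding marginal
    # metabolite abundance. (Real tables have widely varying base levels;
    # the cooccurrence model absorbs those in its bias term.)
    offset <- numeric(M)
    for (it in 1:3) {
      I <- exp(log_signal + matrix(offset, nrow(z), M, byrow = TRUE))
      offset <- offset - log(colMeans(I / rowSums(I)) * M)
    }
    log_int <- log_signal + matrix(offset, nrow(z), M, byrow = TRUE)
    group <- truth$group_assignment[subj]
    log_int[, 1] <- log_int[, 1] + config$planted_metabolite_effect * group
    log_int <- log_int + matrix(stats::rnorm(length(log_int), 0, noise_sd),
                                nrow(log_int))
    intensities <- round(intensity_scale * exp(log_int))
    storage.mode(intensities) <- "integer"
    dimnames(intensities) <- list(rownames(table), metabolites)
    structure(list(
      counts = intensities,
      cooccurrence_true = U %*% t(V),
      enriched_metabolite_id = "CLA_like",
      microbe_latent = U,
      metabolite_latent = V
    ), class = "metabolite_simulation")
  })
}

#' @export
print.metabolite_simulation <- function(x, ...) {
  cat(sprintf("Synthetic metabolite table: %d samples x %d metabolites (enriched: %s)\n",
              nrow(x$counts), ncol(x$counts), x$enriched_metabolite_id))
  invisible(x)
}
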