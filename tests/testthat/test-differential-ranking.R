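test_that("a two-feature flip is ranked in the right direction", {
  # feature A is 9:1 in group 1 and 1:9 in group 0; the exact two-feature
  # logistic fit has a positive group coefficient for A, so its
  # differential must exceed B's
  counts <- toy_table(c(900, 100,
                        880, 120,
                        100, 900,
                        120, 880),
                      paste0("s", 1:4), c("A", "B"))
  meta <- data.frame(SampleID = paste0("s", 1:4),
                     group = c(1, 1, 0, 0))
  fit <- fit_differentials(counts, meta,
                           fast_spec(epochs = 800, min_sample_count = 0))
  d <- fit$differentials[, "group"]
  expect_gt(d["A"], d["B"])
  # oracle: exact logistic regression on the two-feature proportions
  glm_fit <- suppressWarnings(
    stats::glm(cbind(counts[, "A"], counts[, "B"]) ~ meta$group,
               family = stats::binomial()))
  expect_gt(stats::coef(glm_fit)[2], 0)
})

test_that("differentials are centered and deterministic given the seed", {
  cfg <- simulation_config(n_subjects_per_group = 15, n_timepoints = 1,
                           n_microbes = 40, effect_scale = 1, seed = 3)
  sim <- simulate_cohort(cfg)
  spec <- fast_spec(epochs = 400)
  f1 <- fit_differentials(sim$counts, sim$metadata, spec)
  f2 <- fit_differentials(sim$counts, sim$metadata, spec)
  expect_identical(f1$differentials, f2$differentials)
  sums <- colSums(f1$differentials)
  expect_true(all(abs(sums) < 1e-6))
})

test_that("differential rankings survive per-sample count rescaling", {
  # rescaling a sample leaves its composition unchanged; it only reweights
  # that sample in the likelihood, so rankings are stable rather than
  # bitwise identical
  cfg <- simulation_config(n_subjects_per_group = 30, n_timepoints = 1,
                           n_microbes = 60, effect_scale = 1, seed = 8)
  sim <- simulate_cohort(cfg)
  spec <- fast_spec(epochs = 3000, min_sample_count = 0)
  base <- fit_differentials(sim$counts, sim$metadata, spec)
  scaled <- sim$counts
  scaled[3, ] <- scaled[3, ] * 7
  scaled[10, ] <- scaled[10, ] * 3
  re <- fit_differentials(scaled, sim$metadata, spec)
  expect_gt(cor(base$differentials[, "group"], re$differentials[, "group"],
                method = "spearman"), 0.99)
})

test_that("pre-fit count gates are honored", {
  cfg <- simulation_config(n_subjects_per_group = 10, n_timepoints = 1,
                           n_microbes = 30, seed = 12)
  sim <- simulate_cohort(cfg)
  shallow <- rownames(sim$counts)[1]
  sim$counts[1, ] <- round(sim$counts[1, ] / sum(sim$counts[1, ]) * 500)
  fit <- fit_differentials(sim$counts, sim$metadata,
                           fast_spec(epochs = 50, min_sample_count = 1000))
  expect_false(shallow %in% fit$samples)
  expect_error(
    fit_differentials(sim$counts, sim$metadata,
                      fast_spec(epochs = 10, min_sample_count = 1e9)),
    "min_sample_count")
})

test_that("constant covariates and missing metadata are rejected", {
  cfg <- simulation_config(n_subjects_per_group = 5, n_timepoints = 1,
                           n_microbes = 10, seed = 2)
  sim <- simulate_cohort(cfg)
  meta <- sim$metadata
  meta$flat <- 1
  expect_error(fit_differentials(sim$counts, meta,
                                 fast_spec("flat", epochs = 10)), "constant")
  expect_error(fit_differentials(sim$counts, meta,
                                 fast_spec("nope", epochs = 10)), "nope")
  expect_error(fit_differentials(sim$counts, meta[-1, ],
                                 fast_spec(epochs = 10)), "metadata missing")
})

test_that("Q2 is near zero without signal and positive with it", {
  cfg0 <- simulation_config(n_subjects_per_group = 40, n_timepoints = 1,
                            n_microbes = 60, effect_scale = 0, seed = 14)
  sim0 <- simulate_cohort(cfg0)
  q0 <- evaluate_q2(sim0$counts, sim0$metadata,
                    fast_spec(epochs = 500, n_test_samples = 15, seed = 5))
  expect_lt(abs(q0$q2), 0.15)
  cfg1 <- simulation_config(n_subjects_per_group = 100, n_timepoints = 1,
                            n_microbes = 150, effect_scale = 1, seed = 7)
  sim1 <- simulate_cohort(cfg1)
  q1 <- evaluate_q2(sim1$counts, sim1$metadata,
                    fast_spec(epochs = 800, n_test_samples = 20, seed = 5))
  expect_gt(q1$q2, 0)
  expect_lte(q1$q2, 1)
  expect_error(
    evaluate_q2(sim0$counts, sim0$metadata,
                fast_spec(epochs = 10, n_test_samples = 0)),
    ">= 1 sample")
})

test_that("extreme-feature selection takes the k top and bottom ranks", {
  ranks <- structure(list(
    differentials = cbind(Intercept = rep(0, 5),
                          group = c(A = 2, B = 0, C = -1, D = 0.5, E = -0.2))),
    class = "differential_ranks")
  rownames(ranks$differentials) <- LETTERS[1:5]
  pair <- select_extreme_features(ranks, "group", k = 1)
  expect_identical(pair$numerator, "A")
  expect_identical(pair$denominator, "C")
  pair2 <- select_extreme_features(ranks, "group", k = 2)
  expect_identical(pair2$numerator, c("A", "D"))
  expect_identical(pair2$denominator, c("C", "E"))
  expect_error(select_extreme_features(ranks, "group", k = 3), "2 \\* k")
  # boundary ties resolve to the lexicographically smaller ID
  tied <- structure(list(
    differentials = cbind(group = c(b = 1, a = 1, d = -1, c = -1))),
    class = "differential_ranks")
  rownames(tied$differentials) <- c("b", "a", "d", "c")
  tp <- select_extreme_features(tied, "group", k = 1)
  expect_identical(tp$numerator, "a")
  expect_identical(tp$denominator, "c")
})

test_that("written differentials use the featureid layout", {
  cfg <- simulation_config(n_subjects_per_group = 5, n_timepoints = 1,
                           n_microbes = 12, seed = 4)
  sim <- simulate_cohort(cfg)
  fit <- fit_differentials(sim$counts, sim$metadata, fast_spec(epochs = 50))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_differentials(fit, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_identical(colnames(back), c("featureid", "Intercept", "group"))
  expect_equal(back$group, unname(fit$differentials[, "group"]))
})
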