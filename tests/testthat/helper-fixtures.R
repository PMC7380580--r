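# Shared fixtures: tiny hand-built tables and fast fit settings.

# Toy participant metadata covering each exclusion rule once.
toy_participants <- function() {
  data.frame(
    SampleID = sprintf("P%02d", 1:8),
    subject = sprintf("P%02d", 1:8),
    timepoint = 1L,
    age_years = c(30, 18, 30, 30, 30, 30, 30, NA),
    bmi = c(22, 22, 55, 22, 22, 22, 22, 22),
    height_cm = c(170, 170, 170, 220, 170, 170, 170, 170),
    weight_kg = c(70, 70, 70, 70, 250, 70, 70, 70),
    antibiotic_past_year = c("No", "No", "No", "No", "No", "Yes", "No", "No"),
    read_count = 5000,
    stringsAsFactors = FALSE
  )
}

# Small samples x features matrix with named dimensions.
toy_table <- function(values, samples, features) {
  matrix(values, nrow = length(samples), byrow = TRUE,
         dimnames = list(samples, features))
}

# Full-batch settings that converge quickly on desk-scale tables.
fast_spec <- function(covariates = "group", epochs = 1500, seed = 1, ...) {
  regression_spec(covariates = covariates, epochs = epochs,
                  batch_size = 100000, learning_rate = 0.02, seed = seed, ...)
}

# Per-sample group labels named by sample ID.
group_labels <- function(sim) {
  stats::setNames(sim$metadata$group, sim$metadata$SampleID)
}
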