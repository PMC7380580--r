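#' Cohort and count-table filtering criteria
#'
#' Collects the participant, sample, and feature filtering rules of the
#' workflow in one object. Demographic bounds follow the published rules
#' literally: participants are retained only with age strictly between 19
#' and 70 years, and excluded when BMI < 15 or > 50, height < 48 cm or
#' > 210 cm, weight < 2.5 kg or > 200 kg, or when antibiotics were taken
#' in the last year. Sample and feature rules: drop samples below
#' `min_reads` total counts, drop features with table-wide total below
#' `min_feature_total`, zero per-sample entries below
#' `min_relative_abundance` of the sample total, and drop features on an
#' explicit exclusion list (e.g. known bloom sequences).
#'
#' @param age_min,age_max Exclusive age bounds in years.
#' @param bmi_min,bmi_max BMI outlier bounds (kg/m^2); values strictly
#'   outside are excluded.
#' @param height_min,height_max Height outlier bounds (cm).
#' @param weight_min,weight_max Weight outlier bounds (kg).
#' @param exclude_antibiotics_last_year Drop participants flagged for
#'   antibiotic use in the last year.
#' @param min_reads Minimum per-sample total count.
#' @param rarefaction_depth Depth for [rarefy()].
#' @param min_feature_total Features whose table-wide total is below this
#'   are dropped.
#' @param min_relative_abundance Per-sample entries below this fraction of
#'   the sample total are zeroed (0 disables).
#' @param exclusion_list Character vector of feature IDs to drop.
#' @return A `filter_criteria` list.
#' @export
filter_criteria <- function(age_min = 19, age_max = 70,
                            bmi_min = 15, bmi_max = 50,
                            height_min = 48, height_max = 210,
                            weight_min = 2.5, weight_max = 200,
                            exclude_antibiotics_last_year = TRUE,
                            min_reads = 1500,
                            rarefaction_depth = 1500,
                            min_feature_total = 5,
                            min_relative_abundance = 0,
                            exclusion_list = character()) {
  stopifnot(age_min < age_max, bmi_min < bmi_max, height_min < height_max,
            weight_min < weight_max)
  if (min_relative_abundance < 0 || min_relative_abundance >= 1) {
    stop("min_relative_abundance must lie in [0, 1)")
  }
  structure(list(
    age_min = age_min, age_max = age_max,
    bmi_min = bmi_min, bmi_max = bmi_max,
    height_min = height_min, height_max = height_max,
    weight_min = weight_min, weight_max = weight_max,
    exclude_antibiotics_last_year = isTRUE(exclude_antibiotics_last_year),
    min_reads = min_reads,
    rarefaction_depth = rarefaction_depth,
    min_feature_total = min_feature_total,
    min_relative_abundance = min_relative_abundance,
    exclusion_list = as.character(exclusion_list)
  ), class = "filter_criteria")
}

#' Apply participant-level exclusion rules to sample metadata
#'
#' Removes rows with missing required fields, age outside the exclusive
#' (`age_min`, `age_max`) window, BMI/height/weight outside their outlier
#' bounds, or an antibiotic flag. An audit of per-rule exclusion counts
#' (applied sequentially, so counts sum to rows removed) is attached as
#' `attr(, "audit")`.
#'
#' @param meta Sample metadata with columns `age_years`, `bmi`,
#'   `height_cm`, `weight_kg`, `antibiotic_past_year`.
#' @param crit A [filter_criteria()].
#' @return The filtered metadata, with an `audit` attribute.
#' @export
filter_participants <- function(meta, crit = filter_criteria()) {
  required <- c("age_years", "bmi", "height_cm", "weight_kg",
                "antibiotic_past_year")
  missing_cols <- setdiff(required, colnames(meta))
  if (length(missing_cols) > 0) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  audit <- list()
  drop_rule <- function(meta, name, bad) {
    bad[is.na(bad)] <- FALSE
    audit[[name]] <<- sum(bad)
    meta[!bad, , drop = FALSE]
  }
  has_na <- Reduce(`|`, lapply(required, function(cl) {
    v <- meta[[cl]]
    is.na(v) | (is.character(v) & !nzchar(v))
  }))
  meta <- drop_rule(meta, "missing_required_field", has_na)
  meta <- drop_rule(meta, "age_out_of_bounds",
                    !(meta$age_years > crit$age_min &
                        meta$age_years < crit$age_max))
  meta <- drop_rule(meta, "bmi_outlier",
                    meta$bmi < crit$bmi_min | meta$bmi > crit$bmi_max)
  meta <- drop_rule(meta, "height_outlier",
                    meta$height_cm < crit$height_min |
                      meta$height_cm > crit$height_max)
  meta <- drop_rule(meta, "weight_outlier",
                    meta$weight_kg < crit$weight_min |
                      meta$weight_kg > crit$weight_max)
  if (crit$exclude_antibiotics_last_year) {
    flag <- meta$antibiotic_past_year
    bad <- if (is.logical(flag)) flag else
      tolower(as.character(flag)) %in% c("yes", "true", "1")
    meta <- drop_rule(meta, "antibiotics_last_year", bad)
  }
  attr(meta, "audit") <- data.frame(rule = names(audit),
                                    n_excluded = unlist(audit, use.names = FALSE))
  meta
}

#' Keep one sample per (subject, time point), preferring higher read count
#'
#' When biological replicates are present the replicate with the lower
#' read count is removed; read-count ties are broken by keeping the
#' lexicographically smallest sample ID.
#'
#' @param meta Sample metadata with `subject`, `timepoint`, `read_count`,
#'   and `SampleID` columns.
#' @return Deduplicated metadata.
#' @export
dedup_replicates <- function(meta) {
  required <- c("subject", "timepoint", "read_count", "SampleID")
  missing_cols <- setdiff(required, colnames(meta))
  if (length(missing_cols) > 0) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ord <- order(meta$subject, meta$timepoint, -meta$read_count,
               as.character(meta$SampleID))
  meta <- meta[ord, , drop = FALSE]
  keep <- !duplicated(meta[, c("subject", "timepoint")])
  meta[keep, , drop = FALSE]
}

#' Label samples as fermented-food consumers or nonconsumers
#'
#' Consumers report eating fermented plants "occasionally" (1 to 2
#' times/week), "regularly" (3 to 5 times/week), or "daily"; nonconsumers
#' report "rarely" (less than once/week) or "never". Anything else
#' (including missing values) becomes `"unknown"` and should be excluded
#' downstream.
#'
#' @param meta Sample metadata.
#' @param column Name of the consumption-frequency column.
#' @return `meta` with an appended `consumption_label` column.
#' @export
classify_consumption <- function(meta, column = "fermented_plant_frequency") {
  if (!column %in% colnames(meta)) {
    stop("metadata is missing required column(s): ", column)
  }
  freq <- tolower(trimws(as.character(meta[[column]])))
  label <- rep("unknown", nrow(meta))
  label[freq %in% c("occasionally", "regularly", "daily")] <- "consumer"
  label[freq %in% c("never", "rarely")] <- "nonconsumer"
  meta$consumption_label <- label
  meta
}

#' Filter a count table by exclusion list, sample depth, and feature totals
#'
#' Applies, in this fixed order: (1) drop exclusion-list features; (2) drop
#' samples whose total count is below `min_reads`; (3) if
#' `min_relative_abundance > 0`, zero per-sample entries below that
#' fraction of the sample total; (4) drop features whose table-wide total
#' is below `min_feature_total`.
#'
#' @param table Samples x features count matrix.
#' @param crit A [filter_criteria()].
#' @return The filtered count matrix.
#' @export
filter_table <- function(table, crit = filter_criteria()) {
  .check_count_table(table)
  drop <- intersect(colnames(table), crit$exclusion_list)
  if (length(drop) > 0) {
    table <- table[, setdiff(colnames(table), drop), drop = FALSE]
  }
  table <- table[rowSums(table) >= crit$min_reads, , drop = FALSE]
  if (nrow(table) == 0) stop("no samples left after the min_reads filter")
  if (crit$min_relative_abundance > 0) {
    totals <- rowSums(table)
    rel <- table / ifelse(totals > 0, totals, 1)
    table[rel < crit$min_relative_abundance] <- 0
  }
  table <- table[, colSums(table) >= crit$min_feature_total, drop = FALSE]
  if (ncol(table) == 0) stop("no features left after the feature-total filter")
  table
}

#' Rarefy a count table to a fixed depth
#'
#' Samples with fewer than `depth` total counts are dropped; the rest are
#' subsampled without replacement to exactly `depth` counts
#' (via [vegan::rrarefy()]). Deterministic given `seed`.
#'
#' @param table Samples x features count matrix.
#' @param depth Target depth (>= 1).
#' @param seed Integer seed.
#' @return The rarefied count matrix; every row sums to `depth`.
#' @export
rarefy <- function(table, depth = 1500, seed = 1) {
  .check_count_table(table)
  if (depth < 1) stop("depth must be >= 1")
  keep <- rowSums(table) >= depth
  if (!any(keep)) stop("no samples reach the rarefaction depth")
  table <- table[keep, , drop = FALSE]
  .with_seed(seed, {
    # vegan warns whenever the smallest nonzero entry exceeds 1, which is
    # routine for genuine count tables; muffle only that message
    out <- withCallingHandlers(
      vegan::rrarefy(table, depth),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  })
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(table)
  out
}
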