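# Readers and writers for the plain-text interchange formats used across
# the workflow: dense TSV count tables (samples as rows, features as
# columns), QIIME2-dialect metadata with a leading "#SampleID" column,
# two-column feature-set files, differential tables, exclusion lists, and
# (optionally, via biomformat) BIOM tables.

#' Read / write a dense TSV count table
#'
#' Samples are rows, features are columns; the first column holds sample
#' identifiers.
#'
#' @param path File path.
#' @return `read_count_table()`: an integer samples x features matrix.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "numeric"
  .check_count_table(m)
  m
}

#' @rdname read_count_table
#' @param table Samples x features count matrix.
#' @export
write_count_table <- function(table, path) {
  .check_count_table(table)
  df <- data.frame(sample_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write QIIME2-dialect sample metadata
#'
#' TSV with a leading `#SampleID` column; on read that column is renamed
#' `SampleID` and copied to the row names.
#'
#' @param path File path.
#' @return `read_sample_metadata()`: a data frame keyed by `SampleID`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  if (colnames(df)[1] != "#SampleID" && colnames(df)[1] != "SampleID") {
    stop("metadata must start with a '#SampleID' column")
  }
  colnames(df)[1] <- "SampleID"
  rownames(df) <- df$SampleID
  df
}

#' @rdname read_sample_metadata
#' @param meta Metadata data frame with a `SampleID` column.
#' @export
write_sample_metadata <- function(meta, path) {
  if (!"SampleID" %in% colnames(meta)) stop("metadata needs a SampleID column")
  out <- meta
  colnames(out)[colnames(out) == "SampleID"] <- "#SampleID"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a feature-set pair as a two-column TSV
#'
#' Columns `feature_id` and `set` (values `numerator` / `denominator`).
#'
#' @param path File path.
#' @return `read_feature_sets()`: a [feature_set_pair()].
#' @export
read_feature_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("feature_id", "set") %in% colnames(df))) {
    stop("feature-set file needs 'feature_id' and 'set' columns")
  }
  feature_set_pair(df$feature_id[df$set == "numerator"],
                   df$feature_id[df$set == "denominator"])
}

#' @rdname read_feature_sets
#' @param pair A [feature_set_pair()].
#' @export
write_feature_sets <- function(pair, path) {
  stopifnot(inherits(pair, "feature_set_pair"))
  df <- data.frame(
    feature_id = c(pair$numerator, pair$denominator),
    set = rep(c("numerator", "denominator"),
              c(length(pair$numerator), length(pair$denominator))),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature exclusion list (one ID per line)
#'
#' Blank lines and lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return Character vector of feature IDs.
#' @export
read_exclusion_list <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Write fitted differentials in the conventional ranking layout
#'
#' TSV with a `featureid` column followed by one column per covariate
#' (including `Intercept`), so existing rank visualizers can consume it.
#'
#' @param ranks A `differential_ranks` object.
#' @param path File path.
#' @export
write_differentials <- function(ranks, path) {
  stopifnot(inherits(ranks, "differential_ranks"))
  df <- data.frame(featureid = rownames(ranks$differentials),
                   ranks$differentials, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a count table in BIOM format
#'
#' Requires the `biomformat` package. BIOM stores features as rows; these
#' helpers transpose to and from the samples x features orientation used
#' throughout.
#'
#' @param path File path.
#' @return `read_biom_table()`: a samples x features matrix.
#' @export
read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("BIOM support requires the 'biomformat' package")
  }
  b <- biomformat::read_biom(path)
  m <- t(as.matrix(biomformat::biom_data(b)))
  .check_count_table(m)
  m
}

#' @rdname read_biom_table
#' @param table Samples x features count matrix.
#' @export
write_biom_table <- function(table, path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("BIOM support requires the 'biomformat' package")
  }
  .check_count_table(table)
  b <- biomformat::make_biom(t(table))
  biomformat::write_biom(b, path)
  invisible(path)
}

#' Write biplot coordinates as an ordination text file
#'
#' Plain-text ordination layout with `Eigvals`, `Proportion explained`,
#' `Species` (metabolite loadings), and `Site` (microbe scores) blocks.
#'
#' @param coords A `biplot_coordinates`.
#' @param path File path.
#' @export
write_ordination <- function(coords, path) {
  stopifnot(inherits(coords, "biplot_coordinates"))
  k <- ncol(coords$scores)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("Eigvals\t%d", k), con)
  writeLines(paste(signif(coords$eigenvalues, 10), collapse = "\t"), con)
  writeLines("", con)
  writeLines(sprintf("Proportion explained\t%d", k), con)
  writeLines(paste(signif(coords$proportion_explained, 10), collapse = "\t"),
             con)
  writeLines("", con)
  writeLines(sprintf("Species\t%d\t%d", nrow(coords$loadings), k), con)
  utils::write.table(coords$loadings, con, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  writeLines("", con)
  writeLines(sprintf("Site\t%d\t%d", nrow(coords$scores), k), con)
  utils::write.table(coords$scores, con, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(path)
}
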