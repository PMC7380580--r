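# Internal helpers shared across modules.

# Row-wise softmax with the usual max-shift for numerical stability.
.softmax_rows <- function(eta) {
  m <- apply(eta, 1L, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

# Validate a samples x features count table: numeric matrix, nonnegative,
# finite, with sample and feature identifiers.
.check_count_table <- function(x, arg = "table") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric samples x features matrix", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(sprintf("'%s' must carry sample (row) and feature (column) names", arg))
  }
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("'%s' must contain finite nonnegative counts", arg))
  }
  invisible(x)
}

# Resolve a per-sample grouping for the rows of `table`. Accepts a vector
# named by sample ID, an unnamed vector of matching length, or a metadata
# column name together with a metadata data frame.
.align_groups <- function(groups, table) {
  samples <- rownames(table)
  if (!is.null(names(groups))) {
    missing <- setdiff(samples, names(groups))
    if (length(missing) > 0) {
      stop("group labels missing for samples: ", paste(missing, collapse = ", "))
    }
    groups <- groups[samples]
  } else if (length(groups) != nrow(table)) {
    stop("'groups' must be named by sample or match nrow(table)")
  }
  factor(groups)
}

# Metadata lookup keyed on the sample identifier column (or row names).
.meta_by_sample <- function(meta, id_col = "SampleID") {
  if (id_col %in% colnames(meta)) {
    ids <- as.character(meta[[id_col]])
  } else if (!is.null(rownames(meta))) {
    ids <- rownames(meta)
  } else {
    stop(sprintf("metadata must have a '%s' column or row names", id_col))
  }
  if (anyDuplicated(ids)) stop("duplicate sample identifiers in metadata")
  rownames(meta) <- ids
  meta
}

# Evaluate a block with a private RNG stream, restoring the caller's state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
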