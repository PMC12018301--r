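# Labeled dataset container shared by the classifier, the elimination
# wrapper and the synthetic generators.

#' Construct a labeled dataset
#'
#' A thin container holding a samples-by-features numeric matrix with one
#' class label per sample. Feature columns keep their original indices
#' (0-based `positions`) so that encodings of feature subsets stay consistent
#' across elimination rounds.
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param labels Character (or factor) vector of class labels, one per row.
#' @param feature_names Optional feature identifiers; defaults to column
#'   names, then `"feature_<j>"`.
#' @param sample_ids Optional sample identifiers; defaults to row names, then
#'   `"sample_<i>"`.
#' @return An object of class `labeled_dataset` with fields `values`,
#'   `labels`, `feature_names`, `sample_ids` and `positions` (0-based
#'   original column index per feature).
#' @export
labeled_dataset <- function(values, labels, feature_names = NULL,
                            sample_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_hd("`values` must be a numeric matrix")
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) {
    stop_hd("`labels` must have one entry per sample (row)")
  }
  if (anyNA(labels)) stop_hd("class labels must not be missing")
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) {
      feature_names <- sprintf("feature_%d", seq_len(ncol(values)))
    }
  }
  if (length(feature_names) != ncol(values)) {
    stop_hd("`feature_names` must have one entry per feature (column)")
  }
  if (anyDuplicated(feature_names)) stop_hd("feature names must be unique")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) {
      sample_ids <- sprintf("sample_%d", seq_len(nrow(values)))
    }
  }
  if (length(sample_ids) != nrow(values)) {
    stop_hd("`sample_ids` must have one entry per sample")
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(
    list(values = values,
         labels = labels,
         feature_names = as.character(feature_names),
         sample_ids = as.character(sample_ids),
         positions = seq_len(ncol(values)) - 1L),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled dataset:", nrow(x$values), "samples x",
      ncol(x$values), "features\n")
  tab <- table(x$labels)
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  invisible(x)
}

# Restrict a labeled_dataset to a subset of features, keeping the original
# 0-based positions of the retained columns.
subset_features <- function(dataset, features) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  keep <- match(features, dataset$feature_names)
  if (anyNA(keep)) {
    stop_hd("unknown feature(s): ",
            paste(features[is.na(keep)], collapse = ", "))
  }
  out <- dataset
  out$values <- dataset$values[, keep, drop = FALSE]
  out$feature_names <- dataset$feature_names[keep]
  out$positions <- dataset$positions[keep]
  out
}
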