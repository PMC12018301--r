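# The hyperdimensional classifier: per-class bundled vectors, retraining
# (error mitigation), cosine-similarity prediction, and stratified k-fold
# cross-validation.

#' Fit class hypervectors
#'
#' Builds one integer class vector per class as the element-wise sum (bundle)
#' of the encoded training samples belonging to that class.
#'
#' @param encodings Numeric matrix of encoded samples, one sample per row
#'   (see [encode_sample()]).
#' @param labels Class label per sample.
#' @param class_labels Optional explicit class order; defaults to order of
#'   first appearance in `labels`. Prediction ties resolve to the earlier
#'   class in this order.
#' @return An object of class `hd_model` with fields `class_labels`,
#'   `class_vectors` (classes x d matrix), `d` and
#'   `retrain_iterations_used` (0 until [hd_retrain()] is applied).
#' @export
hd_fit <- function(encodings, labels, class_labels = NULL) {
  encodings <- as.matrix(encodings)
  labels <- as.character(labels)
  if (nrow(encodings) == 0) stop_hd("empty training set")
  if (length(labels) != nrow(encodings)) {
    stop_hd("one label per encoded sample required")
  }
  if (is.null(class_labels)) {
    class_labels <- unique(labels)
  } else if (!all(labels %in% class_labels)) {
    stop_hd("labels contain classes absent from `class_labels`")
  }
  f <- factor(labels, levels = class_labels)
  present <- class_labels[class_labels %in% labels]
  cv <- rowsum(encodings, f)  # rows ordered by factor levels, absent dropped
  cv <- cv[match(present, rownames(cv)), , drop = FALSE]
  structure(
    list(class_labels = present,
         class_vectors = cv,
         d = ncol(encodings),
         retrain_iterations_used = 0L),
    class = "hd_model"
  )
}

#' @export
print.hd_model <- function(x, ...) {
  cat("Hyperdimensional classification model\n")
  cat("  d:", x$d, " classes:", paste(x$class_labels, collapse = ", "), "\n")
  cat("  retraining passes used:", x$retrain_iterations_used, "\n")
  invisible(x)
}

#' Predict classes by cosine similarity
#'
#' Each encoded sample is assigned the label of the class vector with the
#' highest cosine similarity; exact ties resolve deterministically to the
#' first class in `model$class_labels`.
#'
#' @param model An [hd_fit()] model.
#' @param encodings A single encoded vector or a matrix with one encoded
#'   sample per row.
#' @return Character vector of predicted labels.
#' @export
hd_predict <- function(model, encodings) {
  stopifnot(inherits(model, "hd_model"))
  if (length(model$class_labels) == 0) stop_hd("model has no classes")
  if (is.null(dim(encodings))) encodings <- matrix(encodings, nrow = 1)
  if (ncol(encodings) != model$d) {
    stop_hd("encoded samples have dimension ", ncol(encodings),
            " but the model expects ", model$d)
  }
  idx <- hd_predict_cpp(t(encodings), t(model$class_vectors))
  model$class_labels[idx + 1L]
}

#' Retrain a model to mitigate bundling noise
#'
#' Performs up to `R` passes over the training samples in dataset order.
#' Within a pass, every misclassified sample's vector is subtracted from the
#' wrongly predicted class vector and added to its true class vector (so the
#' element-wise sum of all class vectors is invariant). The training error is
#' counted by a full evaluation before the first pass and after each pass;
#' passes stop as soon as the count equals the previous count, or after `R`
#' passes.
#'
#' @param model An [hd_fit()] model.
#' @param encodings Training encodings used to fit the model (samples in
#'   rows, in the same order).
#' @param labels True class per training sample.
#' @param R Maximum number of retraining passes (default 10).
#' @return The updated `hd_model`, with `retrain_iterations_used`,
#'   `final_training_errors` and the integer `error_history` (initial count
#'   followed by one count per pass).
#' @export
hd_retrain <- function(model, encodings, labels, R = 10) {
  stopifnot(inherits(model, "hd_model"))
  if (!is.numeric(R) || length(R) != 1 || R < 0) {
    stop_hd("`R` must be a non-negative integer")
  }
  encodings <- as.matrix(encodings)
  labels <- as.character(labels)
  lab_idx <- match(labels, model$class_labels) - 1L
  if (anyNA(lab_idx)) stop_hd("labels contain classes unknown to the model")
  res <- hd_retrain_cpp(t(encodings), lab_idx, t(model$class_vectors),
                        as.integer(R))
  out <- model
  cv <- t(res$class_vectors_t)
  rownames(cv) <- model$class_labels
  out$class_vectors <- cv
  out$retrain_iterations_used <- res$iterations
  out$final_training_errors <- res$final_errors
  out$error_history <- res$error_history
  out
}

#' Evaluate a model on labeled encodings
#'
#' @param model An `hd_model`.
#' @param encodings Encoded test samples (rows).
#' @param labels True class per test sample.
#' @return A list with `accuracy` (fraction correct), the truth-by-prediction
#'   `confusion` count matrix, a `per_class` data frame with one-vs-rest
#'   precision, recall and F1 (zero-denominator ratios reported as 0 with the
#'   corresponding `undefined` flag set), and `n`, the number of evaluated
#'   samples.
#' @export
hd_evaluate <- function(model, encodings, labels) {
  stopifnot(inherits(model, "hd_model"))
  if (is.null(dim(encodings))) encodings <- matrix(encodings, nrow = 1)
  if (nrow(encodings) == 0) stop_hd("empty test set")
  labels <- as.character(labels)
  if (length(labels) != nrow(encodings)) {
    stop_hd("one label per encoded sample required")
  }
  if (!all(labels %in% model$class_labels)) {
    stop_hd("test labels contain classes unknown to the model")
  }
  pred <- hd_predict(model, encodings)
  cl <- model$class_labels
  confusion <- table(factor(labels, levels = cl),
                     factor(pred, levels = cl))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("truth", "predicted")
  n <- sum(confusion)
  acc <- sum(diag(confusion)) / n
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  per_class <- data.frame(
    class = cl,
    precision = as.numeric(precision),
    recall = as.numeric(recall),
    f1 = as.numeric(f1),
    precision_undefined = as.vector(tp + fp == 0),
    recall_undefined = as.vector(tp + fn == 0),
    f1_undefined = as.vector(precision + recall == 0),
    row.names = NULL
  )
  list(accuracy = acc, confusion = confusion, per_class = per_class, n = n)
}

#' Build a class-stratified fold plan
#'
#' Partitions the samples into `k` disjoint test sets after a seeded shuffle
#' within each class, so every fold's per-class counts are within one sample
#' of the proportional share. The plan depends only on `(labels, k, seed)`,
#' which keeps it identical across candidate feature subsets within one
#' selection run.
#'
#' @param labels Class label per sample.
#' @param k Number of folds (>= 2).
#' @param seed Optional seed for the within-class shuffle.
#' @return An object of class `fold_plan`: list with `k`, `seed` and
#'   `test_indices`, a list of `k` integer index vectors.
#' @export
make_folds <- function(labels, k = 5, seed = NULL) {
  labels <- as.character(labels)
  if (!is_count(k, min = 2)) stop_hd("`k` must be an integer >= 2")
  counts <- table(labels)
  if (any(counts < k)) {
    bad <- names(counts)[counts < k]
    stop_hd("every class needs at least k = ", k, " samples for ",
            "stratified folds; too small: ", paste(bad, collapse = ", "))
  }
  assignment <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      # chunk sizes differ by at most one
      sizes <- rep(length(idx) %/% k, k)
      extra <- length(idx) %% k
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      assignment[idx] <- rep(seq_len(k), times = sizes)
    }
  })
  structure(
    list(k = as.integer(k), seed = seed,
         test_indices = lapply(seq_len(k), function(f) which(assignment == f))),
    class = "fold_plan"
  )
}

#' Default classifier configuration
#'
#' Bundles the hyperparameters of the classifier and the elimination wrapper:
#' dimensionality `d` (default 10000), number of levels `L` (1000 for
#' relative-abundance values; use 2 for presence/absence data), maximum
#' retraining passes `R` (10), folds `k` (5), the selection accuracy
#' threshold `T` and accuracy-uncertainty percentage `u` (60 and 1, both in
#' percent), and the run `seed`.
#'
#' @param d,L,R,k,T,u,seed See description.
#' @return A list of class `hd_config`.
#' @export
hd_config <- function(d = 10000, L = 1000, R = 10, k = 5, T = 60, u = 1,
                      seed = NULL) {
  if (!is_count(d)) stop_hd("`d` must be a positive integer")
  if (!is_count(L)) stop_hd("`L` must be a positive integer")
  if (!is.numeric(R) || R < 0) stop_hd("`R` must be >= 0")
  if (!is_count(k, min = 2)) stop_hd("`k` must be an integer >= 2")
  if (!is.numeric(T) || T < 0 || T > 100) stop_hd("`T` must be in [0, 100]")
  if (!is.numeric(u) || u < 0 || u > 100) stop_hd("`u` must be in [0, 100]")
  structure(list(d = as.integer(d), L = as.integer(L), R = as.integer(R),
                 k = as.integer(k), T = T, u = u, seed = seed),
            class = "hd_config")
}

#' Cross-validate the hyperdimensional classifier
#'
#' For each fold of a class-stratified plan: the quantization range is fitted
#' on the training portion only (global min/max over all its values), samples
#' are encoded against a level family shared across folds, class vectors are
#' fitted and retrained, and the held-out portion is evaluated.
#'
#' @param dataset A [labeled_dataset()].
#' @param config An [hd_config()]; its `seed` drives both the level family
#'   and the fold plan.
#' @param folds Optional pre-built [make_folds()] plan (must match the
#'   dataset's samples).
#' @param levels Optional pre-built [generate_levels()] family with matching
#'   `d` and `L`.
#' @return A list with `fold_plan`, per-fold `reports` (see
#'   [hd_evaluate()]), `fold_accuracies`, `mean_accuracy` (arithmetic mean of
#'   fold accuracies, in \[0, 1\]), `retrain_iterations` per fold and
#'   `mean_retrain_iterations`.
#' @export
hd_cross_validate <- function(dataset, config = hd_config(), folds = NULL,
                              levels = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  stopifnot(inherits(config, "hd_config"))
  if (is.null(levels)) {
    levels <- generate_levels(config$d, config$L,
                              seed = derive_seed(config$seed, 1L))
  }
  if (levels$d != config$d || levels$L != config$L) {
    stop_hd("level family does not match the configuration (d, L)")
  }
  if (is.null(folds)) {
    folds <- make_folds(dataset$labels, k = config$k,
                        seed = derive_seed(config$seed, 2L))
  }
  class_labels <- unique(dataset$labels)
  reports <- vector("list", folds$k)
  iters <- numeric(folds$k)
  for (f in seq_len(folds$k)) {
    test_idx <- folds$test_indices[[f]]
    train_idx <- setdiff(seq_along(dataset$labels), test_idx)
    train_vals <- dataset$values[train_idx, , drop = FALSE]
    scheme <- scheme_from_training(train_vals, config$L)
    enc_train <- encode_matrix(train_vals, dataset$positions, levels, scheme)
    enc_test <- encode_matrix(dataset$values[test_idx, , drop = FALSE],
                              dataset$positions, levels, scheme)
    model <- hd_fit(enc_train, dataset$labels[train_idx], class_labels)
    model <- hd_retrain(model, enc_train, dataset$labels[train_idx],
                        R = config$R)
    reports[[f]] <- hd_evaluate(model, enc_test, dataset$labels[test_idx])
    iters[f] <- model$retrain_iterations_used
  }
  accs <- vapply(reports, function(r) r$accuracy, numeric(1))
  list(fold_plan = folds,
       reports = reports,
       fold_accuracies = accs,
       mean_accuracy = mean(accs),
       retrain_iterations = iters,
       mean_retrain_iterations = mean(iters))
}

# Quantization range = global min/max over the training values (one scheme
# per dataset, not per feature). A degenerate range maps everything to level 0.
scheme_from_training <- function(train_values, L) {
  if (length(train_values) == 0) {
    return(quantization_scheme(0, 0, L))
  }
  quantization_scheme(min(train_values), max(train_values), L)
}
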