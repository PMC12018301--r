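# Stepwise backward variable elimination over hyperdimensional models:
# candidate leave-one-out subsets per iteration, band-based multi-feature
# removal, a stop rule on accuracy decrease, and the frontier of compact
# suboptimal models.

#' Model-acceptance cutoff for an elimination iteration
#'
#' The cutoff is the iteration's best accuracy minus its `u` percent
#' (relative): `best * (1 - u / 100)`. Comparisons use the exact value;
#' [cutoff_display()] floors it to an integer percent for reporting.
#'
#' @param best_accuracy Best candidate accuracy of the iteration, in percent.
#' @param u Accuracy-uncertainty percentage in \[0, 100\].
#' @return The exact cutoff in percent.
#' @examples
#' acceptance_cutoff(93, 5)   # 88.35, displayed as 88
#' cutoff_display(acceptance_cutoff(90, 5))  # 85
#' @export
acceptance_cutoff <- function(best_accuracy, u) {
  if (!is.numeric(best_accuracy) || any(best_accuracy < 0 | best_accuracy > 100)) {
    stop_hd("`best_accuracy` must be in [0, 100]")
  }
  if (!is.numeric(u) || any(u < 0 | u > 100)) {
    stop_hd("`u` must be in [0, 100]")
  }
  best_accuracy * (1 - u / 100)
}

#' @rdname acceptance_cutoff
#' @param cutoff A cutoff in percent.
#' @export
cutoff_display <- function(cutoff) {
  as.integer(floor(cutoff))
}

#' Cross-validated evaluator for feature subsets
#'
#' Builds the default evaluator used by [backward_eliminate()]: a function
#' mapping a character vector of retained feature names to the mean k-fold
#' cross-validated accuracy (in percent) of the hyperdimensional classifier
#' restricted to those features. The fold plan, the level family and the
#' per-fold quantization schemes are all fixed once from the full dataset, so
#' every candidate subset is scored under identical conditions and whole-run
#' results are a pure function of the seed.
#'
#' Feature positions are the original column indices, so a subset's encoding
#' equals the full encoding minus the removed features' rotated level
#' vectors; the evaluator exploits this to score leave-one-out candidates
#' incrementally. `attr(evaluator, "commit")` re-bases the cache on the
#' currently accepted subset between iterations.
#'
#' @param dataset A [labeled_dataset()].
#' @param config An [hd_config()].
#' @param positions `"original"` (default) keeps each feature's full-dataset
#'   column index as its rotation, enabling the incremental subset scoring;
#'   `"relative"` renumbers the retained features 0, 1, ... within each
#'   candidate subset (every candidate is then encoded from scratch).
#' @return A function `f(features)` returning a list with `mean_accuracy`
#'   (percent), `fold_accuracies` (percent) and `mean_retrain_iterations`.
#' @export
hd_cv_evaluator <- function(dataset, config = hd_config(),
                            positions = c("original", "relative")) {
  position_mode <- match.arg(positions)
  stopifnot(inherits(dataset, "labeled_dataset"))
  stopifnot(inherits(config, "hd_config"))
  levels <- generate_levels(config$d, config$L,
                            seed = derive_seed(config$seed, 1L))
  folds <- make_folds(dataset$labels, k = config$k,
                      seed = derive_seed(config$seed, 2L))
  labels <- dataset$labels
  class_labels <- unique(labels)
  n <- length(labels)
  all_features <- dataset$feature_names
  positions <- dataset$positions
  names(positions) <- all_features

  # one quantization scheme per fold, fitted on that fold's training rows
  # over the full feature set; folds sharing a scheme share encodings
  schemes <- lapply(folds$test_indices, function(test_idx) {
    train_vals <- dataset$values[-test_idx, , drop = FALSE]
    scheme_from_training(train_vals, config$L)
  })
  scheme_key <- vapply(schemes, function(s) {
    paste(s$value_min, s$value_max)
  }, character(1))
  group_of_fold <- match(scheme_key, unique(scheme_key))
  groups <- lapply(unique(group_of_fold), function(g) {
    scheme <- schemes[[which(group_of_fold == g)[1]]]
    idx <- matrix(value_to_level(as.numeric(dataset$values), scheme),
                  nrow = n, ncol = length(all_features))
    colnames(idx) <- all_features
    list(scheme = scheme, idx = idx)
  })

  encode_full <- function(features) {
    lapply(groups, function(g) {
      E <- matrix(0, nrow = n, ncol = config$d)
      pos <- if (position_mode == "original") {
        positions[features]
      } else {
        seq_along(features) - 1L
      }
      for (i in seq_along(features)) {
        E <- E + feature_contribution(g$idx[, features[i]], pos[[i]], levels)
      }
      E
    })
  }

  cache <- new.env(parent = emptyenv())
  cache$features <- all_features
  cache$E <- encode_full(all_features)

  encodings_for <- function(features) {
    if (position_mode == "relative" || !all(features %in% cache$features)) {
      return(encode_full(features))
    }
    removed <- setdiff(cache$features, features)
    E <- cache$E
    if (length(removed)) {
      for (gi in seq_along(groups)) {
        g <- groups[[gi]]
        for (f in removed) {
          E[[gi]] <- E[[gi]] -
            feature_contribution(g$idx[, f], positions[[f]], levels)
        }
      }
    }
    E
  }

  evaluator <- function(features) {
    features <- as.character(features)
    if (!all(features %in% all_features)) {
      stop_hd("evaluator called with unknown feature(s)")
    }
    E <- encodings_for(features)
    accs <- numeric(folds$k)
    iters <- numeric(folds$k)
    for (f in seq_len(folds$k)) {
      test_idx <- folds$test_indices[[f]]
      train_idx <- setdiff(seq_len(n), test_idx)
      Eg <- E[[group_of_fold[f]]]
      model <- hd_fit(Eg[train_idx, , drop = FALSE], labels[train_idx],
                      class_labels)
      model <- hd_retrain(model, Eg[train_idx, , drop = FALSE],
                          labels[train_idx], R = config$R)
      rep <- hd_evaluate(model, Eg[test_idx, , drop = FALSE],
                         labels[test_idx])
      accs[f] <- rep$accuracy
      iters[f] <- model$retrain_iterations_used
    }
    list(mean_accuracy = 100 * mean(accs),
         fold_accuracies = 100 * accs,
         mean_retrain_iterations = mean(iters))
  }
  attr(evaluator, "commit") <- function(features) {
    cache$E <- encodings_for(features)
    cache$features <- as.character(features)
    invisible(NULL)
  }
  attr(evaluator, "fold_plan") <- folds
  evaluator
}

normalize_eval <- function(res) {
  if (is.numeric(res) && length(res) == 1) {
    res <- list(mean_accuracy = as.numeric(res))
  }
  if (is.null(res$fold_accuracies)) res$fold_accuracies <- NA_real_
  if (is.null(res$mean_retrain_iterations)) {
    res$mean_retrain_iterations <- NA_real_
  }
  res
}

#' Backward variable elimination over hyperdimensional models
#'
#' Starting from the full feature set, each iteration scores every
#' leave-one-out candidate subset, discards candidates whose accuracy falls
#' below the threshold `T`, and removes *all* features whose exclusion scored
#' within the accuracy-uncertainty band of the iteration's best accuracy
#' (cutoff `best * (1 - u/100)`; with `u = 0` exactly one feature is removed
#' per iteration). The procedure stops when: the initial full-set model is
#' below `T`; no candidate reaches `T`; the iteration's best accuracy drops
#' below the previous accepted best by more than the uncertainty band (the
#' iteration is rejected and its removals are not applied); or no features
#' remain.
#'
#' @param dataset A [labeled_dataset()]; may be `NULL` when both `features`
#'   and `evaluator` are supplied (e.g. for injected evaluators in tests).
#' @param config An [hd_config()] providing `T`, `u` and, for the default
#'   evaluator, the classifier parameters and the seed.
#' @param evaluator Function mapping a character vector of retained features
#'   to either a bare mean accuracy in percent or a list with
#'   `mean_accuracy`, `fold_accuracies`, `mean_retrain_iterations`. Defaults
#'   to [hd_cv_evaluator()] on `dataset`.
#' @param features Feature names to start from; defaults to all of
#'   `dataset`'s features.
#' @param direction `"backward"` (the elimination described above) or
#'   `"forward"`, the mirror-image greedy inclusion variant.
#' @return An object of class `selection_result`: `selected` (retained
#'   features), `excluded` (removal order), `trace` (one record per
#'   iteration, including the initial full-set model and any rejected final
#'   iteration), `models_evaluated`, `terminated_reason` (one of
#'   `initial_model_below_threshold`, `below_threshold`,
#'   `accuracy_decreased`, `features_exhausted`), `final_best_accuracy` (best
#'   accuracy of the last accepted iteration, in percent) and `best_model`
#'   (the highest-accuracy accepted model and its feature set).
#' @export
backward_eliminate <- function(dataset = NULL, config = hd_config(),
                               evaluator = NULL, features = NULL,
                               direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  stopifnot(inherits(config, "hd_config"))
  if (is.null(features)) {
    if (is.null(dataset)) stop_hd("supply `dataset` or `features`")
    features <- dataset$feature_names
  }
  features <- as.character(features)
  if (length(features) == 0) stop_hd("at least one feature is required")
  if (is.null(evaluator)) {
    if (is.null(dataset)) stop_hd("an `evaluator` is required without a dataset")
    evaluator <- hd_cv_evaluator(dataset, config)
  }
  if (direction == "forward") {
    return(forward_select(features, config, evaluator))
  }
  commit <- attr(evaluator, "commit")
  T <- config$T
  u <- config$u
  trace <- list()
  models_evaluated <- 0L

  eval_subset <- function(subset) {
    res <- tryCatch(normalize_eval(evaluator(subset)), error = function(e) {
      stop_selection(conditionMessage(e), trace, models_evaluated)
    })
    models_evaluated <<- models_evaluated + 1L
    res
  }

  S <- features
  B <- character(0)
  init <- eval_subset(S)
  trace[[1]] <- list(iteration = 0L,
                     features_present = S,
                     candidates = list(list(
                       excluded = NA_character_,
                       mean_accuracy = init$mean_accuracy,
                       fold_accuracies = init$fold_accuracies,
                       mean_retrain_iterations = init$mean_retrain_iterations)),
                     band_cutoff = NA_real_,
                     removed = character(0),
                     best_accuracy = init$mean_accuracy,
                     accepted = TRUE)
  best_model <- list(features = S, accuracy = init$mean_accuracy)
  final_best <- init$mean_accuracy

  if (init$mean_accuracy < T) {
    return(selection_result(S, B, trace, models_evaluated,
                            "initial_model_below_threshold", final_best,
                            best_model))
  }
  prev_best <- init$mean_accuracy
  reason <- NULL
  iteration <- 0L
  while (is.null(reason)) {
    if (length(S) == 0) {
      reason <- "features_exhausted"
      break
    }
    iteration <- iteration + 1L
    candidates <- vector("list", length(S))
    for (i in seq_along(S)) {
      res <- eval_subset(setdiff(S, S[i]))
      candidates[[i]] <- list(excluded = S[i],
                              mean_accuracy = res$mean_accuracy,
                              fold_accuracies = res$fold_accuracies,
                              mean_retrain_iterations = res$mean_retrain_iterations)
    }
    accs <- vapply(candidates, function(cd) cd$mean_accuracy, numeric(1))
    eligible <- accs >= T
    record <- list(iteration = iteration, features_present = S,
                   candidates = candidates)
    if (!any(eligible)) {
      record$band_cutoff <- NA_real_
      record$removed <- character(0)
      record$best_accuracy <- max(accs)
      record$accepted <- FALSE
      trace[[length(trace) + 1L]] <- record
      reason <- "below_threshold"
      break
    }
    best <- max(accs[eligible])
    band <- acceptance_cutoff(best, u)
    record$band_cutoff <- band
    record$best_accuracy <- best
    if (best < acceptance_cutoff(prev_best, u)) {
      # accuracy dropped beyond the uncertainty band: reject this iteration
      record$removed <- character(0)
      record$accepted <- FALSE
      trace[[length(trace) + 1L]] <- record
      reason <- "accuracy_decreased"
      break
    }
    remove_idx <- which(eligible & accs >= band)
    remove_idx <- remove_idx[order(-accs[remove_idx], remove_idx)]
    removed <- vapply(candidates[remove_idx], function(cd) cd$excluded,
                      character(1))
    record$removed <- removed
    record$accepted <- TRUE
    trace[[length(trace) + 1L]] <- record
    B <- c(B, removed)
    S <- setdiff(S, removed)
    if (!is.null(commit)) commit(S)
    if (best > best_model$accuracy) {
      best_i <- remove_idx[1]
      best_model <- list(
        features = setdiff(record$features_present,
                           candidates[[best_i]]$excluded),
        accuracy = best)
    }
    final_best <- best
    prev_best <- best
  }
  selection_result(S, B, trace, models_evaluated, reason, final_best,
                   best_model)
}

selection_result <- function(selected, excluded, trace, models_evaluated,
                             reason, final_best, best_model) {
  structure(
    list(selected = selected, excluded = excluded, trace = trace,
         models_evaluated = models_evaluated,
         terminated_reason = reason,
         final_best_accuracy = final_best,
         best_model = best_model),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Backward variable elimination\n")
  cat("  selected features: ", length(x$selected), "\n")
  cat("  excluded features: ", length(x$excluded), "\n")
  cat("  models evaluated:  ", x$models_evaluated, "\n")
  cat("  best accepted accuracy (final iteration): ",
      sprintf("%.2f%%", x$final_best_accuracy), "\n", sep = "")
  cat("  terminated:        ", x$terminated_reason, "\n")
  invisible(x)
}

stop_selection <- function(msg, trace, models_evaluated) {
  cond <- structure(
    class = c("hd_selection_error", "error", "condition"),
    list(message = paste0("candidate evaluation failed: ", msg),
         call = NULL, trace = trace, models_evaluated = models_evaluated)
  )
  stop(cond)
}

# Greedy forward counterpart: grow the feature set by the additions scoring
# within the band of each iteration's best, with the same threshold and
# stop-on-decrease rules. Mirror image of the elimination loop.
forward_select <- function(features, config, evaluator) {
  T <- config$T
  u <- config$u
  trace <- list()
  models_evaluated <- 0L
  eval_subset <- function(subset) {
    res <- tryCatch(normalize_eval(evaluator(subset)), error = function(e) {
      stop_selection(conditionMessage(e), trace, models_evaluated)
    })
    models_evaluated <<- models_evaluated + 1L
    res
  }
  S <- character(0)
  remaining <- features
  prev_best <- -Inf
  reason <- NULL
  iteration <- 0L
  best_model <- list(features = character(0), accuracy = -Inf)
  final_best <- NA_real_
  while (is.null(reason)) {
    if (length(remaining) == 0) {
      reason <- "features_exhausted"
      break
    }
    iteration <- iteration + 1L
    candidates <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      res <- eval_subset(c(S, remaining[i]))
      candidates[[i]] <- list(added = remaining[i],
                              mean_accuracy = res$mean_accuracy,
                              fold_accuracies = res$fold_accuracies,
                              mean_retrain_iterations = res$mean_retrain_iterations)
    }
    accs <- vapply(candidates, function(cd) cd$mean_accuracy, numeric(1))
    eligible <- accs >= T
    record <- list(iteration = iteration, features_present = S,
                   candidates = candidates)
    if (!any(eligible)) {
      record$band_cutoff <- NA_real_
      record$added <- character(0)
      record$best_accuracy <- max(accs)
      record$accepted <- FALSE
      trace[[length(trace) + 1L]] <- record
      reason <- if (iteration == 1L) "initial_model_below_threshold" else "below_threshold"
      break
    }
    best <- max(accs[eligible])
    band <- acceptance_cutoff(best, u)
    record$band_cutoff <- band
    record$best_accuracy <- best
    if (is.finite(prev_best) && best < acceptance_cutoff(prev_best, u)) {
      record$added <- character(0)
      record$accepted <- FALSE
      trace[[length(trace) + 1L]] <- record
      reason <- "accuracy_decreased"
      break
    }
    add_idx <- which(eligible & accs >= band)
    add_idx <- add_idx[order(-accs[add_idx], add_idx)]
    added <- vapply(candidates[add_idx], function(cd) cd$added, character(1))
    record$added <- added
    record$accepted <- TRUE
    trace[[length(trace) + 1L]] <- record
    S <- c(S, added)
    remaining <- setdiff(remaining, added)
    if (best > best_model$accuracy) {
      best_model <- list(features = c(record$features_present,
                                      candidates[[add_idx[1]]]$added),
                         accuracy = best)
    }
    final_best <- best
    prev_best <- best
  }
  selection_result(S, setdiff(features, S), trace, models_evaluated, reason,
                   final_best, best_model)
}

#' Frontier of compact suboptimal models
#'
#' Among *all* candidate models evaluated during a selection run (any
#' iteration, including a rejected final one and the initial full-set
#' model) whose mean accuracy exceeds `min_accuracy`, returns the model with
#' the fewest features; ties resolve to the higher accuracy, then to the
#' earliest evaluation.
#'
#' @param result A [backward_eliminate()] `selection_result`.
#' @param min_accuracy Accuracy floor in percent (default 70, exclusive).
#' @return A list with `features`, `accuracy`, `n_features` and `iteration`,
#'   or `NULL` when no evaluated model qualifies.
#' @export
suboptimal_frontier <- function(result, min_accuracy = 70) {
  stopifnot(inherits(result, "selection_result"))
  best <- NULL
  for (record in result$trace) {
    for (cd in record$candidates) {
      if (!is.null(cd$excluded) && !is.na(cd$excluded)) {
        feats <- setdiff(record$features_present, cd$excluded)
      } else if (!is.null(cd$added)) {
        feats <- c(record$features_present, cd$added)
      } else {
        feats <- record$features_present
      }
      if (cd$mean_accuracy <= min_accuracy) next
      if (is.null(best) ||
          length(feats) < best$n_features ||
          (length(feats) == best$n_features &&
           cd$mean_accuracy > best$accuracy)) {
        best <- list(features = feats, accuracy = cd$mean_accuracy,
                     n_features = length(feats),
                     iteration = record$iteration)
      }
    }
  }
  best
}

#' Write a selection trace as JSON lines
#'
#' One JSON object per iteration record (the initial full-set model is
#' iteration 0), suitable for auditing every candidate model of a run.
#'
#' @param result A `selection_result`.
#' @param path Output file path.
#' @export
write_trace <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (record in result$trace) {
    writeLines(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"), con)
  }
  invisible(path)
}
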