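# Backward variable elimination: cutoff arithmetic, the five-feature
# walkthrough oracle, degenerate modes, and the suboptimal frontier.

test_that("the acceptance cutoff is relative and displayed floored", {
  expect_equal(acceptance_cutoff(93, 5), 88.35)
  expect_equal(cutoff_display(acceptance_cutoff(93, 5)), 88L)
  expect_equal(acceptance_cutoff(90, 5), 85.5)
  expect_equal(cutoff_display(acceptance_cutoff(90, 5)), 85L)
  for (x in c(0, 12.5, 60, 100)) expect_equal(acceptance_cutoff(x, 0), x)
  expect_error(acceptance_cutoff(101, 5), "\\[0, 100\\]")
  expect_error(acceptance_cutoff(50, -1), "\\[0, 100\\]")
})

test_that("elimination reproduces the five-feature walkthrough exactly", {
  res <- run_fig2()
  expect_setequal(res$selected, c("F1", "F4"))
  expect_equal(res$excluded, c("F2", "F3", "F5"))
  expect_equal(res$terminated_reason, "accuracy_decreased")
  expect_equal(res$final_best_accuracy, 90)
  expect_equal(res$models_evaluated, 11L)
  # iteration 1 removes F2 and F3 together (band 93 * 0.95 = 88.35)
  it1 <- res$trace[[2]]
  expect_equal(it1$removed, c("F2", "F3"))
  expect_equal(it1$band_cutoff, 88.35)
  expect_true(it1$accepted)
  # iteration 2 removes F5 alone at best 90
  it2 <- res$trace[[3]]
  expect_equal(it2$removed, "F5")
  expect_equal(it2$best_accuracy, 90)
  # final iteration is rejected: its removals are not applied
  it3 <- res$trace[[4]]
  expect_false(it3$accepted)
  expect_equal(it3$removed, character(0))
  expect_equal(it3$best_accuracy, 75)
})

test_that("removed features always met both the threshold and the band", {
  res <- run_fig2()
  for (record in res$trace[-1]) {
    if (!record$accepted) next
    accs <- vapply(record$candidates, function(cd) cd$mean_accuracy,
                   numeric(1))
    excl <- vapply(record$candidates, function(cd) cd$excluded, character(1))
    for (f in record$removed) {
      a <- accs[excl == f]
      expect_gte(a, 70)
      expect_gte(a, record$band_cutoff)
    }
  }
  # selected and excluded partition the initial features
  expect_setequal(c(res$selected, res$excluded), fig2_features)
  expect_length(intersect(res$selected, res$excluded), 0)
})

test_that("an initial model below threshold stops immediately", {
  res <- backward_eliminate(features = c("A", "B"),
                            config = hd_config(T = 70, u = 1),
                            evaluator = function(feats) 50)
  expect_equal(res$terminated_reason, "initial_model_below_threshold")
  expect_setequal(res$selected, c("A", "B"))
  expect_length(res$trace, 1)
  expect_equal(res$models_evaluated, 1L)
})

test_that("u = 0 with distinct accuracies removes exactly one feature per round", {
  # noise features raise accuracy by distinct amounts when removed; signal
  # features cost 5 points each, so their removal triggers the stop rule
  bonus <- c(n1 = 2, n2 = 3, n3 = 4)
  ev <- function(feats) {
    removed <- setdiff(c("s1", "s2", "n1", "n2", "n3"), feats)
    70 + sum(bonus[intersect(removed, names(bonus))]) -
      5 * length(intersect(removed, c("s1", "s2")))
  }
  res <- backward_eliminate(features = c("s1", "s2", "n1", "n2", "n3"),
                            config = hd_config(T = 60, u = 0),
                            evaluator = ev)
  accepted <- Filter(function(r) r$iteration > 0 && r$accepted, res$trace)
  expect_true(all(vapply(accepted, function(r) length(r$removed),
                         integer(1)) == 1L))
  expect_setequal(res$selected, c("s1", "s2"))
  expect_equal(res$excluded, c("n3", "n2", "n1"))  # best bonus removed first
  expect_equal(res$terminated_reason, "accuracy_decreased")
  # models: 1 + 5 + 4 + 3 + 2
  expect_equal(res$models_evaluated, 15L)
})

test_that("no candidate reaching the threshold stops with below_threshold", {
  calls <- new.env(); calls$n <- 0
  ev <- function(feats) {
    calls$n <- calls$n + 1
    if (length(feats) == 3) 80 else 40
  }
  res <- backward_eliminate(features = c("A", "B", "C"),
                            config = hd_config(T = 70, u = 1),
                            evaluator = ev)
  expect_equal(res$terminated_reason, "below_threshold")
  expect_setequal(res$selected, c("A", "B", "C"))
  expect_equal(res$models_evaluated, 4L)
})

test_that("the suboptimal frontier prefers fewer features, then accuracy", {
  res <- run_fig2()
  fr <- suboptimal_frontier(res, min_accuracy = 70)
  expect_equal(fr$features, "F4")
  expect_equal(fr$accuracy, 75)
  expect_equal(fr$n_features, 1L)
  expect_null(suboptimal_frontier(res, min_accuracy = 100))
  # a run with only the full-set model returns that model
  solo <- backward_eliminate(features = c("A", "B"),
                             config = hd_config(T = 90, u = 1),
                             evaluator = function(feats) 80)
  fr2 <- suboptimal_frontier(solo, min_accuracy = 70)
  expect_setequal(fr2$features, c("A", "B"))
  expect_equal(fr2$accuracy, 80)
})

test_that("evaluator failures abort with the partial trace preserved", {
  ev <- function(feats) {
    if (length(feats) == 2) stop("backend exploded")
    80
  }
  err <- tryCatch(
    backward_eliminate(features = c("A", "B", "C"),
                       config = hd_config(T = 60, u = 0), evaluator = ev),
    hd_selection_error = function(e) e)
  expect_s3_class(err, "hd_selection_error")
  expect_match(conditionMessage(err), "backend exploded")
  expect_length(err$trace, 1)  # initial record survived
  expect_equal(err$models_evaluated, 1L)
})

test_that("a selection trace round-trips to JSON lines", {
  res <- run_fig2()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_trace(res, path)
  lines <- readLines(path)
  expect_length(lines, length(res$trace))
  rec <- jsonlite::fromJSON(lines[2], simplifyVector = FALSE)
  expect_equal(rec$iteration, 1)
  expect_equal(unlist(rec$removed), c("F2", "F3"))
})

test_that("the CV evaluator scores subsets identically to a from-scratch run", {
  sim <- simulate_binary_profiles(n_case = 16, n_control = 16,
                                  n_features = 6, n_informative = 2,
                                  seed = 3)
  cfg <- hd_config(d = 800, L = 2, R = 5, k = 4, seed = 3)
  ev <- hd_cv_evaluator(sim$dataset, cfg)
  subset <- sim$dataset$feature_names[c(1, 3, 4, 6)]
  incremental <- ev(subset)
  # oracle: a full cross-validation of the restricted dataset (same seed
  # derivation, so identical levels and folds, but encoded from scratch)
  fresh <- hd_cross_validate(hdselect:::subset_features(sim$dataset, subset),
                             cfg)
  expect_equal(incremental$fold_accuracies, 100 * fresh$fold_accuracies)
  # full set: original and relative positions coincide by construction
  rel <- hd_cv_evaluator(sim$dataset, cfg, positions = "relative")
  expect_equal(ev(sim$dataset$feature_names)$fold_accuracies,
               rel(sim$dataset$feature_names)$fold_accuracies)
  sub_rel <- rel(subset)
  expect_true(sub_rel$mean_accuracy >= 0 && sub_rel$mean_accuracy <= 100)
})

test_that("forward inclusion grows the feature set under the same rules", {
  ev <- function(feats) {
    60 + 15 * length(intersect(feats, c("s1", "s2"))) -
      2 * length(intersect(feats, "n1"))
  }
  res <- backward_eliminate(features = c("s1", "s2", "n1"),
                            config = hd_config(T = 60, u = 0),
                            evaluator = ev, direction = "forward")
  expect_true(all(c("s1", "s2") %in% res$selected))
  expect_true(res$terminated_reason %in%
                c("features_exhausted", "accuracy_decreased"))
})
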