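# Shared fixtures: the five-feature elimination walkthrough oracle and a
# hand-built three-study abundance toy. All fixtures are built in code.

fig2_features <- paste0("F", 1:5)

# Injected evaluator reproducing the five-feature walkthrough: full set 80;
# leave-one-out accuracies 75/93/91/72/68; then from {F1,F4,F5} 65/60/90;
# then from {F1,F4} 75/72.
fig2_evaluator <- function() {
  accs <- list(
    "F1,F2,F3,F4,F5" = 80,
    "F2,F3,F4,F5" = 75, "F1,F3,F4,F5" = 93, "F1,F2,F4,F5" = 91,
    "F1,F2,F3,F5" = 72, "F1,F2,F3,F4" = 68,
    "F4,F5" = 65, "F1,F5" = 60, "F1,F4" = 90,
    "F4" = 75, "F1" = 72)
  function(feats) {
    key <- paste(sort(feats), collapse = ",")
    a <- accs[[key]]
    if (is.null(a)) stop("no stubbed accuracy for subset {", key, "}")
    a
  }
}

run_fig2 <- function() {
  backward_eliminate(features = fig2_features,
                     config = hd_config(T = 70, u = 5),
                     evaluator = fig2_evaluator())
}

sp <- function(name) sprintf("k__Bacteria|p__Firmicutes|s__%s", name)

# Three single-study tables over a handful of species:
#  - shared_a, shared_b: detected in every study (kept by the merge)
#  - two_of_three: absent from study 3 (dropped, reassigned to unclassified)
#  - only_one: detected in study 1 only (dropped)
toy_three_studies <- function() {
  mk <- function(values, samples, study) {
    m <- matrix(values, ncol = length(samples),
                dimnames = list(c(sp("shared_a"), sp("shared_b"),
                                  sp("two_of_three"), sp("only_one"),
                                  "unclassified"), samples))
    abundance_table(m, study = study)
  }
  list(
    mk(c(10, 5, 2, 1, 40,
         8, 6, 3, 0, 50), c("s1", "s2"), "study1"),
    mk(c(12, 4, 1, 0, 30,
         9, 7, 2, 0, 20), c("s3", "s4"), "study2"),
    mk(c(11, 6, 0, 0, 35,
         7, 8, 0, 0, 45), c("s5", "s6"), "study3")
  )
}

# Independent Benjamini-Hochberg step-up oracle used to cross-check the
# package's multiple-testing path.
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- prev
  }
  pmin(q, 1)
}
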