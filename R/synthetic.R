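# Seeded synthetic generators: presence/absence matrices with planted
# differentially prevalent features, and relative-abundance tables with an
# unclassified remainder, mimicking binarized species profiles in a
# case/control design.

#' Simulate a presence/absence dataset with planted features
#'
#' Every informative feature is Bernoulli with probability `p_case` in case
#' samples and `p_control` in controls; all other features are Bernoulli
#' `p_background` in both classes. Draws are independent and the result is a
#' pure function of the arguments including `seed`. Informative features are
#' placed at seeded random positions.
#'
#' @param n_case,n_control Samples per class (defaults 100 and 100).
#' @param n_features Total number of features (default 50).
#' @param n_informative Number of planted features (default 5).
#' @param p_case,p_control Presence probabilities of planted features in case
#'   and control samples (defaults 0.85 and 0.15, a strong prevalence
#'   contrast of the kind discriminative species show).
#' @param p_background Presence probability of the remaining features in all
#'   samples (default 0.5: maximally variable but carrying no class signal).
#' @param class_labels Labels for the two classes (default
#'   `c("case", "control")`).
#' @param seed Integer seed.
#' @return List with `dataset`, a [labeled_dataset()] (samples x features,
#'   0/1 values), and `truth`, the ground-truth description (informative
#'   feature names and the generating probabilities).
#' @export
simulate_binary_profiles <- function(n_case = 100, n_control = 100,
                                     n_features = 50, n_informative = 5,
                                     p_case = 0.85, p_control = 0.15,
                                     p_background = 0.5,
                                     class_labels = c("case", "control"),
                                     seed = NULL) {
  check_sim_args(n_case, n_control, n_features, n_informative,
                 c(p_case, p_control, p_background))
  n <- n_case + n_control
  feature_names <- sprintf("species_%03d", seq_len(n_features))
  labels <- rep(class_labels[1:2], c(n_case, n_control))
  with_seed(seed, {
    informative <- sort(sample.int(n_features, n_informative))
    p <- matrix(p_background, nrow = n, ncol = n_features)
    p[labels == class_labels[1], informative] <- p_case
    p[labels == class_labels[2], informative] <- p_control
    values <- matrix(as.numeric(runif(n * n_features) < p),
                     nrow = n, ncol = n_features)
    colnames(values) <- feature_names
    ds <- labeled_dataset(values, labels)
    truth <- list(informative = feature_names[informative],
                  p_case = p_case, p_control = p_control,
                  p_background = p_background,
                  n_case = n_case, n_control = n_control, seed = seed)
    list(dataset = ds, truth = truth)
  })
}

check_sim_args <- function(n_case, n_control, n_features, n_informative,
                           probs) {
  if (!is_count(n_case) || !is_count(n_control)) {
    stop_hd("class sizes must be positive integers")
  }
  if (!is_count(n_features) || !is_count(n_informative, min = 0) ||
      n_informative > n_features) {
    stop_hd("`n_informative` must be an integer in [0, n_features]")
  }
  if (any(probs < 0 | probs > 1)) {
    stop_hd("presence probabilities must be in [0, 1]")
  }
}

#' Simulate a relative-abundance table with planted features
#'
#' Presence/absence is drawn exactly as in [simulate_binary_profiles()];
#' present species then receive positive abundances from a Gamma
#' distribution (shape `concentration`), a Gamma-weighted share is assigned
#' to the `unclassified` remainder, and each sample is normalized so that
#' species plus unclassified sum to exactly 100.
#'
#' @inheritParams simulate_binary_profiles
#' @param concentration Gamma shape of the abundance weights (default 1;
#'   smaller values give more skewed profiles).
#' @param unclassified_weight Relative Gamma shape of the unclassified
#'   remainder (default 5, i.e. the unclassified fraction behaves like five
#'   average species).
#' @return List with `table` (an [abundance_table()]), `metadata` (a data
#'   frame with `sample_id`, `class`, `sex`, `age`, `study`) and `truth`.
#' @export
simulate_ra_profiles <- function(n_case = 100, n_control = 100,
                                 n_features = 50, n_informative = 5,
                                 p_case = 0.85, p_control = 0.15,
                                 p_background = 0.5, concentration = 1,
                                 unclassified_weight = 5,
                                 class_labels = c("case", "control"),
                                 seed = NULL) {
  if (concentration <= 0) stop_hd("`concentration` must be positive")
  sim <- simulate_binary_profiles(n_case, n_control, n_features,
                                  n_informative, p_case, p_control,
                                  p_background, class_labels, seed)
  presence <- sim$dataset$values
  n <- nrow(presence)
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, 3L), {
    w <- matrix(rgamma(length(presence), shape = concentration),
                nrow = n) * presence
    uncl <- rgamma(n, shape = concentration * unclassified_weight)
    total <- rowSums(w) + uncl
    ra <- 100 * w / total
    uncl_ra <- 100 * uncl / total
    values <- rbind(t(ra), unclassified = uncl_ra)
    rownames(values) <- c(lineage_names(sim$dataset$feature_names),
                          UNCLASSIFIED)
    colnames(values) <- sim$dataset$sample_ids
    metadata <- data.frame(
      sample_id = sim$dataset$sample_ids,
      class = sim$dataset$labels,
      sex = sample(c("female", "male"), n, replace = TRUE),
      age = sample(28:84, n, replace = TRUE),
      study = "synthetic",
      stringsAsFactors = FALSE
    )
    list(table = abundance_table(values, study = "synthetic"),
         metadata = metadata, truth = sim$truth)
  })
}

# Dress bare feature names as species-level lineage strings so the synthetic
# tables round-trip through the MetaPhlAn-style reader.
lineage_names <- function(feature_names) {
  sprintf("k__Bacteria|s__%s", feature_names)
}
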