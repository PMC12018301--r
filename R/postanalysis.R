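# Per-species differential-abundance statistics: prevalence, log2 fold
# change, and Wilcoxon rank-sum tests with Benjamini-Hochberg correction.

feature_matrix <- function(x) {
  if (inherits(x, "abundance_table")) {
    x$values[species_rows(x), , drop = FALSE]
  } else {
    as.matrix(x)
  }
}

#' Per-species prevalence within a class
#'
#' The percentage of a class's samples in which a species is detected
#' (abundance strictly positive).
#'
#' @param x An [abundance_table()] or a species-by-samples numeric matrix.
#' @param labels Class label per sample (column).
#' @param class The class to compute prevalence in.
#' @return Named numeric vector of percentages, one per species.
#' @export
species_prevalence <- function(x, labels, class) {
  m <- feature_matrix(x)
  labels <- as.character(labels)
  if (length(labels) != ncol(m)) stop_hd("one label per sample required")
  in_class <- labels == class
  if (!any(in_class)) stop_hd("no samples in class '", class, "'")
  100 * rowSums(m[, in_class, drop = FALSE] > 0) / sum(in_class)
}

#' Per-species log2 fold change of class-mean abundances
#'
#' `log2(mean_case / mean_control)` per species, with no pseudocount: a zero
#' class mean yields an explicit `Inf`/`-Inf` (or `NaN` when both means are
#' zero) and the corresponding `undefined` flag.
#'
#' @param x An [abundance_table()] or species-by-samples matrix of relative
#'   abundances.
#' @param labels Class label per sample.
#' @param case,control The two class labels to contrast.
#' @return Data frame with `species`, `mean_case`, `mean_control`, `log2fc`
#'   and `undefined`.
#' @export
species_log2fc <- function(x, labels, case, control) {
  m <- feature_matrix(x)
  labels <- as.character(labels)
  if (!any(labels == case) || !any(labels == control)) {
    stop_hd("both classes must be non-empty")
  }
  mean_case <- rowMeans(m[, labels == case, drop = FALSE])
  mean_control <- rowMeans(m[, labels == control, drop = FALSE])
  lfc <- suppressWarnings(log2(mean_case / mean_control))
  data.frame(species = rownames(m),
             mean_case = as.numeric(mean_case),
             mean_control = as.numeric(mean_control),
             log2fc = as.numeric(lfc),
             undefined = !is.finite(lfc),
             row.names = NULL)
}

#' Differential abundance by Wilcoxon rank-sum with BH correction
#'
#' Two-sided rank-sum test per species between the case and control samples,
#' with Benjamini-Hochberg adjusted q-values. By default the p-value uses the
#' normal approximation with tie correction (`exact = FALSE`, no continuity
#' correction); set `exact = TRUE` for the exact distribution (only available
#' without ties). A species is flagged significant when both
#' `p_value <= p_threshold` and `q_value <= fdr_threshold`.
#'
#' @param x An [abundance_table()] or species-by-samples matrix.
#' @param labels Class label per sample.
#' @param case,control The two class labels to contrast.
#' @param p_threshold,fdr_threshold Significance thresholds (defaults 0.05
#'   and 0.2).
#' @param exact Use the exact rank-sum distribution instead of the normal
#'   approximation?
#' @param min_abs_log2fc Optional reporting filter: keep only species with
#'   `|log2fc| >=` this value (`NULL`, the default, keeps all; infinite
#'   log2fc values always pass).
#' @return Data frame with one row per species: prevalences, log2fc,
#'   p-value, q-value, and the `significant` flag.
#' @export
diff_abundance <- function(x, labels, case, control,
                           p_threshold = 0.05, fdr_threshold = 0.2,
                           exact = FALSE, min_abs_log2fc = NULL) {
  m <- feature_matrix(x)
  labels <- as.character(labels)
  n_case <- sum(labels == case)
  n_control <- sum(labels == control)
  if (n_case < 2 || n_control < 2) {
    stop_hd("at least 2 samples per class are required")
  }
  pvals <- apply(m, 1, function(v) {
    suppressWarnings(
      stats::wilcox.test(v[labels == case], v[labels == control],
                         alternative = "two.sided", exact = exact,
                         correct = FALSE)$p.value
    )
  })
  pvals[is.na(pvals)] <- 1  # constant species: no evidence either way
  qvals <- stats::p.adjust(pvals, method = "BH")
  lfc <- species_log2fc(m, labels, case, control)
  out <- data.frame(
    species = rownames(m),
    prevalence_case = as.numeric(species_prevalence(m, labels, case)),
    prevalence_control = as.numeric(species_prevalence(m, labels, control)),
    log2fc = lfc$log2fc,
    log2fc_undefined = lfc$undefined,
    p_value = as.numeric(pvals),
    q_value = as.numeric(qvals),
    row.names = NULL
  )
  out$significant <- out$p_value <= p_threshold & out$q_value <= fdr_threshold
  if (!is.null(min_abs_log2fc)) {
    out <- out[is.infinite(out$log2fc) | abs(out$log2fc) >= min_abs_log2fc, ,
               drop = FALSE]
  }
  out
}
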