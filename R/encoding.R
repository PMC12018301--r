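# Quantization of scalar feature values onto level hypervectors and sample
# encoding by positional permutation + bundling.

#' Define a quantization scheme
#'
#' Partitions the value range `[value_min, value_max]` into `L` equal-width,
#' right-closed bins, one per level hypervector. The minimum maps to level 0
#' and the maximum to level `L - 1`; distinct values falling in the same bin
#' share a level vector.
#'
#' @param value_min,value_max Range of the values to encode (typically the
#'   global range of the training data, e.g. \[0, 100\] for relative
#'   abundances, \[0, 1\] for presence/absence).
#' @param L Number of levels; must match the level family used for encoding.
#' @return An object of class `quantization_scheme`.
#' @export
quantization_scheme <- function(value_min, value_max, L) {
  if (!is.numeric(value_min) || !is.numeric(value_max) ||
      !is.finite(value_min) || !is.finite(value_max)) {
    stop_hd("`value_min` and `value_max` must be finite numbers")
  }
  if (value_min > value_max) {
    stop_hd("`value_min` must not exceed `value_max`")
  }
  if (!is_count(L)) stop_hd("`L` must be a positive integer")
  structure(
    list(value_min = value_min, value_max = value_max, L = as.integer(L)),
    class = "quantization_scheme"
  )
}

#' Map values to level indices
#'
#' Right-closed binning: `x <= value_min` maps to 0, otherwise
#' `ceiling((x - value_min) / w) - 1` with bin width
#' `w = (value_max - value_min) / L`, capped at `L - 1`. With a degenerate
#' range (`value_min == value_max`) every value maps to 0. Values outside the
#' range are clamped with a warning (this happens when test data exceed the
#' training range).
#'
#' @param x Numeric vector of values; must be finite.
#' @param scheme A [quantization_scheme()].
#' @return Integer vector of level indices in `[0, L - 1]`.
#' @examples
#' sc <- quantization_scheme(0, 100, 100)
#' value_to_level(c(0.1, 1.0), sc)  # both fall in level 0
#' @export
value_to_level <- function(x, scheme) {
  stopifnot(inherits(scheme, "quantization_scheme"))
  if (any(!is.finite(x))) {
    stop_hd("values to quantize must be finite")
  }
  lo <- scheme$value_min
  hi <- scheme$value_max
  if (any(x < lo | x > hi)) {
    warning("values outside [", lo, ", ", hi, "] clamped to the range")
    x <- pmin(pmax(x, lo), hi)
  }
  if (lo == hi) {
    return(integer(length(x)))
  }
  w <- (hi - lo) / scheme$L
  idx <- as.integer(ceiling((x - lo) / w)) - 1L
  idx[x <= lo] <- 0L
  pmin(pmax(idx, 0L), scheme$L - 1L)
}

#' Encode one sample as a hypervector
#'
#' Each feature value is quantized to a level vector, the level vector is
#' rotated by the feature's position (position 0 is unrotated), and the
#' rotated vectors are bundled (summed). Positions are the features' original
#' column indices in the full dataset, so the encoding of a feature subset
#' equals the full-sample encoding minus the rotated level vectors of the
#' removed features — the identity the elimination wrapper exploits.
#'
#' @param values Numeric vector of F feature values.
#' @param positions Integer vector of F distinct non-negative positions.
#' @param levels An [generate_levels()] family.
#' @param scheme A [quantization_scheme()] with the same `L` as `levels`.
#' @return Integer vector of length `levels$d` (the zero vector for an empty
#'   feature set).
#' @export
encode_sample <- function(values, positions, levels, scheme) {
  stopifnot(inherits(levels, "hd_levels"))
  if (length(values) != length(positions)) {
    stop_hd("`values` and `positions` must have the same length")
  }
  if (anyDuplicated(positions)) {
    stop_hd("feature positions must be distinct")
  }
  if (length(positions) && any(positions < 0)) {
    stop_hd("feature positions must be non-negative")
  }
  if (scheme$L != levels$L) {
    stop_hd("scheme has L = ", scheme$L, " but the level family has L = ",
            levels$L)
  }
  out <- integer(levels$d)
  if (length(values) == 0) {
    return(out)
  }
  idx <- value_to_level(values, scheme)
  for (i in seq_along(values)) {
    out <- out + hd_permute(levels$levels[idx[i] + 1L, ], positions[i])
  }
  out
}

# Vectorized encoding of a samples x features value matrix. Returns an
# n x d numeric matrix. `positions` are 0-based original column indices.
# Implemented column-rotation-wise: for each feature, the whole level matrix
# is rotated once and indexed by the samples' level indices.
encode_matrix <- function(values, positions, levels, scheme) {
  n <- nrow(values)
  d <- levels$d
  out <- matrix(0, nrow = n, ncol = d)
  if (ncol(values) == 0) {
    return(out)
  }
  idx <- matrix(value_to_level(as.numeric(values), scheme),
                nrow = n, ncol = ncol(values))
  for (j in seq_len(ncol(values))) {
    out <- out + feature_contribution(idx[, j], positions[j], levels)
  }
  out
}

# n x d matrix of rotated level vectors for one feature: row i is the level
# vector of sample i's quantized value, rotated by `position`. Only the level
# rows actually used by the samples are rotated (L can be large).
feature_contribution <- function(level_idx, position, levels) {
  d <- levels$d
  p <- as.integer(position %% d)
  cols <- ((seq_len(d) - 1L - p) %% d) + 1L
  uidx <- sort(unique(level_idx))
  sub <- levels$levels[uidx + 1L, cols, drop = FALSE]
  sub[match(level_idx, uidx), , drop = FALSE] + 0
}
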