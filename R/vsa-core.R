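# Bipolar hypervector algebra: the Multiply-Add-Permute (MAP) operations and
# the generation of correlated level hypervectors.
#
# Hypervectors are plain R integer vectors. Bipolar vectors carry only +1/-1
# components; bundling produces general integer vectors. All arithmetic is
# integer arithmetic so that bundling and retraining are exactly reproducible.

#' Draw a random bipolar hypervector
#'
#' Each of the `d` components is drawn independently and uniformly from
#' \{-1, +1\}. Uses the current R random stream; wrap in `set.seed()` (or pass
#' a seed to the higher-level entry points) for reproducibility.
#'
#' @param d Positive integer dimensionality (typically 10000).
#' @return Integer vector of length `d` with components in \{-1, +1\}.
#' @examples
#' set.seed(1)
#' v <- random_bipolar(16)
#' all(v %in% c(-1L, 1L))
#' @export
random_bipolar <- function(d) {
  if (!is_count(d)) {
    stop_hd("`d` must be a positive integer")
  }
  sample(c(-1L, 1L), d, replace = TRUE)
}

check_same_dim <- function(a, b) {
  if (length(a) != length(b)) {
    stop_hd("hypervectors must have the same dimensionality (",
            length(a), " vs ", length(b), ")")
  }
}

#' Bind two hypervectors (element-wise multiplication)
#'
#' Binding combines two vectors into one that is quasi-orthogonal to both
#' inputs. It is self-inverse on bipolar vectors: `hd_bind(v, v)` is the
#' all-ones identity.
#'
#' @param a,b Hypervectors of equal dimensionality.
#' @return Integer vector, the component-wise product. Bipolar inputs give a
#'   bipolar output.
#' @export
hd_bind <- function(a, b) {
  check_same_dim(a, b)
  as.integer(a) * as.integer(b)
}

#' Bundle hypervectors (element-wise addition)
#'
#' Bundling aggregates a set of vectors into a single integer vector that
#' remains similar to each input; it is the superposition operation used to
#' accumulate class vectors.
#'
#' @param vs Non-empty list of hypervectors of equal dimensionality.
#' @return Integer vector, the component-wise sum.
#' @export
hd_bundle <- function(vs) {
  if (!is.list(vs) || length(vs) == 0) {
    stop_hd("`vs` must be a non-empty list of hypervectors")
  }
  d <- length(vs[[1]])
  out <- integer(d)
  for (v in vs) {
    check_same_dim(out, v)
    out <- out + as.integer(v)
  }
  out
}

#' Permute a hypervector (cyclic rotation)
#'
#' Rotates the components of `v` by `p` positions (reduced modulo the
#' dimensionality). Permutation encodes positional information: a rotated
#' vector is quasi-orthogonal to its original, the operation is invertible by
#' rotating by `d - p`, and it distributes over binding and bundling.
#'
#' @param v Hypervector.
#' @param p Integer number of positions; any integer is accepted.
#' @return The rotated vector.
#' @export
hd_permute <- function(v, p) {
  d <- length(v)
  p <- as.integer(p %% d)
  if (p == 0L) {
    return(v)
  }
  v[((seq_len(d) - 1L - p) %% d) + 1L]
}

#' Cosine similarity between hypervectors
#'
#' @param a,b Hypervectors of equal dimensionality.
#' @return The cosine of the angle between `a` and `b`, in \[-1, 1\]. If either
#'   vector has zero norm (class vectors can cancel to zero during
#'   retraining), returns 0 with a warning rather than failing.
#' @export
hd_cosine <- function(a, b) {
  check_same_dim(a, b)
  a <- as.numeric(a)
  b <- as.numeric(b)
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) {
    warning("cosine similarity with a zero vector is undefined; returning 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

#' Generate a family of level hypervectors
#'
#' Builds the ordered associative memory of `L` bipolar level vectors used to
#' encode quantized scalar values. The first level is a random bipolar vector;
#' each subsequent level flips the sign of `N = floor(d / (2 L))` further
#' positions. Flip positions are consumed in consecutive disjoint blocks of a
#' single random permutation of indices, so each position is flipped at most
#' once across the whole family. Consequently adjacent levels are maximally
#' similar while distant levels are quasi-orthogonal, with the exact closed
#' form `cosine(level_i, level_j) = 1 - 2 N |i - j| / d`.
#'
#' @param d Dimensionality (default 10000).
#' @param L Number of levels (1000 for relative abundances in \[0, 100\]; 2 for
#'   presence/absence data).
#' @param seed Optional integer seed; when supplied the family is a pure
#'   function of `(d, L, seed)`.
#' @return An object of class `hd_levels`: a list with the `L x d` integer
#'   matrix `levels` (one level per row) plus `d`, `L`, `N` and `seed`.
#' @examples
#' lv <- generate_levels(d = 100, L = 5, seed = 1)
#' lv$N  # floor(100 / 10) = 10 flips per adjacent level
#' @export
generate_levels <- function(d = 10000, L = 1000, seed = NULL) {
  if (!is_count(d)) stop_hd("`d` must be a positive integer")
  if (!is_count(L)) stop_hd("`L` must be a positive integer")
  if (L >= 2 && d < 2 * L) {
    stop_hd("`d` must be at least 2*L so that adjacent levels differ ",
            "(d = ", d, ", L = ", L, ")")
  }
  N <- if (L == 1) 0L else as.integer(d %/% (2 * L))
  with_seed(seed, {
    base <- random_bipolar(d)
    flip_order <- sample.int(d)
    levels <- matrix(0L, nrow = L, ncol = d)
    levels[1L, ] <- base
    if (L > 1) {
      current <- base
      for (i in seq_len(L - 1L)) {
        block <- flip_order[((i - 1L) * N + 1L):(i * N)]
        current[block] <- -current[block]
        levels[i + 1L, ] <- current
      }
    }
    structure(
      list(levels = levels, d = as.integer(d), L = as.integer(L),
           N = N, seed = seed),
      class = "hd_levels"
    )
  })
}

#' @export
print.hd_levels <- function(x, ...) {
  cat("Level hypervector family\n")
  cat("  dimensionality d:", x$d, "\n")
  cat("  levels L:        ", x$L, "\n")
  cat("  flips/step N:    ", x$N, "\n")
  if (!is.null(x$seed)) cat("  seed:            ", x$seed, "\n")
  invisible(x)
}

#' Save or restore a level family as JSON
#'
#' Only the construction parameters `{d, L, N, seed}` are stored; the vectors
#' themselves are regenerated from the seed on load.
#'
#' @param levels An `hd_levels` object with a non-`NULL` seed.
#' @param path File path.
#' @return `read_levels` returns the regenerated `hd_levels` object.
#' @export
write_levels <- function(levels, path) {
  stopifnot(inherits(levels, "hd_levels"))
  if (is.null(levels$seed)) {
    stop_hd("only seeded level families can be serialized (seed is NULL)")
  }
  jsonlite::write_json(
    list(d = levels$d, L = levels$L, N = levels$N, seed = levels$seed),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_levels
#' @export
read_levels <- function(path) {
  meta <- jsonlite::read_json(path)
  generate_levels(d = meta$d, L = meta$L, seed = meta$seed)
}
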