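# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operations never perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream as-is.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed so independent components (folds,
# levels, generators) consume distinct but reproducible streams. Kept well
# below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483587)
}

stop_hd <- function(...) stop(..., call. = FALSE)

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == floor(x)
}
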