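`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals (multistart
#' perturbations, simulation draws) never disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

## seeds handed to with_seed() must stay below .Machine$integer.max
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(sprintf("non-finite value in `%s`", what), call. = FALSE)
  invisible(x)
}

#' Number of unordered group pairs
#'
#' Count of pairwise comparisons implied by `G` groups, G(G-1)/2 — the
#' number of two-group contrasts a pairwise invariance search (or the
#' alignment loss) must consider for every item parameter.
#'
#' @param G number of groups (integer >= 2).
#' @return integer count of unordered pairs.
#' @examples
#' n_group_pairs(50)  # 1225 comparisons per item parameter
#' @export
n_group_pairs <- function(G) {
  G <- as.integer(G)
  stopifnot(length(G) == 1L, G >= 2L)
  (G * (G - 1L)) %/% 2L
}

## central-difference Jacobian of a vector-valued function
num_jacobian <- function(f, x, h = NULL) {
  h <- h %||% (1e-5 * (1 + abs(x)))
  if (length(h) == 1L) h <- rep(h, length(x))
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- x[j] + h[j]
    xm <- x; xm[j] <- x[j] - h[j]
    J[, j] <- (f(xp) - f(xm)) / (2 * h[j])
  }
  J
}
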