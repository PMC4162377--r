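#' Quadrature settings for integrating out the latent factor
#'
#' The marginal likelihood integrates the latent factor against its normal
#' distribution by Gauss-Hermite quadrature.  The default 21 nodes is a
#' standard accuracy/speed trade-off for single-factor binary-item models;
#' doubling the node count changes converged log-likelihoods only in the
#' 5th decimal on typical data.
#'
#' @param nodes number of Gauss-Hermite nodes (>= 5).
#' @param adaptive must be `FALSE`; per-respondent adaptive recentring is
#'   not implemented — increase `nodes` instead.
#' @return a `quadrature_spec` object.
#' @export
quadrature_spec <- function(nodes = 21L, adaptive = FALSE) {
  nodes <- as.integer(nodes)
  if (length(nodes) != 1L || is.na(nodes) || nodes < 5L)
    stop("`nodes` must be a single integer >= 5", call. = FALSE)
  if (isTRUE(adaptive))
    stop("adaptive quadrature is not implemented; increase `nodes` instead",
         call. = FALSE)
  structure(list(nodes = nodes, adaptive = FALSE), class = "quadrature_spec")
}

## Gauss-Hermite rule rescaled for a N(0,1) integral:
## int f(t) dnorm(t) dt  ~=~  sum_k w[k] f(x[k])   with  t = sqrt(2) x_GH
gh_rule <- function(nodes) {
  gh <- pracma::gaussHermite(nodes)
  list(x = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}
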