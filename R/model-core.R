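## Two-parameter item response model, threshold parameterization, and the
## conversions between the IRT metric (discrimination a, difficulty b) and
## the factor-analytic metric (loading lambda, threshold tau).
##
## Under the logit link the latent-response residual is standard logistic
## (variance pi^2/3); under probit it is standard normal (variance 1).
## These scalings are fixed constants of the link, not tunable.

#' Residual standard deviation fixed by the link
#'
#' The latent-response residual underlying a binary item is standardized to
#' the standard logistic distribution (variance pi^2/3) for the logit link
#' and to the standard normal (variance 1) for probit.
#'
#' @param link `"logit"` or `"probit"`.
#' @return the residual standard deviation (a fixed constant per link).
#' @export
link_residual_sd <- function(link = c("logit", "probit")) {
  link <- match.arg(link)
  switch(link, logit = pi / sqrt(3), probit = 1)
}

link_cdf <- function(link) {
  switch(link, logit = stats::plogis, probit = stats::pnorm,
         stop("unknown link: ", link))
}

#' Item response probability in the IRT metric
#'
#' P(y = 1 | eta) for a binary item with discrimination `a` and difficulty
#' `b`: the logistic (or normal-ogive) function of `a * (eta - b)`.  The
#' curve crosses 0.5 exactly at `eta = b` and is strictly increasing in
#' `eta` when `a > 0`.
#'
#' @param a discrimination.
#' @param b difficulty.
#' @param eta ability (latent factor) value.
#' @param link `"logit"` (default) or `"probit"`.
#' @return probability in (0, 1); vectorized over the inputs.
#' @examples
#' item_response_prob(1.5, 0.7, 0.7)   # 0.5 at eta = b
#' item_response_prob(1, 0, 2)         # plogis(2)
#' @export
item_response_prob <- function(a, b, eta, link = c("logit", "probit")) {
  link <- match.arg(link)
  stop_if_not_finite(a, "a"); stop_if_not_finite(b, "b")
  stop_if_not_finite(eta, "eta")
  link_cdf(link)(a * (eta - b))
}

#' Item response probability in the factor metric
#'
#' P(y = 1 | eta) under the threshold formulation: the binary response is 1
#' when the latent response `lambda * eta + epsilon` exceeds the threshold
#' `tau`, with the residual `epsilon` standardized by the link
#' (see [link_residual_sd()]).  Equivalent to [item_response_prob()] with
#' `a = lambda`, `b = tau / lambda` whenever `lambda != 0`.
#'
#' @param lambda factor loading.
#' @param tau threshold.
#' @param eta ability value.
#' @param link `"logit"` or `"probit"`.
#' @return probability in (0, 1); vectorized.
#' @export
threshold_model_prob <- function(lambda, tau, eta, link = c("logit", "probit")) {
  link <- match.arg(link)
  stop_if_not_finite(lambda, "lambda"); stop_if_not_finite(tau, "tau")
  stop_if_not_finite(eta, "eta")
  link_cdf(link)(lambda * eta - tau)
}

#' Convert factor-metric item parameters to the IRT metric
#'
#' `a = lambda`, `b = tau / lambda`.  The difficulty is undefined for a
#' zero loading (the item carries no information about the factor), in
#' which case an error names the offending entries.
#'
#' @param lambda loadings (vector).
#' @param tau thresholds (vector, recycled against `lambda`).
#' @param labels optional labels used in the zero-loading error message.
#' @return list with components `a` and `b`.
#' @export
factor_to_irt <- function(lambda, tau, labels = NULL) {
  stop_if_not_finite(lambda, "lambda"); stop_if_not_finite(tau, "tau")
  bad <- which(lambda == 0)
  if (length(bad)) {
    lab <- if (is.null(labels)) paste("entry", bad) else labels[bad]
    stop("difficulty undefined for zero loading: ",
         paste(lab, collapse = ", "), call. = FALSE)
  }
  list(a = lambda, b = tau / lambda)
}

#' Convert IRT-metric item parameters to the factor metric
#'
#' `lambda = a`, `tau = a * b`.  Round-trips with [factor_to_irt()]
#' whenever `a != 0`.
#'
#' @param a discriminations.
#' @param b difficulties.
#' @return list with components `lambda` and `tau`.
#' @export
irt_to_factor <- function(a, b) {
  stop_if_not_finite(a, "a"); stop_if_not_finite(b, "b")
  list(lambda = a, tau = a * b)
}
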