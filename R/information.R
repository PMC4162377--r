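## Observed-information (and sandwich) standard errors for a single-group
## marginal ML fit.  The Hessian is obtained by central finite differences
## of the analytic gradient; the sandwich variant uses the outer product
## of per-respondent scores (independent observations).

#' Observed-information covariance and standard errors
#'
#' Covariance = inverse of the negative Hessian of the marginal
#' log-likelihood at the estimate (parameter order: all loadings, then
#' all thresholds).  `type = "sandwich"` returns the robust
#' A^-1 B A^-1 form with B the outer product of per-respondent scores.
#'
#' @param fit a `group_2pl_fit` from [fit_group_2pl()].
#' @param type `"observed"` (default) or `"sandwich"`.
#' @return list with `vcov` and `se` (named `lambda.*` / `tau.*`).
#' @export
observed_information_se <- function(fit, type = c("observed", "sandwich")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "group_2pl_fit"))
  blk <- fit$.blk; rule <- fit$.rule
  P <- length(fit$lambda)
  gr <- function(x) {
    gm <- group_marginal(blk, x[1:P], x[(P + 1):(2 * P)], 0, 1, rule,
                         fit$link, grad = TRUE)
    c(gm$grad$lambda, gm$grad$tau)
  }
  theta <- c(fit$lambda, fit$tau)
  H <- num_jacobian(gr, theta)
  H <- (H + t(H)) / 2
  A <- -H
  nms <- c(paste0("lambda.", fit$items), paste0("tau.", fit$items))
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(A, symmetric = TRUE)
    bad <- which(ev$values <= 0)
    offenders <- unique(unlist(lapply(bad, function(k)
      nms[which(abs(ev$vectors[, k]) > 0.3)])))
    stop("information matrix is not positive definite; offending parameter(s): ",
         paste(offenders, collapse = ", "), call. = FALSE)
  }
  V <- chol2inv(ch)
  if (type == "sandwich") {
    S <- group_marginal(blk, fit$lambda, fit$tau, 0, 1, rule, fit$link,
                        grad = TRUE, scores = TRUE)$scores
    B <- crossprod(S)
    V <- V %*% B %*% V
  }
  dimnames(V) <- list(nms, nms)
  list(vcov = V, se = stats::setNames(sqrt(pmax(diag(V), 0)), nms))
}
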