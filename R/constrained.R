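## Metric and scalar invariance models and the likelihood-ratio chain
## configural -> metric -> scalar.
##
## Identification conventions (chosen so the free-parameter DIFFERENCES
## give the likelihood-ratio df):
##   configural: all P loadings and thresholds free per group; factor
##     N(0, 1) in every group.                    free = 2*P*G
##   metric: loadings shared; thresholds free per group; factor means 0
##     in all groups, variance 1 in group 1 and free in groups 2..G.
##                                                free = P + P*G + (G-1)
##   scalar: loadings and thresholds shared; factor mean/variance (0, 1)
##     in group 1, free in groups 2..G.           free = 2*P + 2*(G-1)
## Differences: configural - metric = (G-1)(P-1),
##              configural - scalar = 2(G-1)(P-1).

#' Free-parameter count for an invariance level
#'
#' Number of free parameters under this package's identification
#' conventions (see Details).  Absolute counts depend on parameterization
#' conventions; the differences between levels are convention-free and
#' equal the degrees of freedom of the likelihood-ratio tests:
#' configural - metric = (G-1)(P-1) and configural - scalar =
#' 2(G-1)(P-1).
#'
#' @param level `"configural"`, `"metric"` or `"scalar"`.
#' @param G number of groups (>= 2).
#' @param P number of items (>= 2).
#' @return integer count.
#' @examples
#' free_parameter_count("configural", 14, 17) -
#'   free_parameter_count("metric", 14, 17)   # 208
#' @export
free_parameter_count <- function(level = c("configural", "metric", "scalar"),
                                 G, P) {
  level <- match.arg(level)
  G <- as.integer(G); P <- as.integer(P)
  stopifnot(G >= 2L, P >= 2L)
  switch(level,
         configural = 2L * P * G,
         metric = P + P * G + (G - 1L),
         scalar = 2L * P + 2L * (G - 1L))
}

#' Fit a metric- or scalar-invariance model
#'
#' Joint multi-group marginal ML under equality constraints: the metric
#' model shares loadings across groups (thresholds free, factor means 0,
#' variances free except the reference); the scalar model shares loadings
#' and thresholds (means and variances free except the reference group,
#' fixed to 0 and 1).  Started from the configural solution.
#'
#' @param data a [response_data()] object.
#' @param level `"metric"` or `"scalar"`.
#' @param quad [quadrature_spec()].
#' @param link `"logit"` or `"probit"`.
#' @param configural optionally a precomputed [fit_configural()] result
#'   used for starting values (fitted internally when absent).
#' @return object of class `constrained_fit` with per-group expanded
#'   `lambda`/`tau`, `alpha`, `psi`, `loglik`, `n_free`.
#' @export
fit_invariance_model <- function(data, level = c("metric", "scalar"),
                                 quad = quadrature_spec(),
                                 link = c("logit", "probit"),
                                 configural = NULL) {
  level <- match.arg(level); link <- match.arg(link)
  stopifnot(inherits(data, "response_data"))
  G <- length(data$groups); P <- length(data$items)
  cf <- configural %||% fit_configural(data, quad, link, se = FALSE)
  blks <- lapply(data$groups, function(g) prep_block(group_block(data, g)))
  rule <- gh_rule(quad$nodes)

  ## parameter packing
  if (level == "metric") {
    ## x = (lambda[P], tau[P*G], logpsi[G-1])
    x0 <- c(rowMeans(cf$lambda), as.numeric(cf$tau), rep(0, G - 1))
    unpack <- function(x) {
      list(lambda = matrix(x[1:P], P, G),
           tau = matrix(x[P + 1:(P * G)], P, G),
           alpha = rep(0, G),
           psi = c(1, exp(x[P + P * G + seq_len(G - 1)])))
    }
    lower <- c(rep(-PARAM_BOUND, P), rep(-PARAM_BOUND, P * G), rep(-6, G - 1))
    upper <- c(rep(PARAM_BOUND, P), rep(PARAM_BOUND, P * G), rep(6, G - 1))
  } else {
    ## x = (lambda[P], tau[P], alpha[G-1], logpsi[G-1])
    x0 <- c(rowMeans(cf$lambda), rowMeans(cf$tau),
            rep(0, G - 1), rep(0, G - 1))
    unpack <- function(x) {
      list(lambda = matrix(x[1:P], P, G),
           tau = matrix(x[P + 1:P], P, G),
           alpha = c(0, x[2 * P + seq_len(G - 1)]),
           psi = c(1, exp(x[2 * P + G - 1 + seq_len(G - 1)])))
    }
    lower <- c(rep(-PARAM_BOUND, 2 * P), rep(-10, G - 1), rep(-6, G - 1))
    upper <- c(rep(PARAM_BOUND, 2 * P), rep(10, G - 1), rep(6, G - 1))
  }

  pack_grad <- function(x, per_group) {
    ## per_group: list over g of grad lists from group_marginal
    if (level == "metric") {
      gl <- Reduce(`+`, lapply(per_group, function(g) g$lambda))
      gt <- unlist(lapply(per_group, function(g) g$tau))
      gp <- vapply(per_group[-1], function(g) g$logpsi, 0)
      c(gl, gt, gp)
    } else {
      gl <- Reduce(`+`, lapply(per_group, function(g) g$lambda))
      gt <- Reduce(`+`, lapply(per_group, function(g) g$tau))
      ga <- vapply(per_group[-1], function(g) g$alpha, 0)
      gp <- vapply(per_group[-1], function(g) g$logpsi, 0)
      c(gl, gt, ga, gp)
    }
  }

  obj <- make_objective(function(x) {
    th <- unpack(x)
    ll <- 0; grads <- vector("list", G)
    for (g in seq_len(G)) {
      gm <- group_marginal(blks[[g]], th$lambda[, g], th$tau[, g],
                           th$alpha[g], th$psi[g], rule, link, grad = TRUE)
      ll <- ll + gm$loglik
      grads[[g]] <- gm$grad
    }
    list(value = -ll, gradient = -pack_grad(x, grads))
  })
  opt <- stats::optim(x0, obj$fn, obj$gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 1000L, factr = 1e4))
  if (opt$convergence != 0)
    stop(sprintf("%s fit did not converge (code %d): %s", level,
                 opt$convergence, opt$message %||% ""), call. = FALSE)
  th <- unpack(opt$par)
  dimnames(th$lambda) <- dimnames(th$tau) <- list(data$items, data$groups)
  structure(
    list(level = level, lambda = th$lambda, tau = th$tau,
         alpha = stats::setNames(th$alpha, data$groups),
         psi = stats::setNames(th$psi, data$groups),
         loglik = -opt$value,
         n_free = free_parameter_count(level, G, P),
         G = G, P = P, link = link,
         groups = data$groups, items = data$items,
         convergence = list(code = opt$convergence, counts = opt$counts)),
    class = "constrained_fit")
}

#' @export
print.constrained_fit <- function(x, ...) {
  cat(sprintf("constrained_fit (%s): %d items x %d groups, loglik %.3f, %d free parameters\n",
              x$level, x$P, x$G, x$loglik, x$n_free))
  invisible(x)
}

model_level <- function(fit) {
  if (inherits(fit, "configural_fit")) "configural" else fit$level
}

model_dims <- function(fit) {
  if (inherits(fit, "configural_fit"))
    c(G = ncol(fit$lambda), P = nrow(fit$lambda))
  else c(G = as.integer(fit$G), P = as.integer(fit$P))
}

#' Likelihood-ratio test of nested invariance models
#'
#' Chi-square = 2 (loglik_general - loglik_restricted), df = difference
#' in free-parameter counts, p from the chi-square upper tail.  The
#' restriction ordering is configural > metric > scalar.
#'
#' @param general the less restricted fit (e.g. configural).
#' @param restricted the nested, more restricted fit.
#' @return list of class `lrt`: `statistic`, `df`, `p.value`, `models`.
#' @export
likelihood_ratio_test <- function(general, restricted) {
  rank <- c(configural = 3, metric = 2, scalar = 1)
  lg <- model_level(general); lr <- model_level(restricted)
  if (rank[lg] <= rank[lr])
    stop(sprintf("'%s' is not nested in '%s'", lr, lg), call. = FALSE)
  dg <- model_dims(general); dr <- model_dims(restricted)
  if (!identical(dg, dr))
    stop("fits have different numbers of groups or items", call. = FALSE)
  llg <- general$loglik; llr <- restricted$loglik
  stat <- 2 * (llg - llr)
  if (stat < -1e-6 * max(1, abs(llg)))
    stop(sprintf(
      "restricted log-likelihood exceeds the general one (chi-square %.6g); fits are inconsistent",
      stat), call. = FALSE)
  stat <- max(stat, 0)
  df <- free_parameter_count(lg, dg["G"], dg["P"]) -
    free_parameter_count(lr, dg["G"], dg["P"])
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 models = c(general = lg, restricted = lr)),
            class = "lrt")
}

#' @export
print.lrt <- function(x, ...) {
  cat(sprintf("%s against %s: chi-square %.3f, df %d, p %.4g\n",
              x$models["restricted"], x$models["general"],
              x$statistic, x$df, x$p.value))
  invisible(x)
}
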