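## Delta-method standard errors for everything the alignment produces.
## The mapping from configural estimates to (alpha, psi, aligned lambda,
## aligned tau) involves an inner argmin, so it is differentiated
## numerically: each configural parameter is perturbed by a central
## difference and the alignment re-solved locally from the base solution
## (warm start; the perturbation is tiny so a single quasi-Newton run
## converges in a few iterations).  The resulting Jacobian is sandwiched
## around the block-diagonal configural covariance (groups independent).

## re-solve the alignment from a warm start for perturbed configural
## parameters; returns the full output vector of the alignment mapping
realign_outputs <- function(lambda0, tau0, result) {
  opt2 <- result$options
  opt2$n_starts <- 1L
  fit2 <- configural_fit(lambda0, tau0, result$group_sizes, result$link,
                         groups = result$groups, items = result$items)
  W <- result$weights
  eng <- loss_engine(lambda0, tau0, W, opt2)
  G <- ncol(lambda0)
  ref <- result$ref_group; free <- result$free_index
  ## warm start at the base solution (fixed-reference parameterization
  ## mirrors align())
  if (opt2$identification == "fixed") {
    x0 <- c(result$alpha[free], log(result$psi[free]))
    expand <- function(x) {
      alpha <- numeric(G); lp <- numeric(G)
      alpha[free] <- x[seq_len(G - 1)]
      lp[free] <- x[G - 1 + seq_len(G - 1)]
      list(alpha = alpha, psi = exp(lp))
    }
    shrink <- function(e) c(e$g_alpha[free], e$g_logpsi[free])
  } else {
    x0 <- c(result$alpha[free], log(result$psi[seq_len(G - 1)]))
    expand <- function(x) {
      alpha <- numeric(G); lp <- numeric(G)
      alpha[free] <- x[seq_len(G - 1)]
      lp[seq_len(G - 1)] <- x[G - 1 + seq_len(G - 1)]
      lp[G] <- -sum(lp[seq_len(G - 1)])
      list(alpha = alpha, psi = exp(lp))
    }
    shrink <- function(e) c(e$g_alpha[free],
                            e$g_logpsi[seq_len(G - 1)] - e$g_logpsi[G])
  }
  obj <- make_objective(function(x) {
    th <- expand(x)
    e <- eng(th$alpha, th$psi, want_grad = TRUE)
    list(value = e$value, gradient = shrink(e))
  })
  G1 <- length(x0) / 2
  opt <- stats::optim(x0, obj$fn, obj$gr, method = "L-BFGS-B",
                      lower = c(rep(-10, G1), rep(-5, G1)),
                      upper = c(rep(10, G1), rep(5, G1)),
                      control = list(maxit = 300L, factr = 1e3))
  th <- expand(opt$par)
  al <- align_transform(lambda0, tau0, th$alpha, th$psi)
  c(th$alpha, th$psi, as.numeric(al$lambda), as.numeric(al$tau))
}

#' Delta-method standard errors for aligned quantities
#'
#' Standard errors (and full covariance) for the estimated group factor
#' means and variances and the aligned loadings and thresholds, obtained
#' by numerically differentiating the full configural-to-aligned mapping
#' (central differences, relative step 1e-5, with the inner optimization
#' warm-started at the base solution) and sandwiching the Jacobian around
#' the configural parameter covariance.  Reference-group pinned
#' quantities get standard error 0.
#'
#' @param result an [align()] result.
#' @param fit the `configural_fit` the result came from; must carry
#'   per-group parameter covariances (`se = TRUE` in [fit_configural()]).
#' @return list of class `aligned_se`: `se_alpha`, `se_psi`, `se_lambda`
#'   and `se_tau` (P x G matrices), `vcov` (full covariance of the output
#'   vector) and `index` locating each block in `vcov`.
#' @export
aligned_standard_errors <- function(result, fit) {
  stopifnot(inherits(result, "alignment_result"),
            inherits(fit, "configural_fit"))
  if (is.null(fit$vcov) || any(vapply(fit$vcov, is.null, TRUE)))
    stop("configural fit carries no parameter covariances; refit with se = TRUE",
         call. = FALSE)
  P <- nrow(fit$lambda); G <- ncol(fit$lambda)
  for (g in seq_len(G)) {
    ev <- eigen(fit$vcov[[g]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("singular configural covariance in group ", fit$groups[g],
           call. = FALSE)
  }
  theta0 <- as.numeric(rbind(fit$lambda, fit$tau))  # per group: lambda, tau
  mapfun <- function(theta) {
    Th <- matrix(theta, 2 * P, G)
    realign_outputs(Th[seq_len(P), , drop = FALSE],
                    Th[P + seq_len(P), , drop = FALSE], result)
  }
  J <- num_jacobian(mapfun, theta0)
  V0 <- matrix(0, 2 * P * G, 2 * P * G)
  for (g in seq_len(G)) {
    idx <- (g - 1) * 2 * P + seq_len(2 * P)
    V0[idx, idx] <- fit$vcov[[g]]
  }
  V <- J %*% V0 %*% t(J)
  V <- (V + t(V)) / 2
  se <- sqrt(pmax(diag(V), 0))
  idx_alpha <- seq_len(G)
  idx_psi <- G + seq_len(G)
  idx_lambda <- 2 * G + seq_len(P * G)
  idx_tau <- 2 * G + P * G + seq_len(P * G)
  se_alpha <- stats::setNames(se[idx_alpha], result$groups)
  se_psi <- stats::setNames(se[idx_psi], result$groups)
  if (result$options$identification == "fixed") {
    se_alpha[result$ref_group] <- 0
    se_psi[result$ref_group] <- 0
  }
  structure(
    list(se_alpha = se_alpha, se_psi = se_psi,
         se_lambda = matrix(se[idx_lambda], P, G,
                            dimnames = dimnames(result$lambda)),
         se_tau = matrix(se[idx_tau], P, G,
                         dimnames = dimnames(result$tau)),
         vcov = V,
         index = list(alpha = idx_alpha, psi = idx_psi,
                      lambda = idx_lambda, tau = idx_tau)),
    class = "aligned_se")
}
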