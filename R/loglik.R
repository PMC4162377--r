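## Marginal likelihood engine for one group of the multi-group binary
## response model, in the factor metric: P(y=1|eta) = F(lambda*eta - tau),
## eta ~ N(alpha, psi), integrated by Gauss-Hermite quadrature.
##
## Everything downstream (configural/metric/scalar fits, the alignment
## likelihood-equality check) is built on these two functions.  Missing
## responses contribute nothing to their item's likelihood term
## (missing-at-random full-information ML).

CLIP <- 1e-12  # probability clip inside likelihood code only

## Precompute the fixed per-group pieces: Y0 (NA -> 0), mask M, n.
prep_block <- function(Y) {
  M <- 1 - is.na(Y)
  Y0 <- Y
  Y0[is.na(Y0)] <- 0
  storage.mode(Y0) <- "double"
  storage.mode(M) <- "double"
  list(Y0 = Y0, M = M, n = nrow(Y))
}

## Marginal log-likelihood for one group.
## blk: prep_block() output; lambda,tau: length-P; alpha,psi: scalars.
## Returns loglik, and when grad=TRUE also the gradient wrt
## (lambda, tau, alpha, log psi) plus posterior weights for score use.
group_marginal <- function(blk, lambda, tau, alpha, psi, rule,
                           link = "logit", grad = FALSE, scores = FALSE) {
  eta <- alpha + sqrt(psi) * rule$x          # K nodes
  K <- length(eta)
  P <- length(lambda)
  Z <- tcrossprod(lambda, eta) - tau         # P x K  (lambda_p*eta_k - tau_p)
  if (link == "logit") {
    logP1 <- stats::plogis(Z, log.p = TRUE)
    logP0 <- stats::plogis(-Z, log.p = TRUE)
  } else {
    logP1 <- stats::pnorm(Z, log.p = TRUE)
    logP0 <- stats::pnorm(-Z, log.p = TRUE)
  }
  logP1 <- pmax(logP1, log(CLIP)); logP0 <- pmax(logP0, log(CLIP))
  LL <- blk$Y0 %*% logP1 + (blk$M - blk$Y0) %*% logP0   # n x K
  A <- sweep(LL, 2, log(rule$w), `+`)
  m <- apply(A, 1, max)
  lli <- m + log(rowSums(exp(A - m)))
  out <- list(loglik = sum(lli), loglik_i = lli)
  if (!grad && !scores) return(out)

  R <- exp(A - lli)                          # n x K posterior node weights
  ## d logF / dz evaluated at Z, for y=1 and y=0 branches
  if (link == "logit") {
    P1 <- stats::plogis(Z)
    TY <- crossprod(blk$Y0, R)               # P x K
    TM <- crossprod(blk$M, R)
    E <- TY - P1 * TM                        # sum_i r_ik * dloglik/dz
  } else {
    u1 <- exp(stats::dnorm(Z, log = TRUE) - logP1)
    u0 <- -exp(stats::dnorm(Z, log = TRUE) - logP0)
    TY <- crossprod(blk$Y0, R)
    TM <- crossprod(blk$M, R)
    E <- TY * u1 + (TM - TY) * u0
  }
  g_lambda <- drop(E %*% eta)
  g_tau <- -rowSums(E)
  g_alpha <- sum(lambda * rowSums(E))
  g_logpsi <- sum(lambda * drop(E %*% ((eta - alpha) / 2)))
  out$grad <- list(lambda = g_lambda, tau = g_tau,
                   alpha = g_alpha, logpsi = g_logpsi)
  if (scores) {
    ## per-respondent score wrt (lambda, tau): n x 2P
    if (link == "logit") {
      D1 <- 1 - P1; D0 <- -P1
    } else {
      phi <- exp(stats::dnorm(Z, log = TRUE))
      D1 <- phi / pmax(exp(logP1), CLIP)
      D0 <- -phi / pmax(exp(logP0), CLIP)
    }
    S_lam <- matrix(0, blk$n, P)
    S_tau <- matrix(0, blk$n, P)
    for (k in seq_len(K)) {
      ## per-person, per-item dloglik/dz at node k, posterior-weighted
      Wk <- R[, k]
      Tk <- sweep(blk$Y0, 2, D1[, k], `*`) +
        sweep(blk$M - blk$Y0, 2, D0[, k], `*`)
      S_lam <- S_lam + (Tk * Wk) * eta[k]
      S_tau <- S_tau - Tk * Wk
    }
    out$scores <- cbind(S_lam, S_tau)
  }
  out
}
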