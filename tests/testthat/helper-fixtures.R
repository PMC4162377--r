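# Fixture builders shared across the suite.  Everything is generated in
# code under fixed seeds; no stored data.

# Invariant two-group, ten-item scenario: invariant parameters pushed to
# the configural scale by the inverse alignment transformation under
# group distributions (0, 1) and (-1, 2).
invariant_twogroup_fit <- function(n_per_group = 1000) {
  lam <- seq(0.8, 1.7, length.out = 10)
  tau <- seq(-1.2, 1.2, length.out = 10)
  inv <- irtalign:::align_transform_inverse(cbind(lam, lam),
                                            cbind(tau, tau),
                                            alpha = c(0, -1),
                                            psi = c(1, 2))
  configural_fit(inv$lambda, inv$tau,
                 group_sizes = rep(n_per_group, 2),
                 groups = c("g1", "g2"))
}

# small simulated multi-group dataset
small_data <- function(G = 3, P = 5, n = 300, means = NULL, vars = NULL,
                       seed = 42, noninv = list(threshold_pct = 0,
                                                loading_pct = 0)) {
  pop <- make_population(G, P, noninv = noninv,
                         group_means = means %||% rep(0, G),
                         group_vars = vars %||% rep(1, G),
                         seed = seed)
  generate_responses(pop, rep(n, G), seed = seed + 1)
}

# alignment options tuned for quick property tests (fewer starts; the
# fixtures here have well-behaved single-basin losses)
quick_opts <- function(seed = 1, ...) {
  alignment_options(n_starts = 5, seed = seed, ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# brute-force total-loss oracle: naive double loop over items and
# unordered group pairs, mirroring the loss definition independently of
# the vectorized implementation
oracle_total_loss <- function(lambda0, tau0, alpha, psi, W,
                              options = alignment_options()) {
  tr <- align_transform(lambda0, tau0, alpha, psi)
  P <- nrow(lambda0); G <- ncol(lambda0)
  total <- 0
  for (p in seq_len(P)) for (g in seq_len(G - 1)) for (h in (g + 1):G) {
    S <- if (options$difference_scaling == "lambda-geomean")
      max(sqrt(abs(tr$lambda[p, g] * tr$lambda[p, h])), 0.05) else 1
    total <- total +
      W[g, h] * clf((tr$lambda[p, g] - tr$lambda[p, h]) / S,
                    options$epsilon, options$clf) +
      W[g, h] * clf(tr$tau[p, g] - tr$tau[p, h],
                    options$epsilon, options$clf)
  }
  total
}

# high-resolution quadrature log-likelihood oracle (direct product over
# persons and items, 501 nodes)
oracle_loglik <- function(Y, lambda, tau, alpha = 0, psi = 1,
                          link = "logit", nodes = 501) {
  gh <- pracma::gaussHermite(nodes)
  eta <- alpha + sqrt(psi) * sqrt(2) * gh$x
  w <- gh$w / sqrt(pi)
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    Lk <- w
    for (p in seq_len(ncol(Y))) {
      y <- Y[i, p]
      if (is.na(y)) next
      pr <- threshold_model_prob(lambda[p], tau[p], eta, link)
      Lk <- Lk * (if (y == 1) pr else 1 - pr)
    }
    ll <- ll + log(sum(Lk))
  }
  ll
}
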