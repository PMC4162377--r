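test_that("single-group marginal log-likelihood matches a 501-node brute-force oracle", {
  set.seed(7)
  Y <- matrix(rbinom(10, 1, 0.5), nrow = 5, ncol = 2)
  Y[2, 1] <- NA  # missing cell must drop out of its item's term
  lam <- c(1.2, 0.8); tau <- c(0.3, -0.5)
  for (link in c("logit", "probit")) {
    ll <- irtalign:::group_loglik_at(Y, lam, tau, link = link,
                                     quad = quadrature_spec(501))
    expect_equal(ll, oracle_loglik(Y, lam, tau, link = link),
                 tolerance = 1e-6)
  }
  # a non-trivial factor distribution too
  ll2 <- irtalign:::group_loglik_at(Y, lam, tau, alpha = -0.4, psi = 1.7,
                                    quad = quadrature_spec(501))
  expect_equal(ll2, oracle_loglik(Y, lam, tau, alpha = -0.4, psi = 1.7),
               tolerance = 1e-6)
})

test_that("duplicating every respondent doubles the log-likelihood exactly", {
  dat <- small_data(G = 2, P = 4, n = 80)
  Y <- irtalign:::group_block(dat, "g1")
  f1 <- fit_group_2pl(Y, se = FALSE)
  ll2 <- irtalign:::group_loglik_at(rbind(Y, Y), f1$lambda, f1$tau)
  expect_equal(ll2, 2 * f1$loglik, tolerance = 1e-8)
})

test_that("group fit recovers generating parameters at n = 2000", {
  pop <- make_population(2, 5, seed = 3)
  dat <- generate_responses(pop, c(2000, 50), seed = 4)
  fit <- fit_group_2pl(irtalign:::group_block(dat, "g1"), se = TRUE)
  se <- sqrt(diag(fit$vcov))
  # within 3 standard errors of truth, coordinate-wise
  expect_true(all(abs(fit$lambda - pop$lambda[, 1]) <
                    3 * se[1:5] + 1e-8))
  expect_true(all(abs(fit$tau - pop$tau[, 1]) < 3 * se[6:10] + 1e-8))
})

test_that("an all-0 or all-1 item column triggers a boundary warning naming the item", {
  Y <- cbind(Y1 = rep(1, 30), Y2 = rbinom(30, 1, 0.5))
  expect_warning(fit_group_2pl(Y, se = FALSE), "Y1")
})

test_that("configural log-likelihood is the sum over independent groups and is order-invariant", {
  dat <- small_data(G = 3, P = 4, n = 120, means = c(0, 0.5, -0.5))
  cf <- fit_configural(dat, se = FALSE)
  expect_equal(cf$loglik, sum(cf$loglik_by_group), tolerance = 1e-10)
  # permute group order in the data: same total, same per-group estimates
  idx <- order(as.integer(dat$group), decreasing = TRUE)
  dat2 <- response_data(dat$y[idx, ], as.character(dat$group)[idx])
  cf2 <- fit_configural(dat2, se = FALSE)
  expect_equal(cf2$loglik, cf$loglik, tolerance = 1e-6)
  expect_equal(cf2$lambda[, dat$groups], cf$lambda, tolerance = 1e-4)
})

test_that("doubling quadrature nodes barely moves the converged log-likelihood", {
  dat <- small_data(G = 2, P = 4, n = 150)
  Y <- irtalign:::group_block(dat, "g1")
  f21 <- fit_group_2pl(Y, quadrature_spec(21), se = FALSE)
  f42 <- fit_group_2pl(Y, quadrature_spec(42), se = FALSE)
  expect_lt(abs(f21$loglik - f42$loglik) / abs(f42$loglik), 1e-4)
})

test_that("quadrature spec validates its arguments", {
  expect_error(quadrature_spec(3), ">= 5")
  expect_error(quadrature_spec(21, adaptive = TRUE), "not implemented")
  expect_equal(quadrature_spec()$nodes, 21L)
})

test_that("mean absolute bias of loadings and thresholds is small at n = 2000", {
  # parameter recovery across replications of configural data
  pop <- make_population(2, 5, group_means = c(0, 0.3), seed = 9)
  th <- irtalign:::align_transform_inverse(pop$lambda, pop$tau,
                                           pop$alpha, pop$psi)
  n_reps <- 12
  bias_l <- bias_t <- 0
  for (r in seq_len(n_reps)) {
    dat <- generate_responses(pop, c(2000, 2000), seed = 100 + r)
    cf <- fit_configural(dat, se = FALSE)
    bias_l <- bias_l + (cf$lambda - th$lambda) / n_reps
    bias_t <- bias_t + (cf$tau - th$tau) / n_reps
  }
  expect_lt(mean(abs(bias_l)), 0.05)
  expect_lt(mean(abs(bias_t)), 0.05)
})
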