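test_that("population perturbation ledger has the promised sizes and reproducibility", {
  pop <- make_population(28, 17,
                         noninv = list(threshold_pct = 33,
                                       loading_pct = 11,
                                       magnitude = c(0.3, 1)),
                         seed = 8)
  expect_identical(sum(pop$ledger$family == "threshold"),
                   as.integer(round(0.33 * 28 * 17)))
  expect_identical(sum(pop$ledger$family == "loading"),
                   as.integer(round(0.11 * 28 * 17)))
  expect_true(all(abs(pop$ledger$delta) >= 0.3 &
                    abs(pop$ledger$delta) <= 1))
  pop2 <- make_population(28, 17,
                          noninv = list(threshold_pct = 33,
                                        loading_pct = 11,
                                        magnitude = c(0.3, 1)),
                          seed = 8)
  expect_identical(pop$lambda, pop2$lambda)
  expect_identical(pop$tau, pop2$tau)
  # 0/0: all groups share the base parameters exactly
  pop0 <- make_population(4, 6, seed = 9)
  expect_true(all(pop0$lambda == pop0$lambda[, 1]))
  expect_identical(nrow(pop0$ledger), 0L)
})

test_that("generated data have the right shape, determinism, and marginal rates", {
  pop <- make_population(3, 4, group_means = c(0, 0.8, -0.5), seed = 12)
  dat <- generate_responses(pop, c(30, 20, 10), seed = 13)
  expect_identical(dim(dat$y), c(60L, 4L))
  expect_identical(dat$group_sizes, c(30L, 20L, 10L))
  dat2 <- generate_responses(pop, c(30, 20, 10), seed = 13)
  expect_identical(dat$y, dat2$y)
  # empirical item proportions match the quadrature-integrated marginal
  big <- generate_responses(pop, c(100000, 5, 5), seed = 14)
  Y1 <- irtalign:::group_block(big, "g1")
  gh <- irtalign:::gh_rule(101)
  for (p in 1:4) {
    marg <- sum(gh$w * threshold_model_prob(pop$lambda[p, 1],
                                            pop$tau[p, 1], gh$x))
    expect_equal(mean(Y1[, p]), marg, tolerance = 0.005)
  }
})

test_that("mean correlation: exact match, sign flip, and a hand-computed case", {
  true <- c(0, 1, 2)
  expect_equal(mean_correlation(true, rbind(true, true)), 1)
  expect_equal(mean_correlation(true, -true), -1)
  est <- c(0.1, 0.8, 2.4)
  expect_equal(mean_correlation(true, est), cor(true, est))
  expect_equal(mean_correlation(true, rbind(true, -true)), 0)
  expect_error(mean_correlation(c(1, 1, 1), est), "zero variance")
})

test_that("Monte Carlo harness recovers invariant-population means and is seed-stable", {
  pop <- make_population(5, 6,
                         group_means = c(0, 0.4, 0.9, -0.3, 1.3),
                         seed = 17)
  mc <- run_monte_carlo(pop, rep(400, 5), n_reps = 2,
                        options = quick_opts(), seed = 18)
  expect_identical(mc$n_ok, 2L)
  expect_gte(mc$mean_correlation, 0.98)
  expect_true(all(abs(mc$bias_alpha) < 0.15))
  mc2 <- run_monte_carlo(pop, rep(400, 5), n_reps = 2,
                         options = quick_opts(), seed = 18)
  expect_identical(mc$est_alpha, mc2$est_alpha)
  # a single replication reduces to that fit's correlation
  mc1 <- run_monte_carlo(pop, rep(400, 5), n_reps = 1,
                         options = quick_opts(), seed = 19)
  expect_equal(mc1$mean_correlation,
               cor(pop$alpha, mc1$est_alpha[1, ]))
})

test_that("promoting an alignment result to a population round-trips its parameters", {
  fit <- invariant_twogroup_fit()
  res <- align(fit, quick_opts())
  pop <- as_population(res)
  expect_equal(pop$lambda, res$lambda)
  expect_equal(pop$alpha, res$alpha)
  dat <- generate_responses(pop, c(50, 50), seed = 1)
  expect_identical(nrow(dat$y), 100L)
})
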