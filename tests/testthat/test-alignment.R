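test_that("alignment transform is the identity at (0, 1) and rejects psi <= 0", {
  l0 <- matrix(runif(6, 0.5, 2), 3, 2); t0 <- matrix(rnorm(6), 3, 2)
  tr <- align_transform(l0, t0, c(0, 0), c(1, 1))
  expect_equal(tr$lambda, l0)
  expect_equal(tr$tau, t0)
  expect_error(align_transform(l0, t0, c(0, 0), c(1, 0)), "positive")
})

test_that("transformed parameters reproduce the configural likelihood for any (alpha, psi)", {
  # the foundational identity of the method
  dat <- small_data(G = 2, P = 4, n = 60, seed = 15)
  Y <- irtalign:::group_block(dat, "g1")
  l0 <- runif(4, 0.5, 2); t0 <- rnorm(4)
  base <- irtalign:::group_loglik_at(Y, l0, t0, 0, 1)
  set.seed(16)
  for (i in 1:100) {
    a <- rnorm(1); p <- exp(rnorm(1, 0, 0.5))
    tr <- align_transform(l0, t0, a, p)
    expect_equal(irtalign:::group_loglik_at(Y, tr$lambda, tr$tau, a, p),
                 base, tolerance = 1e-8)
  }
})

test_that("inverse transform round-trips through the forward transform", {
  lam <- seq(0.8, 1.7, length.out = 10); tau <- seq(-1.2, 1.2, length.out = 10)
  inv <- irtalign:::align_transform_inverse(cbind(lam, lam), cbind(tau, tau),
                                            c(0, -1), c(1, 2))
  back <- align_transform(inv$lambda, inv$tau, c(0, -1), c(1, 2))
  expect_equal(back$lambda, cbind(lam, lam), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(back$tau, cbind(tau, tau), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("component loss function: even, increasing in |x|, known values", {
  expect_equal(clf(0), 0.1)                       # epsilon^(1/4)
  expect_equal(clf(1), 1.0000250, tolerance = 1e-7)
  expect_equal(clf(0, form = "square-root"), 0.01)
  set.seed(5)
  x <- rnorm(100, sd = 2)
  expect_equal(clf(x), clf(-x))
  xs <- sort(abs(x))
  expect_true(all(diff(clf(xs)) > 0))
})

test_that("pairwise weights: sqrt-product, unit, symmetry", {
  W <- pair_weights(c(100, 100, 100))
  expect_true(all(W == 100))
  expect_true(all(pair_weights(c(3, 7), "unit") == 1))
  W2 <- pair_weights(c(10, 40, 90))
  expect_equal(W2, t(W2))
  expect_equal(W2[1, 2], sqrt(10 * 40))
})

test_that("total loss equals the brute-force double-loop oracle", {
  set.seed(2)
  for (rep in 1:5) {
    G <- sample(2:5, 1); P <- sample(2:4, 1)
    l0 <- matrix(runif(P * G, 0.5, 2), P, G)
    t0 <- matrix(rnorm(P * G), P, G)
    al <- runif(G, -1, 1); ps <- exp(runif(G, -0.5, 0.5))
    W <- pair_weights(sample(10:50, G))
    for (scaling in c("lambda-geomean", "none")) {
      opt <- alignment_options(difference_scaling = scaling)
      expect_equal(as.numeric(total_loss(l0, t0, al, ps, W, opt)),
                   oracle_total_loss(l0, t0, al, ps, W, opt),
                   tolerance = 1e-10)
    }
  }
})

test_that("perfect invariance attains the loss floor and perturbation increases it", {
  P <- 4; G <- 3
  l0 <- matrix(rep(runif(P, 0.8, 1.5), G), P, G)
  t0 <- matrix(rep(rnorm(P), G), P, G)
  opt <- alignment_options()
  floor_val <- 2 * P * n_group_pairs(G) * clf(0)
  f0 <- total_loss(l0, t0, rep(0, G), rep(1, G),
                   matrix(1, G, G), opt)
  expect_equal(as.numeric(f0), floor_val, tolerance = 1e-9)
  # perturbing one threshold strictly increases the loss
  t1 <- t0; t1[2, 3] <- t1[2, 3] + 0.4
  f1 <- total_loss(l0, t1, rep(0, G), rep(1, G), matrix(1, G, G), opt)
  expect_gt(as.numeric(f1), as.numeric(f0))
  # the floor is a global lower bound
  expect_gte(as.numeric(f1), floor_val)
})

test_that("aligning the invariant two-group scenario recovers mean -1 and variance 2", {
  fit <- invariant_twogroup_fit()
  res <- align(fit, alignment_options(seed = 1))
  expect_equal(unname(res$alpha[2]), -1, tolerance = 1e-3)
  expect_equal(unname(res$psi[2]), 2, tolerance = 1e-3)
  expect_identical(unname(res$alpha[1]), 0)
  expect_identical(unname(res$psi[1]), 1)
  # at the optimum every difference is zero: the loss floor
  floor_val <- 2 * 10 * 1 * 1000 * clf(0)
  expect_equal(res$loss, floor_val, tolerance = 1e-6 * floor_val)
})

test_that("alignment is deterministic under a fixed seed", {
  dat <- small_data(G = 3, P = 4, n = 150, means = c(0, 0.5, -0.3),
                    seed = 27)
  cf <- fit_configural(dat, se = FALSE)
  r1 <- align(cf, quick_opts(seed = 99))
  r2 <- align(cf, quick_opts(seed = 99))
  expect_identical(r1$alpha, r2$alpha)
  expect_identical(r1$psi, r2$psi)
  expect_identical(r1$loss, r2$loss)
  # and never worse than the configural starting point
  W <- pair_weights(cf$group_sizes)
  l_start <- total_loss(cf$lambda, cf$tau, rep(0, 3), rep(1, 3), W,
                        r1$options)
  expect_lte(r1$loss, as.numeric(l_start) + 1e-9)
})

test_that("loss decomposition by item and group conserves the total", {
  dat <- small_data(G = 3, P = 5, n = 200, means = c(0, 0.6, -0.4),
                    seed = 31)
  cf <- fit_configural(dat, se = FALSE)
  res <- align(cf, quick_opts(seed = 2))
  lc <- loss_contributions(res)
  expect_equal(sum(lc$by_item$total), res$loss, tolerance = 1e-9 * res$loss)
  expect_equal(sum(lc$by_group$group_share), res$loss,
               tolerance = 1e-9 * res$loss)
  expect_equal(sum(lc$by_item$loading), res$loss_loading,
               tolerance = 1e-9 * max(1, res$loss_loading))
})

test_that("an item with injected DIF has the largest loss contribution", {
  # 5 items, one with a large threshold shift in two groups
  P <- 5; G <- 4
  lam <- matrix(rep(seq(0.9, 1.5, length.out = P), G), P, G)
  tau <- matrix(rep(seq(-1, 1, length.out = P), G), P, G)
  tau[3, 2] <- tau[3, 2] + 1.2
  tau[3, 4] <- tau[3, 4] - 0.8
  fit <- configural_fit(lam, tau, rep(500, G))
  res <- align(fit, quick_opts(seed = 7))
  lc <- loss_contributions(res)
  expect_identical(which.max(lc$by_item$total), 3L)
})

test_that("reference-group choice only re-anchors the solution", {
  # analytic invariant 3-group construction (the re-anchoring identity is
  # exact when the optimum zeroes every pairwise difference)
  lam <- seq(0.9, 1.6, length.out = 6); tau <- seq(-1, 1, length.out = 6)
  inv <- irtalign:::align_transform_inverse(
    cbind(lam, lam, lam), cbind(tau, tau, tau),
    alpha = c(0, 0.5, -0.3), psi = c(1, 1.3, 0.8))
  cf <- configural_fit(inv$lambda, inv$tau, rep(400, 3))
  r1 <- align(cf, quick_opts(seed = 3))
  r2 <- align(cf, quick_opts(seed = 3, ref_group = 2L))
  # affine re-anchoring: alpha' = (alpha - alpha_2)/sqrt(psi_2), psi' = psi/psi_2
  expect_equal(unname((r1$alpha - r1$alpha[2]) / sqrt(r1$psi[2])),
               unname(r2$alpha), tolerance = 1e-4)
  expect_equal(unname(r1$psi / r1$psi[2]), unname(r2$psi),
               tolerance = 1e-4)
})
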