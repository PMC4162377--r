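test_that("response probability crosses 0.5 at eta = b for any finite a, b", {
  cases <- expand.grid(a = c(-2, 0.3, 1, 4), b = c(-3, 0, 0.7, 2))
  for (link in c("logit", "probit"))
    for (i in seq_len(nrow(cases)))
      expect_equal(item_response_prob(cases$a[i], cases$b[i], cases$b[i],
                                      link), 0.5)
})

test_that("logit and probit curves match direct link evaluations", {
  expect_equal(item_response_prob(1, 0, 2), plogis(2), tolerance = 1e-6)
  expect_equal(item_response_prob(1, 0, 2), 0.880797, tolerance = 1e-6)
  expect_equal(item_response_prob(2, 1, 0), 0.119203, tolerance = 1e-6)
  expect_equal(threshold_model_prob(1, 0, 1, "probit"), pnorm(1),
               tolerance = 1e-12)
  expect_equal(threshold_model_prob(1, 0, 1, "probit"), 0.841345,
               tolerance = 1e-6)
})

test_that("probabilities are strictly inside (0,1) and increasing in eta for a > 0", {
  # range chosen so the probit tail stays away from double rounding to 1
  eta <- seq(-5, 5, length.out = 41)
  for (link in c("logit", "probit")) {
    p <- item_response_prob(1.5, 0.3, eta, link)
    expect_true(all(p > 0 & p < 1))
    expect_true(all(diff(p) > 0))
  }
})

test_that("non-finite inputs are rejected", {
  expect_error(item_response_prob(NA, 0, 1), "non-finite")
  expect_error(item_response_prob(1, Inf, 1), "non-finite")
  expect_error(threshold_model_prob(1, 0, NaN), "non-finite")
})

test_that("threshold and IRT formulations agree under the parameter conversion", {
  expect_equal(threshold_model_prob(2, 1, 0.3),
               item_response_prob(2, 0.5, 0.3))
  # crossing point: P = 0.5 exactly when lambda * eta = tau
  expect_equal(threshold_model_prob(1.7, 0.85, 0.5), 0.5)
  set.seed(11)
  for (i in 1:1000) {
    lam <- runif(1, -3, 3); if (abs(lam) < 1e-3) lam <- 1
    tau <- runif(1, -3, 3); eta <- runif(1, -3, 3)
    link <- sample(c("logit", "probit"), 1)
    cv <- factor_to_irt(lam, tau)
    expect_equal(threshold_model_prob(lam, tau, eta, link),
                 item_response_prob(cv$a, cv$b, eta, link),
                 tolerance = 1e-12)
  }
})

test_that("factor/IRT conversions are exact inverses away from lambda = 0", {
  expect_identical(factor_to_irt(1, 0), list(a = 1, b = 0))
  expect_equal(factor_to_irt(2, 1), list(a = 2, b = 0.5))
  expect_equal(irt_to_factor(2, 0.5), list(lambda = 2, tau = 1))
  rt <- factor_to_irt(irt_to_factor(1.3, -0.4)$lambda,
                      irt_to_factor(1.3, -0.4)$tau)
  expect_equal(rt, list(a = 1.3, b = -0.4))
})

test_that("zero loading makes the difficulty undefined, with a named error", {
  expect_error(factor_to_irt(0, 1), "zero loading")
  expect_error(factor_to_irt(c(1, 0), c(0, 1), labels = c("Y1/g2", "Y2/g2")),
               "Y2/g2")
  # representable on the factor side
  expect_equal(irt_to_factor(0, 3)$lambda, 0)
})

test_that("link residual scalings are the fixed constants of each link", {
  expect_equal(link_residual_sd("logit"), pi / sqrt(3))
  expect_equal(link_residual_sd("probit"), 1)
})
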