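# Post-alignment inference: delta-method SEs, invariant-set detection,
# non-invariance rates, factor-mean ranking.

# one moderately sized aligned analysis shared across this file
report_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dat <- small_data(G = 3, P = 4, n = 800,
                        means = c(0, 0.6, -0.4), vars = c(1, 1.2, 0.9),
                        seed = 81)
      cf <- fit_configural(dat, se = TRUE)
      res <- align(cf, quick_opts(seed = 82))
      ses <- aligned_standard_errors(res, cf)
      cache <<- list(dat = dat, cf = cf, res = res, ses = ses)
    }
    cache
  }
})

test_that("delta-method SEs: pinned reference, nonnegativity, sane magnitudes", {
  fx <- report_fixture()
  expect_identical(unname(fx$ses$se_alpha[1]), 0)
  expect_identical(unname(fx$ses$se_psi[1]), 0)
  expect_true(all(fx$ses$se_alpha >= 0))
  expect_true(all(fx$ses$se_lambda >= 0))
  # group means at n = 800 should have SEs in a plausible band
  expect_true(all(fx$ses$se_alpha[-1] > 0.01 & fx$ses$se_alpha[-1] < 0.3))
  expect_error(aligned_standard_errors(fx$res, fit_configural(
    fx$dat, se = FALSE)), "covariances")
})

test_that("delta-method SEs agree with a parametric-bootstrap oracle", {
  # bootstrap the full pipeline from the estimated population; reduced
  # replication count, so agreement is asserted within 20%
  fx <- report_fixture()
  pop <- as_population(fx$res)
  B <- 80
  boot_alpha <- matrix(NA_real_, B, 3)
  for (b in seq_len(B)) {
    db <- generate_responses(pop, fx$dat$group_sizes, seed = 9000 + b)
    cb <- fit_configural(db, se = FALSE)
    rb <- align(cb, quick_opts(seed = b))
    boot_alpha[b, ] <- rb$alpha[fx$res$groups]
  }
  sd_boot <- apply(boot_alpha, 2, sd)[-1]
  expect_equal(unname(fx$ses$se_alpha[-1]), unname(sd_boot),
               tolerance = 0.20)
})

test_that("invariant-set detection flags an injected threshold shift and not clean cells", {
  # analytic configural construction: exact parameters plus one large
  # threshold shift in group 3, item 2; small jitter stands in for noise
  set.seed(91)
  P <- 5; G <- 4; n <- 2000
  reps <- 20; hit <- 0; false_flags <- 0; clean_cells <- 0
  base_lam <- seq(0.9, 1.5, length.out = P)
  base_tau <- seq(-1, 1, length.out = P)
  pop <- make_population(G, P,
                         base_params = list(lambda = base_lam,
                                            tau = base_tau),
                         group_means = c(0, 0.3, -0.2, 0.5), seed = 92)
  pop$tau[2, 3] <- pop$tau[2, 3] + 1.0   # the DIF cell
  for (r in seq_len(reps)) {
    dat <- generate_responses(pop, rep(n, G), seed = 9200 + r)
    cf <- fit_configural(dat, se = TRUE)
    res <- align(cf, quick_opts(seed = r))
    ses <- aligned_standard_errors(res, cf)
    fl <- detect_invariant_sets(res, ses, alpha_level = 0.01)
    hit <- hit + fl$threshold$flagged[2, 3]
    clean <- fl$threshold$flagged[-2, ]
    false_flags <- false_flags + sum(clean)
    clean_cells <- clean_cells + length(clean)
  }
  expect_gte(hit / reps, 0.9)               # power at shift 1.0, n = 2000
  expect_lte(false_flags / clean_cells, 0.05)  # ~ 2 x alpha + slack
})

test_that("alpha -> 0 flags nothing; flag sets partition the groups", {
  fx <- report_fixture()
  fl0 <- detect_invariant_sets(fx$res, fx$ses, alpha_level = 1e-12)
  expect_true(all(!fl0$threshold$flagged))
  expect_true(all(!fl0$loading$flagged))
  fl <- detect_invariant_sets(fx$res, fx$ses, alpha_level = 0.01)
  for (p in 1:4) {
    s <- fl$threshold$sets[[p]]
    expect_setequal(c(s$invariant, s$flagged), fx$res$groups)
    expect_length(intersect(s$invariant, s$flagged), 0)
  }
  # deterministic given identical inputs
  fl2 <- detect_invariant_sets(fx$res, fx$ses, alpha_level = 0.01)
  expect_identical(fl$threshold$flagged, fl2$threshold$flagged)
})

test_that("non-invariance summary arithmetic and the 25% rule of thumb", {
  fx <- report_fixture()
  fl <- detect_invariant_sets(fx$res, fx$ses, 0.01)
  ns <- noninvariance_summary(fl)
  expect_equal(ns$average_pct, (ns$threshold_pct + ns$loading_pct) / 2)
  # constructed flag objects at the extremes
  mkflags <- function(rate) {
    f <- fl
    f$threshold$flagged[] <- rate == 1
    f$loading$flagged[] <- rate == 1
    f
  }
  all0 <- noninvariance_summary(mkflags(0))
  expect_equal(all0$average_pct, 0)
  expect_identical(all0$verdict, "trustworthy")
  all1 <- noninvariance_summary(mkflags(1))
  expect_equal(all1$average_pct, 100)
  expect_identical(all1$verdict, "run Monte Carlo")
})

test_that("threshold 33% and loading 11% average to 22% and pass the rule", {
  fx <- report_fixture()
  fl <- detect_invariant_sets(fx$res, fx$ses, 0.01)
  # overwrite flags with exact rational patterns
  tm <- matrix(FALSE, 100, 1); tm[1:33] <- TRUE
  lm <- matrix(FALSE, 100, 1); lm[1:11] <- TRUE
  fl$threshold$flagged <- tm
  fl$loading$flagged <- lm
  ns <- noninvariance_summary(fl)
  expect_equal(ns$threshold_pct, 33)
  expect_equal(ns$loading_pct, 11)
  expect_equal(ns$average_pct, 22)
  expect_identical(ns$verdict, "trustworthy")
})

test_that("factor-mean ranking orders by mean and lists only lower-ranked groups", {
  fx <- report_fixture()
  rk <- factor_mean_ranking(fx$res, fx$ses, alpha_level = 0.05)
  expect_identical(rk$mean, sort(rk$mean, decreasing = TRUE))
  expect_true(any(rk$group == fx$res$groups[1] & rk$mean == 0))
  # transitive consistency: nobody lists a group ranked above them
  for (i in seq_len(nrow(rk))) {
    listed <- strsplit(rk$smaller[i], " ")[[1]]
    listed <- listed[nzchar(listed)]
    expect_true(all(match(listed, rk$group) > i))
  }
})

test_that("a clearly higher group flags the lower one as significantly smaller", {
  # true means 0 and 1 at n = 2000: one-sided test should fire
  reps <- 10; fired <- 0
  pop <- make_population(3, 5, group_means = c(0, 1, 0.5), seed = 95)
  for (r in seq_len(reps)) {
    dat <- generate_responses(pop, rep(2000, 3), seed = 9500 + r)
    cf <- fit_configural(dat, se = TRUE)
    res <- align(cf, quick_opts(seed = r))
    ses <- aligned_standard_errors(res, cf)
    rk <- factor_mean_ranking(res, ses, 0.05)
    top <- rk[rk$group == "g2", ]
    fired <- fired + grepl("\\bg1\\b", top$smaller)
  }
  expect_gte(fired / reps, 0.9)
})
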