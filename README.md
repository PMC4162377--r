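# irtalign

Comparing latent factor means across many groups of binary-item
respondents — countries in an international assessment, sites in a
multi-centre study — normally requires *scalar measurement invariance*:
identical item loadings and thresholds everywhere.  With dozens of
groups that requirement always fails, and repairing it item by item is
hopeless (50 groups already imply 50·49/2 = 1225 pairwise contrasts per
item parameter).

`irtalign` implements the **alignment method** for multiple-group
two-parameter item response models.  Instead of demanding invariance, it

1. fits the **configural** model — marginal maximum likelihood per
   group, factor fixed to N(0, 1), binary 2PL with logit or probit link:

   P(y = 1 | η) = F(λ η − τ),  η ~ N(α_g, ψ_g),  a = λ, b = τ/λ;

2. exploits the fact that for any candidate group means/variances
   (α_g, ψ_g) there is an exactly likelihood-preserving transformation
   of the configural estimates, λ₁ = λ₀/√ψ, τ₁ = τ₀ + α λ₀/√ψ;

3. chooses (α_g, ψ_g) to minimize a **component-loss simplicity
   function** over all items and group pairs,

   F = Σ_p Σ_{g1<g2} w_{g1,g2} [ f(Δλ scaled) + f(Δτ) ],
   f(x) = (x² + ε)^¼, ε = 10⁻⁴,

   whose concavity concentrates the remaining non-invariance in few
   large differences (loading differences are scaled by the geometric
   mean of the pair's loadings; weights default to √(N_g1 N_g2));

4. reports which item parameters are non-invariant in which groups,
   summarises the rates against the 25 % rule of thumb, ranks groups by
   factor mean with pairwise significance, and checks ranking quality by
   Monte Carlo simulation (the accepted bar: mean correlation ≥ 0.98
   between generating and estimated means).

It also provides the traditional configural/metric/scalar
likelihood-ratio machinery for comparison, delta-method standard errors
for all aligned quantities, a seeded synthetic-data generator, JSON/TSV
writers, and a command-line interface.

## Worked example

An invariant two-group, ten-item population whose configural parameters
are constructed analytically from group distributions (0, 1) and
(−1, 2); alignment must recover the second group's mean and variance:

```r
library(irtalign)
lam <- seq(0.8, 1.7, length.out = 10)
tau <- seq(-1.2, 1.2, length.out = 10)
lam0 <- cbind(g1 = lam, g2 = lam * sqrt(2))   # inverse transform at (0,1), (-1,2)
tau0 <- cbind(g1 = tau, g2 = tau + lam)
fit <- configural_fit(lam0, tau0, group_sizes = c(1000, 1000))
align(fit)
#> alignment_result: 10 items x 2 groups (logit link, fourth-root CLF, fixed identification)
#> total loss F = 2000 (loadings 1000 + thresholds 1000), best of 30 starts
#>  group mean variance
#>     g1    0        1
#>     g2   -1        2
```

The loss sits exactly at its floor (2 · 10 items · 1 pair · w = 1000
terms of f(0) = 0.1) because every pairwise difference is zero at the
optimum.  A full pipeline on simulated data with injected differential
item functioning:

```r
pop <- make_population(6, 12,
                       noninv = list(threshold_pct = 15, loading_pct = 5),
                       group_means = seq(0, 1.5, length.out = 6), seed = 7)
dat <- generate_responses(pop, rep(800, 6), seed = 8)
cf   <- fit_configural(dat)
res  <- align(cf)
ses  <- aligned_standard_errors(res, cf)
noninvariance_summary(detect_invariant_sets(res, ses))
#> non-invariant cells: thresholds 6.9%, loadings 4.2%, average 5.6%
#> verdict: trustworthy (average <= 25%)
factor_mean_ranking(res, ses)
#> factor mean ranking (one-sided pairwise tests, alpha = 0.05)
#>  rank group  mean    se significantly smaller
#>     1    g6 1.497 0.241           g4 g3 g2 g1
#>     2    g5 1.399 0.310           g4 g3 g2 g1
#>     3    g4 0.950 0.162              g3 g2 g1
#>     4    g3 0.680 0.166                 g2 g1
#>     5    g2 0.384 0.132                    g1
#>     6    g1 0.000 0.000
```

The generating means were 0, 0.3, 0.6, 0.9, 1.2, 1.5: the ranking is
recovered exactly and every estimate sits within two standard errors of
its target despite 15 % threshold and 5 % loading non-invariance.  The
reference group (g1) is pinned at mean 0, variance 1, so its SE is 0 and
all means are expressed in its latent metric.

Quality check by simulation:

```r
mc <- run_monte_carlo(pop, rep(800, 6), n_reps = 5, seed = 1)
mc$mean_correlation   # >= 0.98 => ranking trustworthy
```

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli/irtalign.R", package="irtalign"))') \
    align --data responses.tsv --out out/ --seed 1
```

Subcommands: `fit` (configural/metric/scalar with the likelihood-ratio
table), `align`, `report` (invariance flags, non-invariance summary,
mean ranking), `simulate`, `mc`.  Options can be stored in a YAML config
(`--config`); explicit flags win.  Outputs are schema-versioned JSON
plus TSV tables.

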