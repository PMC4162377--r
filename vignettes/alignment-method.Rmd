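---
title: "Comparing factor means across many groups: the alignment workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing factor means across many groups: the alignment workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irtalign)
```

## The problem

Cross-national surveys routinely score the same battery of binary items
(e.g. knowledge-test questions) in dozens of country samples and then
want to rank the groups on the latent trait.  The classical route —
establish scalar measurement invariance, then compare factor means —
fails in practice: with many groups the scalar model is always rejected,
and freeing parameters one at a time (50 groups means
`n_group_pairs(50)` = 1225 pairwise contrasts *per item parameter*) is
hopeless.

The alignment method inverts the logic.  It starts from the *configural*
model — every group gets its own item parameters, with the factor fixed
to N(0, 1) per group — and then searches for group factor means and
variances under which the item parameters come as close to invariance as
possible, concentrating whatever non-invariance remains in as few
parameters as possible.

## Model

Each binary response follows the two-parameter model.  In the factor
metric, item $p$ in group $g$ has loading $\lambda_{pg}$ and threshold
$\tau_{pg}$:

$$P(y_{ipg} = 1 \mid \eta_{ig}) = F(\lambda_{pg}\,\eta_{ig} - \tau_{pg}),
\qquad \eta_{ig} \sim N(\alpha_g, \psi_g),$$

with $F$ the standard logistic CDF (residual variance $\pi^2/3$) or the
standard normal CDF (probit, residual variance 1).  The IRT metric is a
reparameterization: discrimination $a_{pg} = \lambda_{pg}$ and difficulty
$b_{pg} = \tau_{pg}/\lambda_{pg}$ (undefined at $\lambda_{pg}=0$;
`factor_to_irt()` refuses).

`fit_group_2pl()` maximizes the marginal likelihood per group, with the
factor integrated out by Gauss–Hermite quadrature.  The default 21
non-adaptive nodes leave relative integration error in the converged
log-likelihood below $10^{-4}$ on typical data; the node count is
configurable via `quadrature_spec()`.  Optimization is quasi-Newton
(L-BFGS-B) on analytic gradients; loadings and thresholds are boxed to
$(-25, 25)$ so quasi-separated items cannot diverge.  Starting values
come from per-item logistic regressions on the standardized total score.
Missing responses contribute nothing to their item's likelihood term
(missing-at-random full-information ML); a group in which an item is
missing for everyone is rejected at data validation.

## The alignment step

The configural model fixes $\alpha_g = 0$, $\psi_g = 1$ everywhere, so
group differences in the factor distribution leak into the item
parameters.  For *any* candidate $(\alpha_g, \psi_g)$ there is an exactly
likelihood-preserving reparameterization of the configural estimates
$(\lambda_{pg,0}, \tau_{pg,0})$:

$$\lambda_{pg,1} = \frac{\lambda_{pg,0}}{\sqrt{\psi_g}}, \qquad
\tau_{pg,1} = \tau_{pg,0} + \alpha_g \frac{\lambda_{pg,0}}{\sqrt{\psi_g}}.$$

(Thresholds are negated intercepts, hence the plus sign in the second
equation; `align_transform()` carries the identity, and the test suite
verifies likelihood equality to $10^{-8}$ over random distributions.)

`align()` chooses the free $(\alpha_g, \psi_g)$ to minimize the total
loss ("simplicity function")

$$F = \sum_p \sum_{g_1 < g_2} w_{g_1 g_2}\,
      f\!\left(\frac{\lambda_{pg_1,1} - \lambda_{pg_2,1}}
                    {\sqrt{\lambda_{pg_1,1}\lambda_{pg_2,1}}}\right)
    + \sum_p \sum_{g_1 < g_2} w_{g_1 g_2}\,
      f(\tau_{pg_1,1} - \tau_{pg_2,1}),$$

with component loss function $f(x) = (x^2 + \epsilon)^{1/4}$,
$\epsilon = 10^{-4}$.  Because $f$ is concave in $|x|$, the optimum
prefers a few large non-invariant parameters plus many near-invariant
ones over many medium-sized deviations — the same logic as rotation
criteria in exploratory factor analysis.  A square-root form
$(x^2+\epsilon)^{1/2}$ is selectable but loses that property.

Three design choices deserve comment:

* **Pair weights.** $w_{g_1 g_2} = \sqrt{N_{g_1} N_{g_2}}$ by default:
  pairs of large groups carry more precisely estimated differences and
  should dominate the loss.  Unit weights are selectable.
* **Loading-difference scaling.** The loading differences are divided by
  the geometric mean of the two aligned loadings.  Without this the loss
  is degenerate on noisy estimates: inflating every $\psi_g$ shrinks all
  aligned loadings toward zero, and a concave loss rewards that collapse
  no matter the data.  The scaled form is invariant to the overall
  aligned-loading scale, so only genuine *relative* loading differences
  are penalized.  Threshold differences are location-driven and enter
  raw.  The unscaled form is retained (`difference_scaling = "none"`)
  for study, not for use.
* **Identification.** The loss is flat along re-anchorings of the latent
  scale, so one group is pinned: the reference group (first by default)
  keeps $\alpha = 0$, $\psi = 1$.  A product-constraint alternative
  ($\prod_g \psi_g = 1$, first group mean 0) is provided.  Rerunning with
  a different reference only re-anchors the solution (exactly so for
  invariant inputs; a test asserts this).

The loss surface is multimodal, so `align()` uses seeded multistart
(default 30 starts: the unperturbed configural point plus 29 random
perturbations, $\alpha \sim N(0, 0.5)$, $\log\psi \sim N(0, 0.3)$),
quasi-Newton with analytic gradients within each start, means boxed to
$[-10, 10]$ and log variances to $[-5, 5]$, and returns the lowest-loss
solution (ties: earliest start).  Identical seeds give bit-identical
results.

## Post-alignment inference

`aligned_standard_errors()` differentiates the *entire* mapping from
configural estimates to aligned output (including the inner argmin) by
central differences with warm-started re-optimization, and sandwiches
the Jacobian around the block-diagonal configural covariance.  Pinned
reference quantities get SE 0.  A parametric-bootstrap check in the test
suite confirms the delta-method SEs on a three-group fixture.

`detect_invariant_sets()` reports, per item and parameter family, which
groups are significantly non-invariant: all pairwise z-tests, a greedy
largest mutually-non-significant set (ties broken by total sample size,
then label order), then iterative refinement against the
inverse-variance-weighted set mean until stable.  The test statistic and
level behind such tables are conventions, not consequences of the model;
the defaults (two-sided z, $\alpha = 0.01$ per test, no multiplicity
correction) are configurable.  With two groups the procedure reduces to
the single pairwise test.

`noninvariance_summary()` reports the flagged-cell percentages and the
working rule of thumb: up to 25% average non-invariance, alignment
results can be taken at face value; beyond that, confirm by simulation.
`factor_mean_ranking()` orders groups by estimated mean and attaches,
per group, the groups with significantly smaller means (one-sided z at
$\alpha = 0.05$ by default, optional Bonferroni), using the delta-method
covariance between aligned means when available.

## Monte Carlo quality assessment

Because alignment tolerates non-invariance rather than eliminating it,
the factor-mean ranking needs a quality check.  `run_monte_carlo()`
generates data from a specified (or estimated — `as_population()`)
population, refits and realigns each replication, and reports the
Pearson correlation between generating and estimated factor means,
computed over groups and averaged over replications.  A correlation of
at least 0.98 is the accepted bar for a trustworthy ranking.

`make_population()` builds study populations: invariant base parameters
(default loadings evenly spaced on 1.0–1.8 and thresholds on −1.5–1.5,
typical of a mixed-difficulty knowledge test) replicated across groups,
with a chosen percentage of threshold and loading cells perturbed by
uniform ±[0.3, 1.0] shifts — large enough to matter, small enough to be
realistic differential item functioning; every perturbation is recorded
in a ledger.  The generator emulates group-varying normal factor
distributions and clean 2PL response processes.  It does *not* emulate
survey features of real assessments — stratified/clustered sampling,
weights, booklet designs, non-normal ability distributions, guessing —
so passing simulations demonstrate correctness of the machinery under
the model's own assumptions, not robustness to violations of them.

The packaged simulation study (also recomputed by
`scripts/acceptance.R`) uses 28 groups, 17 items, 500 respondents per
group, means spread over [0, 2], unit variances, 33% of threshold and
11% of loading cells perturbed, and 5 replications; it attains a mean
correlation above 0.98.  Replication counts are kept modest because the
full pipeline (28 marginal-ML fits plus a 54-parameter multistart
alignment per replication) is the unit of cost; the test suite sizes its
other simulations (type-I error of the metric-vs-configural test at 500
small replications; recovery and coverage at 30; detection power at 20)
the same way.

## Traditional invariance testing

For comparison with the conventional workflow,
`fit_invariance_model()` fits the metric model (shared loadings;
thresholds free; variances free except the reference) and the scalar
model (shared loadings and thresholds; means and variances free except
the reference), and `likelihood_ratio_test()` performs the nested
chi-square tests.  Absolute free-parameter counts depend on
identification conventions, but the *differences* do not:
configural − metric = $(G-1)(P-1)$ and configural − scalar =
$2(G-1)(P-1)$ — e.g. 208 and 416 at $G=14$, $P=17$; 432 at $G=28$.
These tests are powerful to the point of uselessness at survey sample
sizes (every model is rejected), which is precisely the motivation for
alignment; binary-item ML offers no CFI/RMSEA-style mitigation.

## Numerical notes and limitations

* Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ inside
  likelihood code only; public probability functions return exact link
  values.
* The loading-geometric-mean scale is floored at 0.05 (its derivative
  dropped when floored) so near-zero loadings cannot blow up the loss.
* The degenerate-direction analysis above means results with
  `difference_scaling = "none"` should not be trusted on real
  (noisy) data.
* Adaptive quadrature is not implemented; `quadrature_spec()` rejects
  the flag with advice to raise the node count.
* Single factor only; no cross-loadings, no polytomous items, no
  guessing parameter, no survey weighting/clustering, no Bayesian
  (approximate-invariance) variant.
* With fewer than three groups the mean-recovery correlation is
  undefined; `mean_correlation()` refuses.

## A worked example

```{r, eval = FALSE}
library(irtalign)

# an invariant two-group population whose configural parameters are
# constructed analytically from group distributions (0, 1) and (-1, 2)
lam <- seq(0.8, 1.7, length.out = 10)
tau <- seq(-1.2, 1.2, length.out = 10)
lam0 <- cbind(lam * sqrt(1), lam * sqrt(2))
tau0 <- cbind(tau - 0 * lam, tau - (-1) * lam)
fit <- configural_fit(lam0, tau0, group_sizes = c(1000, 1000))
res <- align(fit)
res$alpha  # 0, -1
res$psi    # 1,  2

# a full pipeline on simulated data
pop <- make_population(6, 12,
                       noninv = list(threshold_pct = 15, loading_pct = 5),
                       group_means = seq(0, 1.5, length.out = 6),
                       seed = 7)
dat <- generate_responses(pop, rep(800, 6), seed = 8)
cf <- fit_configural(dat)
res <- align(cf)
ses <- aligned_standard_errors(res, cf)
flags <- detect_invariant_sets(res, ses)
noninvariance_summary(flags)
factor_mean_ranking(res, ses)
```
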