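---
title: "Decision-theoretic selection of breeding candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-theoretic selection of breeding candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Selection as a decision problem

A breeding program advances the candidates believed to carry the highest
breeding values (BVs). Under genomic selection those BVs are predictions
from a regression of phenotypes on genome-wide markers, and every
prediction carries posterior uncertainty. Conventional ("Std") selection
ranks posterior-mean BVs and keeps the top fraction `q`; the uncertainty
plays no role in the decision.

`gsloss` instead frames selection as a Bayes decision. Truncation
selection at threshold `yc` defines the breeder's *target*: the selected
parents follow the upper-truncated distribution of the base population,
with mean `muS`. A loss function `L` measures the divergence between a
candidate's predictive BV distribution and that target, and each candidate
`o` is scored by its posterior expected loss — the average of `L` over the
joint posterior of the model parameters and the candidate's predictive
distribution. Candidates with the smallest expected loss are selected.
Because `muS`, the phenotypic variance and the candidate's predictive
distribution are all recomputed per posterior draw, the score integrates
over parameter uncertainty exactly as the Bayes-action formalism requires.

## Truncation quantities

For a normal base population `N(mu1, sigma^2)` truncated above `yc`
(`d = (yc - mu1)/sigma`):

* retained probability `z = 1 - Phi(d)`;
* selected-parent mean `muS = mu1 + sigma * phi(d)/(1 - Phi(d))`;
* selection differential `S = muS - mu1` and intensity `i = S/sigma`.

`truncated_normal_summary()` evaluates these with the inverse Mills ratio
computed on the log scale, so thresholds deep in the tail do not overflow;
a truncation with `z < 1e-12` is treated as degenerate and raises an error
rather than returning infinities. Thresholds are usually derived from a
selection pressure with `truncation_point_from_pressure()`, which makes
`z = q` by construction and re-derives `yc` from whatever the current
population parameters are — in the simulator the threshold therefore moves
with the population every cycle while the selected fraction stays fixed.

For `t` traits the base population is `MVN(mu1, P)` and the target is the
TMVN distribution above the threshold vector `yc`. No closed form exists
for the orthant probability or the TMVN mean at `t > 1`, so both are
estimated numerically with seeded samplers: `mvn_orthant_probability()`
uses plain Monte Carlo (default `1e5` draws; the univariate case is exact),
and `tmvn_mean()` uses rejection sampling with batch top-up. Inside the
expected-loss engine the TMVN mean is instead estimated by a coordinate
Gibbs sampler (400 sweeps, 100 burn-in by default), which remains accurate
when the orthant probability is tiny and rejection sampling would starve.
The `-log z` term of the multivariate KL loss is shared by every candidate
within a posterior draw, so Monte-Carlo noise in `z` shifts all scores
equally and never perturbs the ranking.

## The loss functions

Univariate, written in the deviation `e = muS - mu2` (`mu2` the candidate
mean) and, via the breeder's equation `R = h2 * S`, in heritability form:

* **KL**: `-log z + (e^2 - S^2)/(2 sigma^2)` =
  `-log z + i^2 h2 (h2 - 2)/2`. Strictly decreasing in `h2` for fixed
  `i > 0`: heritable signal makes selection less lossy.
* **CRPS**: `-sigma * (c - 2 phi(e/sigma) - (e/sigma)(2 Phi(e/sigma) - 1))`.
  Two conventions for the constant `c` are provided: the package default
  uses `c = 1/pi`; `constant = "sqrt_pi"` uses `1/sqrt(pi)`, which makes
  the expression the exact CRPS of a Gaussian against a point target (the
  tests verify this against numerical integration of the defining
  `(F - 1)^2` integral). The two differ by a candidate-independent offset
  proportional to `sigma`, so rankings of candidates sharing `sigma` are
  identical under either constant.
* **LinLin**: the pinball loss `(alpha - 1(e<0)) e`, `alpha` in (0, 1).
  With `alpha > 0.5`, candidates whose means fall short of `muS` are
  penalized more than equidistant overshooters.

Multivariate:

* **mKL**: `-log z + (e' P^-1 e - S' P^-1 S)/2`;
  `kl_multivariate_struct()` gives the equivalent structural form
  `-log z + S'[(I - G P^-1)' P^-1 (I - G P^-1) - P^-1] S / 2` in which the
  candidate mean has been eliminated through `R = G P^-1 S`. The sign of
  the `log z` term is fixed by the univariate limit: at `t = 1` with
  `G = h2 * P` the structural form reduces exactly to the heritability-form
  KL, which requires `-log z`.
* **EnergyS**: `E||Yo - muS|| - E||Yo - Yo'||/2`, estimated from the
  predictive draw stream with the two independent copies realized as
  disjoint half-streams. Computed on draws of the observable phenotype, it
  needs no normality assumption.
* **MALF**: L2 form `(||e|| + tau'e) ||e||`, L1 form `sum|e| + tau'e`. In
  one dimension with `tau = 2 alpha - 1` the L1 form is exactly twice the
  LinLin loss. Positivity is only guaranteed for `||tau|| <= 1`; a larger
  asymmetry vector triggers a warning, not an error, since moderate
  per-component values (0.7-0.9) are the practically relevant regime.

## Posterior expected loss

`expected_loss_univariate()` takes the BV draw matrices directly: per
posterior draw `j`, the base-population mean `mu1_j` and genetic variance
are taken from the base-population BV draws, the phenotypic variance is
their sum with the residual-variance draw, the threshold is re-derived
from `q`, and the candidate's loss is evaluated at its BV draw. The
reported score is the arithmetic mean across draws. Which lines constitute
the "base population" is the caller's choice of the `bv_base` argument; the
simulator passes the full current population (training plus candidates),
but passing the candidate set alone is equally valid and changes only the
target, not the machinery. `expected_loss_multivariate()` is the `t`-trait
analogue with `P_j = cov(BV draws) + Rcov_j`.

Ranking is ascending in expected loss (descending in posterior-mean BV for
`Std`), ties broken by candidate identifier so selections are
deterministic, and `select_top()` keeps `round(q * n)` candidates — at
`q = 0.10` on 320 candidates, exactly 32 lines.

## Prediction models

`fit_brr()` implements Bayesian Ridge Regression,
`y = 1 mu + X beta + e`, with iid Gaussian prior on the marker effects,
scaled-inverse-chi-squared priors (df 5) on both variances with prior
modes at a 50/50 split of the sample phenotypic variance, and a flat prior
on the intercept. The marker-effect block is drawn jointly through a
one-off eigendecomposition of `X'X`, making the per-iteration cost two
`p x p` matrix-vector products; chains are bit-reproducible given a seed.

`fit_mtm()` implements the multi-trait genomic mixed model
`Y = 1 m' + U + E` with `vec(U) ~ N(0, G (x) K)` for a VanRaden-type
genomic relationship matrix `K` (`grm()`, diagonal jittered by `1e-8`) and
inverse-Wishart priors (df `t + 3`, scale half the sample phenotype
covariance) on `G` and the residual covariance. Each iteration works in
the eigenbasis of `K` and simultaneously diagonalizes `G` against the
residual covariance, so the `n x t` update of `U` is elementwise
shrinkage — no per-line loops, which keeps a full chain under a second at
test scale. Candidate lines are predicted by conditioning their genetic
values on the training lines through the partitioned `K` (train/test block
of the joint Gaussian). Single-trait input is accepted; the model is then
the GBLUP dual of BRR and the two samplers' predictions agree in rank to
better than 0.95 on common data, which the tests check.

Default chain settings retain 10,000 draws after a 30,000-iteration
burn-in; the `"fast"` profile (500 after 500) is used throughout the test
suite and is adequate for the posterior means and rankings exercised
there.

## The simulator

`simulate_founders()` draws fully homozygous inbred lines (genotypes
-1/+1) at unlinked biallelic loci with allele frequencies uniform on
[0.05, 0.95]. Gene effects are either univariate — magnitudes
Gamma(shape 2, scale 2), signs random by default (an all-positive mode
exists; the sign rule is an interpretation, since only the magnitude
distribution is specified by the design) — or fully pleiotropic MVN
vectors per locus with unit variances and target correlations
(-0.37, 0.34, -0.02 for the three-trait default). Because loci are
independent, founder TBV correlations match the effect correlations in
expectation; at 1000 lines and 1000 loci a single realization scatters
around the target with a standard deviation near 0.05.

Phenotypes add iid normal residuals with
`sigma_e^2 = sigma_g^2 (1 - h2)/h2`, calibrated once against the founder
genetic variance and held fixed across cycles, so realized heritability
drifts downward as selection erodes variance; a `recalibrate` switch
re-derives the residual variance each cycle instead. A target `h2 = 0` is
interpreted as a pure-noise trait — the phenotype is residual noise only,
independent of the genotype, with variance set to the founder genetic
variance — because the ratio formula is undefined at zero. This keeps the
null breeding program (no heritable signal, hence no expected response)
well-defined and testable.

Crossing follows a doubled-haploid convention: each offspring comes from a
uniformly drawn pair of distinct parents and, locus by locus, inherits one
of the two parental alleles with probability 1/2, doubled to homozygosity.
This keeps the -1/+1 coding closed under reproduction and conserves any
allele fixed among the parents. Loci assort independently; linkage,
mutation and explicit inbreeding tracking are out of scope.

`run_program()` chains the cycle: phenotype, 70/30 train/candidate split
(the same split fractions are applied in the univariate and multivariate
settings), model fit, expected-loss ranking, top-`q` selection *within the
candidate set*, and crossing back to the full population size. Replicate
seeds derive deterministically from the master seed, so a whole
multi-replicate program is reproducible bit for bit. Summaries report the
standardized response `(mu_i - mu_1)/sigma_1` and scaled variance
`sigma_i^2/sigma_1^2` on the true-breeding-value scale relative to each
replicate's first cycle, and the percent change of genetic mean and
variance between the last and first cycles.

## What the tests do and do not show

The test suite verifies the closed forms against quadrature and rejection-
sampling oracles, the algebraic identities among the KL and CRPS forms,
parameter recovery of both samplers, the founder calibration at the design
scale (1000 lines x 1000 loci, averaged over four founder populations to
estimate the expected realized values), and two end-to-end properties of
the simulator at a deliberately desk-sized configuration (160 lines, 240
loci, 10 cycles, 20 replicates, fast chains): positive standardized
response with eroding variance at `h2 = 0.5`, and response within two
standard errors of zero without heritable signal. These runs demonstrate
internal consistency of the machinery, not field performance: real marker
panels have linkage disequilibrium, non-Gaussian residuals, missing data
and genotype-by-environment structure that the generator deliberately
omits, and absolute gains depend on population size and locus count, which
are free parameters here. Comparisons between criteria should therefore be
read as qualitative orderings under the stated architecture, not as
predicted magnitudes for any particular crop program.

## Numerical choices, in brief

* Degenerate truncation: error at `z < 1e-12` everywhere.
* `K` and Schur complements jittered by `1e-8` before factorization;
  eigenvalues clamped at small positive floors.
* Monte-Carlo estimators (orthant probability, TMVN mean, energy score)
  are seeded and their sample counts configurable; defaults are `1e5`
  stand-alone and `2000`/400 Gibbs sweeps per posterior draw inside the
  expected-loss engine, where errors average out across draws.
* Ties in expected loss break by identifier; selection sizes round to the
  nearest integer.
* Zero-variance markers are retained but centered to zero, so they carry
  no signal and no numerical hazard.
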