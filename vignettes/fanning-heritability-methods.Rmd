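---
title: "Methods: estimating the heritability of paternal fanning behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating the heritability of paternal fanning behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fanherit)
```

## The scientific problem

Male three-spined stickleback are the sole providers of parental care; the
most conspicuous care behaviour is *fanning* — driving oxygenated water over
the eggs — quantified as seconds spent fanning within a 300-s observation
window. `fanherit` analyses a father–son common-garden design: wild-caught
sires and their laboratory-reared sons are observed on the peak care day
(the fifth egg day, ED5), and the phenotypic resemblance among relatives is
converted into an estimate of narrow-sense heritability with a pedigree
animal model. The package covers the full analysis chain: pedigree
relationship matrices, a Bayesian animal model, repeatability and
evolvability summaries, a growth-curve model of fanning across the care
period, a sampling-error robustness simulation, and a synthetic-data
generator that stands in for raw data that were never deposited.

## The animal model

The core model for the ED5 phenotype $y$ of individual $i$ is

$$ y_i = \mathbf{x}_i' \boldsymbol\beta + a_i + p_{g(i)} + e_i, \qquad
   \mathbf{a} \sim N(0, \mathbf{A}\,\sigma^2_A), \quad
   p \sim N(0, \mathbf{I}\,\sigma^2_{patch}), \quad
   e \sim N(0, \mathbf{I}\,\sigma^2_R), $$

where $\mathbf{A}$ is the additive (numerator) relationship matrix built
from the pedigree by the recursive tabular method (parent–offspring and
full sibs 0.5, half sibs 0.25, diagonal $1 + F_i$). The "uncorrected" model
has an intercept only; the "corrected" model adds male condition
(weight/length) and clutch size as fixed covariates and the rearing patch
as an identity-covariance random effect. Narrow-sense heritability is
computed per posterior sample as $h^2_t = \sigma^2_{A,t} / \sum_k
\sigma^2_{k,t}$ (the denominator is the sum of *all* fitted variance
components, so the corrected model's denominator includes patch), then
summarized; evolvability is reported as $CV_A = 100\sqrt{V_A}/\bar{x}$ and
$I_A = (CV_A/100)^2$ using the model's predicted mean.

Priors are weakly informative inverse-gammas specified through the
$(V, \nu)$ parameterization, $\mathrm{shape} = \nu/2$, $\mathrm{scale} =
\nu V / 2$, with the study's choice $V = 1$, $\nu = 0.002$ for every
variance component. Fixed effects take a flat (improper uniform) prior —
the exact limit of the conventional zero-mean Gaussian with variance
$10^{10}$, and what makes the spectral reduction below exact.

## How the sampler works, and why it is collapsed

For models with a single structured random effect (the genetic effect, or
individual identity in the repeatability model) the package performs a
one-off generalized eigendecomposition of the pair
$(\mathbf{W}'\mathbf{W}, \mathrm{blockdiag}(0, \mathbf{G}^{-1}))$, where
$\mathbf{W} = [\mathbf{X}\;\mathbf{Z}]$. In that basis both the likelihood
and the random-effect prior are diagonal, so the marginal posterior of the
two variance components given the data — with *all* location effects
integrated out analytically — can be evaluated in $O(\#\text{distinct
eigenvalues})$. Each MCMC iteration updates $\log\sigma^2_A$ and
$\log\sigma^2_R$ by coordinate slice sampling on this exact marginal, and
location effects (fixed effects and breeding values) are drawn from their
exact joint Gaussian conditional at storage points.

This collapsed scheme replaced the textbook alternation of Gaussian
location draws with inverse-gamma full-conditional variance draws. The
textbook kernel targets the same posterior but mixes catastrophically here:
with one record per individual the sampled breeding values can absorb the
data, the residual variance then collapses, and the chain takes millions of
iterations to escape — we measured integrated autocorrelation times for
$\sigma^2_R$ in the millions on a 100-sire design at $h^2 = 0.9$, and
verified against an exact grid evaluation of the marginal posterior that
even $2\times10^6$ iterations had not converged. The collapsed sampler
reproduces the grid posterior to three decimals and decorrelates in a
handful of iterations. Because the variance updates no longer depend on
sampled location effects, thinning requirements drop sharply; the historical
schedules (e.g. $10^7$ iterations thinned by 2000) remain available and
cheap. Models with several independent random components (the corrected
model and the trajectory model) keep the classic full-conditional Gibbs
kernel, which mixes adequately at their sizes; their schedules are long by
default for that reason.

Breeding values are sampled only for phenotyped individuals: the prior of
that subvector is $N(0, \mathbf{A}_{obs}\,\sigma^2_A)$ with
$\mathbf{A}_{obs}$ the corresponding submatrix (multivariate-normal
marginals are submatrices), so every reported posterior is unchanged.

All randomness flows through R's RNG: a fit with the same inputs and seed
is bit-identical, and the pipeline derives per-stage sub-seeds from one
master seed.

## Point estimates and intervals

Two summary conventions are provided. The default — kernel-density
posterior mode and highest-posterior-density (HPD) interval — mirrors the
reporting convention of the Bayesian mixed-model software family this
analysis descends from, and is what the worked examples print. For
frequentist calibration studies the package uses (and recommends) the
posterior mean with equal-tailed quantile intervals: the $(V=1,
\nu=0.002)$ prior has an integrable spike at the variance boundary, so
ratio posteriors such as $h^2$ pile up at 0 or 1 when the data are weak,
the shortest-interval HPD hugs that boundary, and its frequentist coverage
of interior truths drops (we measured 0.73–0.79 at true $h^2 \in \{0.2,
0.9\}$ on 100-replicate balanced designs, against 0.85–0.93 for
equal-tailed intervals with biases below 0.04). The density mode is
evaluated on the sample range, so it can never leave $[0, 1]$ for a ratio.

`pMCMC` for a covariate is twice the smaller posterior sign fraction,
floored at $2/n$ — a chain cannot witness a tail probability smaller than
one sample.

## Convergence diagnostics

`lag_autocorrelation` is the standard sample autocorrelation; schedules are
chosen so stored chains stay below 0.1 at lag 1. `heidelberg_stationarity`
implements the Heidelberger–Welch procedure: a Cramér–von Mises statistic
on the standardized cumulative-sum (Brownian-bridge) process, with the
long-run variance estimated as the spectral density at zero from an AR fit
to the second half of the tested window; if the full chain fails at level
$\alpha$, the first 10% is discarded and the test repeated up to a 50%
discard. The reported `p_value` is the full-chain first-window p-value —
the quantity whose rejection rate is near-nominal (measured 0.044–0.047 at
$\alpha = 0.05$ on iid chains) — while `pass` reports the outcome of the
iterative procedure, which by construction rejects less often. The
four-term Bessel series for the Cramér–von Mises CDF is clamped to 1 above
statistic values of 2 (CDF there $1 - 1.3\times10^{-5}$), where the series
itself degrades. The pipeline treats diagnostic failures as warnings, not
aborts: they are checks on a run, not gates.

## The sampling-error robustness study

A 5-min window is a sample of a male's behaviour; to ask how much that
sampling noise could distort heritability, the package tiles an hour-long
bout record into twelve 300-s windows (an 11-window option exists), forms
the deviation of each window's fanning proportion from the hour-wide
proportion, and then repeatedly (i) adds an independently resampled
deviation $\times$ 300 s to every phenotype, clipped to $[0, 300]$,
(ii) refits the animal model at a reduced schedule (13 000 iterations,
burn-in 3000, thinning 10), and (iii) records the $h^2$ point estimate.
With strongly heritable data the resulting distribution is left-skewed:
perturbations can only erode a high estimate. Deviations are stored as
proportions and converted to seconds at application time; resampling is
with replacement, independently per data point and replicate, with
per-replicate sub-seeds drawn from the master seed.

## The trajectory model

Fanning over the care period is modelled as
$y = \beta_0 + \beta_1 d + \beta_2 d^2 + u_{0f} + u_{1f} d + u_{2f} d^2 + e$
with mutually independent fish-level deviations (the simplest structure
consistent with per-fish intercepts and slopes; a correlated version is
deliberately not implemented). Day codes are ED1 = 1, ED3 = 3, ED5 = 5,
FD1 = 6, FD3 = 8, FD5 = 10 — hatching closes day 5 — and the map is
configurable because observation-day coding conventions differ between
studies. This module refits the same mean and random structure by MCMC
rather than REML so that one sampler family serves the entire package; AIC
comparison among candidate structures and Satterthwaite p-values are out of
scope.

## What the synthetic-data generator emulates

No raw data are deposited, so the generator defines study-like conditions
with known truth:

* **Design**: 13 unrelated, non-inbred wild-caught sires, one dam per
  family (sons are full sibs, $A = 0.5$; a flag codes unknown dams, giving
  half sibs at 0.25, since whether dams were recorded is unknown), 2 sons
  per sire; sires and sons phenotyped, dams not.
* **Phenotype scale** (`preset = "study"`): mean 39.47 s, total phenotypic
  variance 3280.78 s², true $h^2 = 0.95$, patch explaining 2.35% of
  variance across 6 rearing patches assigned round-robin over sons,
  condition and clutch-size effects zero. Values are Gaussian on a latent
  scale and clipped to $[0, 300]$; at this scale roughly a fifth of values
  clip at 0, which is the realism (many males do not fan in a given
  window), and a diagnostic warning fires when clipping exceeds 10%.
* **Recovery preset** (`preset = "recovery"`): a 100-sire × 4-son balanced
  design at mean 150 s, variance 3000 s², where clipping is below 1%, used
  for calibration studies so boundary clipping cannot bias them.
* **Trajectory**: per-fish quadratic curves peaking at day code 5
  (hatching). The curvature scale is $\beta_2 = -3.79$; the linear
  coefficient default is 37.9 so the vertex sits at the hatching day under
  this package's day coding (published coefficient pairs presume their
  study's own coding, so they are recovered in tests by passing them
  explicitly, which is coding-agnostic).
* **Hour record**: alternating exponential fanning bouts and gaps,
  stationary initial state, 40% fanning overall (the documented share of
  time fanning at peak care). The bout and gap means (3 s and 4.5 s)
  calibrate the implied 5-min-window deviation spread (sd ≈ 0.05
  proportion, i.e. ≈ 15 s of 300) to the within-male variance implied by
  the measured repeatability of 0.93 across repeated 5-min windows: an
  exponential renewal process is over-dispersed relative to real rhythmic
  fanning, so matching the window-level variance — the quantity that
  drives the robustness analysis — requires shorter nominal bouts than
  real fanning bouts.
* **Repeated observations**: two observations per male with a male effect
  of variance $r \cdot V$ and residual $(1 - r) V$, left unclipped so
  closed-form intraclass-correlation oracles apply exactly.

Passing tests on these data show that the estimators recover known truth
under Gaussian-latent, clipped, balanced conditions; they cannot show that
the real behavioural data satisfy those assumptions (real fanning is
zero-inflated and right-skewed, families are unbalanced, and dam structure
is unknown).

## Numerical choices and degenerate inputs

Pencil eigenvalues are clamped to $[0, 1]$ and grouped with an absolute
tolerance of $10^{-9}$; the location precision in the general kernel gets
one ridge retry of $10^{-10}\,\mathrm{tr}(C)/m$ before failing. Constant
responses, collinear designs, non-positive-definite relationship matrices,
duplicated individuals, cyclic pedigrees and out-of-range phenotypes are
all rejected with specific errors; parents referenced but never defined are
promoted to founders with a warning. A constant chain is a degenerate
posterior summary (point = value, zero-width interval) but an *error* for
autocorrelation and stationarity, which are undefined there. Perturbation
replicates that fail to fit are recorded and skipped, not fatal.

## Problem sizes used in checks

The shipped checks run, on one CPU: gene-dropping validation of the
relationship matrix on 30-individual pedigrees at $2\times10^5$ allele
drops; Kolmogorov–Smirnov agreement of the no-pedigree sampler with the
conjugate closed form at $10^4$ stored samples; 100 recovery replicates per
true $h^2 \in \{0.2, 0.5, 0.9\}$ on the 100 × 4 design at 50 000-iteration
chains; 1000 iid chains for the stationarity-test size; and a 200-replicate
perturbation study at the reduced schedule. These sizes were chosen so the
full suite characterizes calibration while remaining quick to run; the
acceptance script runs the historical $10^7$-iteration schedule for the
headline fit, which the collapsed sampler makes inexpensive.

## Known limitations

* The generator's latent-Gaussian-then-clip phenotype model understates the
  skewness of real fanning data; heritability estimated from heavily
  clipped study-scale data is attenuated relative to the latent truth.
* At 13 families the posterior for $h^2$ is wide, and occasional
  realizations carry weak family signal; single-dataset point estimates at
  this size are honest but unstable, which is exactly the small-sample
  caveat the original design carries.
* One trait, one observation per individual in the animal model; no
  multi-trait models, no REML route, no genomic relationship matrices, no
  parameter expansion (superseded by the collapsed kernel for the models
  that needed it).
* The corrected model's patch percentage is weakly identified at $n = 39$
  and its posterior mode often sits near zero even when the generating
  patch fraction is positive.
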