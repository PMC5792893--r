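# fanherit

Quantitative genetics of paternal care in three-spined stickleback
(*Gasterosteus aculeatus*), a species in which fathers alone provide the
care their offspring need. The package estimates how heritable paternal
**fanning** behaviour is — seconds spent fanning the nest per 300-s
observation window — from a father–son common-garden design: wild-caught
sires and their laboratory-reared sons observed on the peak care day (egg
day 5).

It is written for behavioural ecologists and quantitative geneticists who
want the full analysis chain as reusable, tested functions:

* **Pedigrees**: parsing/validation and the additive (numerator)
  relationship matrix **A** by the recursive tabular method
  (`A[i,j] = (A[j,sire] + A[j,dam])/2`, diagonal `1 + F`).
* **Animal model**: Bayesian univariate mixed model
  `y = Xb + Za + Zp + e`, `a ~ N(0, A·V_A)`, with weakly informative
  inverse-gamma variance priors (`V = 1`, `nu = 0.002`). Single-component
  models use a collapsed sampler — variance components updated by slice
  sampling on their exact location-integrated marginal posterior after a
  one-off spectral reduction — which makes even 10⁷-iteration schedules
  cheap and avoids the notorious mixing failure of naive Gibbs at high
  heritability.
* **Derived statistics**: heritability `h² = V_A / V_total` per posterior
  sample, repeatability, evolvability (`CV_A = 100·sqrt(V_A)/mean`,
  `I_A = (CV_A/100)²`), pMCMC, father–son regression.
* **Diagnostics**: lag autocorrelation and a Heidelberger–Welch
  stationarity test (Cramér–von Mises on the cumulative-sum process).
* **Trajectory model**: fanning across the ten-day care period with linear
  + quadratic day effects and per-fish random intercept/slope/curvature.
* **Robustness**: the observation-window sampling-error study — resample
  5-min-window deviations from an hour-long bout record, perturb every
  phenotype (clipped to [0, 300] s), refit, and summarize the resulting
  heritability distribution.
* **Synthetic data**: a generator with known ground truth emulating the
  study design (13 sires × 2 sons, study-scale means/variances, patch
  effects, hour-long bout records), since the raw data are unpublished.

## Worked example

```r
library(fanherit)

ped <- generate_pedigree(13, 2)                    # 13 sires, 26 sons, 52 ids
A   <- additive_relationship_matrix(ped)
phe <- simulate_ed5_phenotypes(ped, generator_config("study"))

fit <- fit_animal_model(phe, A, cfg = mcmc_config(2e6, 1e5, 400, seed = 32))
heritability_posterior(fit)
#> 1.0000 (95% CI 0.8670-1.0000, mode)

evolvability(3142.21, 39.47)   # the printed-table arithmetic
#> CV_A = 142.02%  I_A = 2.02  (V_A = 3142.21 s^2, mean = 39.47 s)

heritability_from_components(3142.21, 3280.78)
#> [1] 0.9577631
```

The first result says that for this synthetic study-like dataset
(generated at true h² = 0.95) essentially all phenotypic variance on the
peak care day is additive-genetic: the posterior mode of h² is at the
upper boundary with a 95% credible interval of roughly 0.87–1.00. The
`evolvability` call reproduces the standard mean-standardized measures
from a printed additive variance and trait mean: a CV_A of 142% means the
additive genetic standard deviation exceeds the trait mean — abundant
fuel for evolution. The last call is the ratio of printed variance
components, h² to two decimals 0.96.

The sampling-error robustness study:

```r
dist <- deviation_distribution(simulate_hour_record())
ps   <- perturbation_study(phe, A, dist = dist, n_replicates = 200, seed = 42)
summarize_perturbation(ps)[c("min", "max", "skewness")]
#> $min  0.996  $max  1.000  $skewness  -6.0
```

a left-skewed distribution: plausible observation-window sampling error
only erodes, and barely moves, the high estimate.

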