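# adeliescan

Detection-corrected abundance estimation for Adélie penguin colonies in
medium-resolution (30 m) multispectral satellite imagery.

Colonial seabirds leave guano stains whose spectral signature is separable
from rock, soil and snow in Landsat-class imagery, so colony *presence* and
*area* can be retrieved automatically at continental scale. Turning that
into defensible *abundance* requires two corrections that this package
implements end to end, for ecologists and remote-sensing analysts building
regional or continental censuses:

1. **Area → pairs.** For detected colonies, abundance is modelled as
   `N_i ~ Poisson(λ_i)`, `log λ_i = log A_i + β`, a Poisson regression with
   log guano area as a fixed offset, so `e^β` is the *apparent density*
   (nests per m² of detected guano; published values 0.34 nests/m² for
   continental Antarctica and 0.52 nests/m² for the Antarctic Peninsula).
2. **Missed colonies.** Detection is logistic in colony size,
   `logit p_det(N) = β0 + β1·N`, and colony sizes follow a lognormal law
   `log N ~ N(μ, σ²)`. The expected size of a missed colony is the
   conditional expectation `E[N | M=0] = Σ n(1−p_det(n))P(n) / Σ
   (1−p_det(n))P(n)`, the number of missed colonies is Negative Binomial
   with success probability equal to the overall detection rate, and their
   product (by Monte Carlo, with a percentile interval) is the abundance
   the survey never saw.

Around this core: a one-class Mahalanobis-ellipsoid pixel classifier with
connected-component candidate extraction and four-outcome scoring against
a reference registry; Kendall rank-correlation validation of the
pixels-vs-abundance scaling; scaled-difference equivalence testing of
model-based vs reference totals across aggregation scales; and a
synthetic-scene generator (lognormal colony sizes, class-wise multivariate
normal spectra, cloud/shadow/dropout degradation, truth masks) so the whole
pipeline is testable with no satellite download.

## A worked example

```r
library(adeliescan)

cfg <- default_run_config()   # the published parameter world, 244 colonies
cfg$seed <- 1
rep <- run_pipeline(cfg)
rep
#> <pipeline_report>
#>   continent  180 colonies: 157 detected,  23 omitted,  0 commissions
#>   peninsula   64 colonies:  46 detected,  18 omitted,  0 commissions
#>   survey total 11664760 (true 12250615), 95% CI [10291527, 26302564], covered: TRUE

rep$missing
#> <missing_abundance_estimate> 183223 breeding pairs (95% CI 78645-335606)
#>              region k_detected     p_hat e_missing_size expected_missing_colonies
#> continent continent        157 0.8722222       5494.275                        23
#> peninsula peninsula         46 0.7187500       3026.286                        18
```

Reading this: of 244 simulated colonies, the retrieval found 203; the
fitted logistic detection curves and lognormal size laws imply ≈41 missed
colonies carrying ≈183k pairs, and adding that correction to the
area-based estimate for detected colonies gives a survey total whose 95%
interval covers the true simulated total (it does so in 98 of 100
replicate worlds).

Interrogating the models directly:

```r
fit <- detection_model(beta0 = -1.00, beta1 = 4e-4)   # continental curve
detection_probability(fit, 0)                         # 0.2689 — a tiny colony
size_at_detection_probability(fit, 0.5)               # 2500 pairs for 50% detection

f <- fit_abundance_model(guano_area = c(100, 200), n_pairs = c(34, 68))
apparent_density(f)                                   # 0.34 nests/m^2
```

## Layout

* `R/` — synthetic world (`sample_colony_registry`, `render_scene`),
  retrieval (`fit_ellipsoid`, `classify_pixels`, `extract_candidates`,
  `match_outcomes`), models (`fit_detection_model`, `fit_abundance_model`,
  `fit_colony_size_distribution`), missing-abundance correction
  (`expected_missing_colony_size`, `missing_colony_count`,
  `total_missing_abundance`), aggregation (`sample_aggregate_differences`,
  `ks_compare`, `find_equivalence_scale`), orchestration (`run_pipeline`)
  and I/O (CSV registries, multipage-TIFF scene containers with JSON
  sidecars, KML export, YAML run configs).
* `vignettes/detection-corrected-abundance.Rmd` — the models, their
  assumptions, numerical choices, and what the synthetic world does and
  does not demonstrate.
* `tests/testthat/` — unit, property and end-to-end acceptance tests.
* `inst/scripts/run_pipeline.R` — thin command-line wrapper over
  `run_pipeline()`.
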