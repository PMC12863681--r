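# checklistOccupancy

Annual species occupancy from unstructured, presence-only checklist
records — the kind of data produced when plantation workers, rangers or
volunteer naturalists report sightings with no fixed protocol, no fixed
species lists, and wildly unequal effort.

The package is for ecologists and biodiversity managers who hold such
opportunistic multi-species sighting tables and want defensible annual
occupancy estimates per species, with detection probability modeled
rather than ignored. It implements the full workflow:

* **Ingestion**: validated record and site tables, deduplication of
  same-species/date/site reports by different observers, species
  inclusion thresholds (≥ 5 presence records every year and > 150 in
  total).
* **Non-detection generation**: visits are (site, date, observer)
  checklists; a species absent from a checklist is an inferred
  non-detection, generated under four schemes of increasing strictness
  (`standard`, `nondet3grp`, `nondet3grp_obs1grp`, `nondet3grp_obs3grp`),
  plus site filters for poorly surveyed sites.
* **Model**: a hierarchical Bayesian multi-season single-species
  occupancy model with calendar-year closure,

      z_it ~ Bernoulli(psi_it)         logit(psi) = intercept + year +
                                         habitat of site + distance to
                                         large forest + site size
      y_ijt ~ Bernoulli(z_it * p_ijt)  logit(p) = intercept + list length +
                                         habitat of observation + observer

  with the observer term a zero-mean normal random effect, quantitative
  covariates standardized, Normal(0, 2.72) priors on fixed effects and
  inverse-Gamma(0.1, 0.1) on the observer variance. Fitting is Gibbs
  sampling with exact Pólya-Gamma data augmentation (compiled in C++),
  the latent z sampled so finite-sample occupancy
  `sum_i z_it / N` is directly available.
* **Selection & checking**: WAIC over an 18-model candidate grid,
  Gelman-Rubin convergence (Rhat < 1.1), 95% credible-interval
  significance, and Freeman-Tukey / Chi-square posterior predictive
  checks grouped by sites and by visit replicates.
* **Derived outputs**: annual finite-sample occupancy series
  (mean ± sd), back-transformed baseline detection, covariate response
  curves, and paired t / Pearson comparisons of per-species estimates
  across dataset variants.
* **Synthetic data**: `simulateChecklists()` generates realistic
  checklist programs with known truth (sites, observers, five species
  groups, short lists, one-year sites), so the whole pipeline is testable
  without any field data.

## Worked example

```r
library(checklistOccupancy)

cfg <- simulationConfig(nSites = 150, nYears = 3, nObservers = 60,
                        occupancyCoefs = list(intercept = 0.4, year = c(0.3, -0.2),
                                              habitat_of_site = 1.0,
                                              distance_to_large_forest = -0.8,
                                              site_size = 0.7),
                        seed = 42)
sim <- simulateChecklists(cfg)
dataset <- deduplicateRecords(sim$dataset)
dataset
#> ChecklistDataset: 5807 records, 150 sites, 61 species, years 2020-2022

visits  <- buildVisits(dataset)
history <- assembleHistory(visits, "monitor_lizard", dataset)
history
#> DetectionHistory for 'monitor_lizard'
#>  2455 visits at 150 sites, 3 seasons, 60 observers
#>  detections: 316  non-detections: 2139

grid <- list(
  occuModelSpec("habitat+effort", c("habitat_of_site", "site_size"),
                c("list_length", "observer")),
  occuModelSpec("intercept-only"))
sel <- selectTopModel(grid, history, chains = 2, iterations = 2000,
                      burnIn = 1000, thin = 2, seed = 1)
sel$ladder
#>          spec_id     waic      lppd   penalty converged max_rhat n_terms
#> 1 habitat+effort 1673.597 -796.0541 40.744491      TRUE 1.005568       4
#> 2 intercept-only 1818.114 -906.9561  2.100742      TRUE 1.000077       0
```

The model with habitat, site size, list length and observer effects wins
by ~145 WAIC points over intercept-only. Its report:

```r
rep <- fitReport(sel$fit, ppc = TRUE, ppcSeed = 1)
rep$coefficients
#>    submodel            term       mean         sd       lower     upper significant
#> 1 occupancy     (Intercept)  0.3417352 0.22724334 -0.05248946 0.8204045       FALSE
#> 2 occupancy habitat_of_site  2.1022746 0.78079060  0.90618098 3.8035540        TRUE
#> 3 occupancy       site_size  0.6697279 0.57718927 -0.22647092 1.8211248       FALSE
#> 4 detection     (Intercept) -1.6074043 0.12147457 -1.84105594 -1.3666301       TRUE
#> 5 detection     list_length  0.6500009 0.07014341  0.51247374 0.7866299        TRUE
#> 6 detection    sigma_sq_obs  0.4218829 0.14605573  0.19901123 0.7660574          NA

round(rep$detection_baseline, 3)   # back-transformed detection intercept
#>  mean    sd
#> 0.168 0.017
round(rep$bayes_p, 2)              # posterior predictive p-values (~0.5 is ideal)
#>         ft_sites    ft_replicates      chisq_sites chisq_replicates
#>             0.49             0.86             0.22             0.93
```

Baseline detection — the probability that one visit by an average
observer with a mean-length list outside forest records the species — is
0.168 ± 0.017: the species is missed on five of six visits to occupied
sites, which is exactly why raw reporting rates mislead. Forest habitat
raises occupancy significantly (coefficient 2.10 on the logit scale);
longer lists raise detection. The annual finite-sample occupancy tracks
the (normally unobservable) simulated truth:

```r
finiteSampleOccupancy(sel$fit)
#>   year occupancy_mean occupancy_sd
#> 1 2020      0.6108333   0.04001244
#> 2 2021      0.6726800   0.03837681
#> 3 2022      0.6268067   0.03528334
colMeans(sim$truth$zFocal)         # realized truth per year
#>      2020      2021      2022
#> 0.6200000 0.6933333 0.5600000
```

`runStudy()` (or `inst/scripts/run-study.R` from a shell) orchestrates
the same steps across all dataset variants and species and emits WAIC
ladders, fit reports, occupancy series and cross-variant comparison
tables.

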