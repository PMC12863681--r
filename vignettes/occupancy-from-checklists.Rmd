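---
title: "Estimating occupancy from unstructured checklist records"
author: "checklistOccupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating occupancy from unstructured checklist records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Opportunistic sighting programs — plantation workers, park rangers,
volunteer naturalists — produce presence-only records with no fixed
protocol: observers report whatever they noticed, usually one to a few
species per outing, with wildly unequal effort across places, dates and
people. The scientific question is nevertheless a standard one: what
proportion of spatial units does a species occupy each year, and is that
proportion changing? Raw reporting rates cannot answer it, because a site
that is visited more often, or by keener observers, will look more
occupied than it is. Occupancy models separate the *state* process (is the
site used by the species this season?) from the *observation* process (was
it recorded on this visit?), and are the standard tool for this class of
data. This package implements that workflow end to end for checklist-style
records: ingestion and validation, deduplication, non-detection
generation, detection-history assembly, a hierarchical Bayesian
multi-season occupancy model, model selection and checking, and the
sensitivity analyses such a design needs.

## The model

Sites $i$ are crossed with calendar-year seasons $t$ (the closure period:
the species is assumed to either use or not use a site for a whole year).
The latent state and the observations are

$$z_{it} \sim \mathrm{Bernoulli}(\psi_{it}), \qquad
  y_{ijt} \mid z_{it} \sim \mathrm{Bernoulli}(z_{it}\, p_{ijt}),$$

with logit-linear submodels

$$\mathrm{logit}(\psi_{it}) = \beta_0 + \beta_{\mathrm{year}(t)}
  + \beta_1\,\mathrm{forestSite}_i + \beta_2\,\mathrm{dist}_i
  + \beta_3\,\mathrm{area}_i,$$
$$\mathrm{logit}(p_{ijt}) = \alpha_0 + \alpha_1\,\mathrm{listLength}_{ijt}
  + \alpha_2\,\mathrm{forestObs}_{ijt} + \eta_{o(ijt)}, \qquad
  \eta_o \sim \mathrm{N}(0, \sigma^2_{\mathrm{obs}}).$$

Year enters occupancy as categorical fixed effects against the first
season; the detection submodel deliberately has no year terms (sparse
checklist data rarely support year-varying detection). The observer effect
$\eta_o$ is a random effect: hundreds of observers contribute, most with
few checklists, and detection heterogeneity between them is large.
Quantitative covariates (distance to large forest, site area, list length)
are standardized to mean 0, sd 1 over the units used for fitting, with the
affine transform recorded so predictions can be issued on natural scales.

There is no colonization/extinction structure: the $z_{it}$ are
conditionally independent across years given $\psi_{it}$ ("stacked" years).
This matches the submodel above — year effects on the occupancy intercept
describe between-season change — and avoids dynamic parameters the data
could not inform.

Our interest is *finite-sample* occupancy: the realized fraction
$\sum_i z_{it} / N$ of the fitted sites occupied in season $t$, summarized
by its posterior mean and sd. Because $z$ is sampled rather than
marginalized, this quantity is available directly from the draws. The
denominator $N$ is, by default, the number of sites with at least one
visit; `assembleHistory(sitePopulation = "all")` switches to the full site
table, since with opportunistic data it is genuinely ambiguous whether the
statistical population is "sites that were surveyed" or "sites that
exist".

## From presence-only records to detection histories

A **visit** is a unique (site, date, observer) combination with at least
one record: since observer identity is a detection covariate, two people
at the same site on the same day are two replicates. Records of the same
species, date and site by different observers are first **deduplicated**
(they frequently describe the same sighting made by people in the field
together); the record of the observer with the longest list at that site
and date is kept, remaining ties going to the lexicographically smallest
observer id — a deterministic rule that preserves the most informative
checklist.

Because observers keep no fixed lists, a non-detection ("the species was
not on the checklist") is an inference, not an observation, and there is
no unique way to generate one. Four schemes are implemented:

* **standard** — every visit generates a non-detection for every
  unreported study species;
* **nondet3grp** — plant and insect records are discarded first, so only
  visits that reported birds, mammals or reptiles generate
  non-detections (list lengths are recomputed over the three groups, and
  emptied visits vanish);
* **nondet3grp_obs1grp** — additionally, only observers who recorded the
  focal species' group at least once anywhere in the dataset;
* **nondet3grp_obs3grp** — only observers who recorded all three study
  groups.

Observer eligibility is judged over the whole dataset rather than per
year: the schemes describe what kind of observer someone is, not what they
happened to record in one season. Note a structural consequence used by
the sensitivity tests: the schemes remove *visits*, never flip surviving
detections, so focal detections under any scheme are a subset of those
under `standard`.

Two site filters address survey imbalance: dropping sites whose records
span a single calendar year, and dropping sites recorded only in the final
season.

## Priors, sampler, numerics

Fixed effects get independent Normal(0, 2.72) priors on the logit scale
and the observer variance an inverse-Gamma(0.1, 0.1) — the conventional
weakly informative defaults for Bayesian occupancy models of this form,
exposed through `occuPriors()`. Sampling is plain Gibbs with Pólya-Gamma
data augmentation: each logistic submodel becomes conditionally Gaussian
given auxiliary PG(1, ·) variables, the latent $z$ at undetected
site-years has a closed-form Bernoulli conditional
$\psi q / (\psi q + 1 - \psi)$ with $q = \prod_j (1 - p_{ijt})$, and
$\sigma^2_{\mathrm{obs}}$ is conjugate. The PG(1, z) draw is the exact
alternating-series rejection sampler (no truncation approximation); it is
validated in the test suite against the closed-form mean
$\tanh(z/2)/(2z)$. All randomness flows through R's RNG, so a fixed seed
reproduces every draw bit-for-bit, across the whole pipeline.

Numerical choices worth knowing:

* linear predictors are clipped at ±35 before exponentiation — far
  outside any statistically meaningful logit, but it keeps degenerate
  configurations finite;
* the per-site-year marginal log-likelihood (latent state integrated out)
  is stored at every retained draw; an all-zero history contributes
  $\log(\psi \prod_j (1-p) + 1 - \psi)$ via log-sum-exp, and a site-year
  with no visits contributes exactly 0 while still carrying a latent
  state;
* WAIC is computed from those pointwise values with log-sum-exp
  stabilization; ties in model selection go to the spec with fewer terms;
* the Chi-square discrepancy uses a stabilizing constant $10^{-4}$ in
  denominators; posterior predictive p-values count ties in the upper
  tail;
* chains are initialized from mildly dispersed draws and run
  sequentially from one seed, so "same seed, same results" holds for any
  chain count.

Default sampler settings mirror a production run (3 chains of 60,000
iterations, 50,000 burn-in, thinning 10); tests and examples use reduced
settings, which the Gelman-Rubin diagnostic (threshold 1.1) shows to be
adequate at the simulated data sizes.

## Model selection and checking

`defaultModelGrid()` ships 18 candidate specs: the full model, all
single-term deletions of either submodel, intercept-only variants,
single-covariate occupancy submodels with full detection, and reduced
detection submodels that keep list length (with and without the observer
effect). The exact published grids of comparable field studies are rarely
printed in full; this grid is a reconstruction anchored on the models such
studies actually name, and every function that takes a grid accepts a
user-supplied list instead. `selectTopModel()` fits all specs with a
shared seed policy, ranks by WAIC, and flags — but does not drop —
non-converged fits.

Posterior predictive checks use both the Freeman-Tukey statistic
$\sum_g (\sqrt{o_g} - \sqrt{e_g})^2$ and the Chi-square statistic, with
detections grouped across sites (per-site totals over all seasons and
visits) or across replicates (per within-site-year visit rank). At each
retained draw, replicate detections are simulated conditional on that
draw's latent states ($y^{rep} \sim \mathrm{Bernoulli}(z p)$ — the
convention of standard occupancy software), and both observed and
replicate group counts are compared with the expected counts from the
draw's $\psi p$ structure. A p-value near 0.5 indicates a good fit; the
package reports all four combinations.

Two honest caveats, both verified in the validation experiments. First,
because replicates condition on $z$, the check is chiefly sensitive to
*detection-side* misfit (for instance a site-level covariate of detection
left out of the model); occupancy-side misfit is largely absorbed by the
latent states, and when detection is so low that occupied site-years
frequently end up with all-zero histories, the latent states can absorb
detection misfit too — the check has real power only where replication
per site-year is adequate. Second, WAIC computed from likelihoods
conditional on the sampled observer effects tends to retain the observer
term even when the true observer variance is zero — a known property of
conditional information criteria, and consistent with observer models
ranking high in field applications. Comparisons meant to probe covariate
structure should therefore compare specs that agree on the observer
term.

## The synthetic-data generator

`simulateChecklists()` emulates the structure of a real plantation
recording program, because the raw field data such programs produce are
typically not public. What it reproduces: a site universe of a few hundred
production blocks and forest sites with areas, distances to large forest
and forest-patch flags; five species groups with short, commonness-biased
checklists, birds dominating the reporting and plants/insects in the
minority — so discarding the latter two removes only a small share of
checklists, as in real programs of this kind; several hundred observers
of heterogeneous quality (normal
random effects on detection) and optionally of specialized group
interests; Poisson visit counts per surveyed site-year (default mean 7,
matching 6–8 visits per site and year in the motivating program); a
configurable fraction of sites surveyed in a single year (default 28%);
and one focal species following the full occupancy/detection model above.
Filler species carry their own latent presence states, so no species is
ever recorded where its true state is absent — which is what makes the
scheme-sensitivity experiments meaningful rather than cosmetic.

List length is drawn as $1 + \mathrm{Poisson}$, and a detected focal
species occupies one of those slots. This keeps the list-length covariate
exogenous to the focal detection outcome: the alternative (appending the
focal to the list) feeds the outcome back into its own covariate and
would make even the generating model slightly misspecified. Distance is
exponential and area log-normal (forest sites scaled up), qualitative
choices matching "mostly small plots, a few large forest blocks".

What the generator does *not* emulate: spatial autocorrelation or any
point process for sightings (sites are exchangeable given covariates),
phenology or within-year effort waves, misidentification, and
colonization/extinction dynamics. Passing tests on this generator
therefore demonstrates that the pipeline recovers the truth *of this
generative family* — unmodeled spatial structure or seasonal closure
violations in real data are outside what these tests can certify.

Scenario defaults (`scenarioLibrary()`) are fixed once: `kal_like` for
structure checks, `kal_like_small` (300 sites, 5 seasons, baseline
detection 0.2, effects at most 1.5 on the logit scale) for parameter
recovery, `high_detection` / `low_detection` (baseline 0.5 / 0.05) for
the precision contrast, `no_covariate_effects` (all effects and the
observer variance zero) for null model selection, and
`scheme_sensitivity` (specialized observers) to make the four
non-detection schemes genuinely differ.

## Problem sizes used by the tests

The test suite and the acceptance script run reduced designs chosen to
exercise every moving part at simulation sizes a single workstation
handles comfortably: likelihood oracle instances of at most 5 sites × 2
years against brute-force enumeration over all latent-state
configurations; parameter recovery on `kal_like_small` replicates at 3
chains × 6,000 iterations (burn 3,000, thin 3); model selection,
calibration and scheme sensitivity on 100–150-site designs at around
1,200–1,500 iterations per chain. These sizes are the package's own
validation design; the fitting functions themselves have no size-specific
assumptions.

## Known limitations

* No spatial random fields: the distance-to-forest covariate is the only
  spatial structure. Residual spatial autocorrelation will show up as
  lack of fit (low Freeman-Tukey p-values grouped by sites), not be
  corrected.
* Detection is assumed constant across years; programs whose observer
  corps improves over time violate this.
* The year-long closure assumption suits resident species only.
* Finite-sample occupancy precision collapses when detection drops below
  roughly 0.1–0.2 per visit; the model reports this honestly as wide
  posteriors rather than failing, and the precision contrast in the
  acceptance checks quantifies it.
* The deduplication tie-break and the visit definition are reasonable
  conventions, not identifiable from the data; both are documented and
  deterministic.
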