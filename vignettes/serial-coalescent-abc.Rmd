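---
title: "Serial coalescent ABC for ancient and modern mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial coalescent ABC for ancient and modern mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialabc)
```

## The inference problem

`serialabc` asks a classic question of ancient-DNA population genetics: are
the people living in a region today the maternal descendants of the people
who lived there thousands of years earlier, or were those early inhabitants
replaced by later immigrants? The motivating setting is Sardinia: a handful
of Mesolithic mitogenomes from the island, a modern sample from an isolated
Sardinian population, and Early/Middle Neolithic mitogenomes from
continental Europe as a stand-in for the source of Neolithic migrants.
Because a single non-recombining locus carries limited information, the
package frames the question as explicit model comparison by Approximate
Bayesian Computation (ABC): simulate whole-mitogenome samples under
competing demographic models, summarize them with the same statistics as
the observed data, and ask which model reproduces the observation.

Three genealogical models are compared:

* **continuity** — modern islanders descend entirely from the local
  Mesolithic population (admixture proportion P = 0);
* **discontinuity** — complete replacement by continental Neolithic
  lineages (P = 1);
* **admixture** — a mixture, with P (the fraction of modern island
  lineages of continental Neolithic origin) free up to 0.75.

A fourth model, **admixture_tot**, frees P over the whole of [0, 1] and is
used for parameter estimation, since it nests the other three: its event
schedule with P = 0 or P = 1 is identical, event for event, to the
continuity and discontinuity schedules.

## The demographic model and its parameters

Two demes exist, the island ("sardinia") and the mainland ("continent").
Looking backwards in time from the present:

* at 6,000 years BP (200 generations at 30 y/generation) a fraction P of
  island lineages moves to the continent — this is the Neolithic pulse —
  and both demes switch from their current sizes (`Ncs`, `Ncn`) to their
  ancient sizes (`Nas`, `Nan`);
* at the island colonization time `Tcol` every remaining island lineage
  moves to the continent, preceded by a founder bottleneck in which the
  island size is `Nas / rs` for 10 generations;
* the continent deme is the single ancestral population.

The eight parameters and their default priors:

| parameter | meaning | prior |
|---|---|---|
| `P` | proportion of modern island lineages of Neolithic origin | fixed 0 / fixed 1 / U(0, 0.75) / U(0, 1) by model |
| `rs` | colonization bottleneck reduction factor (size divided by `rs`) | log-uniform(1, 100) |
| `Nan`, `Nas` | ancient continental / island haploid sizes | log-uniform(100, 10,000) |
| `Ncn`, `Ncs` | current continental / island haploid sizes | log-uniform(1,000, 100,000) |
| `mut` | mutation rate, per nucleotide per year | uniform(1e-8, 4e-8) |
| `Tcol` | island colonization time, years BP | uniform(10,500, 21,000) |

Sizes are haploid effective sizes, the natural unit for mtDNA: a deme of
size N gives each lineage pair a coalescence rate of 1/N per generation.
The log-uniform shape spreads prior mass evenly over orders of magnitude,
the usual weakly-informative choice for population sizes; the 100–10,000
interval for the ancient sizes matches the broad range a small prehistoric
population could plausibly occupy, and the mutation-rate interval brackets
published whole-mitogenome rate estimates (~2–3 × 10⁻⁸ /nt/year). `Tcol`'s
lower bound keeps colonization strictly older than the oldest (10,000 yBP)
sample, which the schedule compiler also enforces with an explicit error.
All bounds are configurable through `default_priors()`.

The default `study_design()` fixes the sampling scheme: 63 modern island
mitogenomes (MS, 0 yBP), 2 Mesolithic island mitogenomes (MSS,
10,000 yBP), 28 Early Neolithic (EN, 8,700 yBP) and 18 Middle Neolithic
(MN, 7,700 yBP) continental mitogenomes, one 16,569-site non-recombining
locus, 30 years per generation. Ancient samples sit on their branch at the
average of their dating interval, converted to generations by
`round(years / 30)` (MSS 333, EN 290, MN 257). Rounding half-up at the
generation scale moves a sample by at most 15 years, far below dating
uncertainty.

## The simulator

`simulate_genealogy()` implements the serial-sampling coalescent in
continuous time: within a deme the next coalescence is exponential with
rate k(k−1)/(2N); lineages activate at their sampling times; pulse events
move each lineage of the source deme independently with the event's
probability (probability 1 moves all lineages deterministically).
Continuous waiting times rather than generation-by-generation bookkeeping
make the cost per genealogy linear in the number of events, so the
131-leaf study design simulates in well under a millisecond; the engine is
compiled code, with all randomness drawn from R's RNG so `set.seed()`
governs every replicate.

`drop_mutations()` uses a finite-sites, two-state model: branch mutation
counts are Poisson with mean `mut × 30 × L × branch length`, each mutation
hits a uniform site, and a repeat hit toggles the site back. The summary
panel depends only on the allele partition at each site, so two states
lose nothing relative to a four-letter alphabet at mtDNA divergence levels
(a 16,569-site locus at these rates carries a few hundred variable sites;
double hits are rare). For file realism, `write_study_alignment()` maps
the binary states onto a random reference background as transitions
(A↔G, C↔T) — a purely cosmetic export layer whose round-trip is tested to
reproduce the panel exactly.

Reference tables (`build_reference_table()`) seed row i with
`(master seed + i) mod (2^31 − 1)`, which makes tables reproducible,
extendable (the first rows of a longer table equal the shorter table), and
trivially parallelizable.

## The summary panel

`compute_panel()` evaluates 31 statistics in a fixed, versioned order: for
each population, segregating sites S, distinct haplotypes H, haplotype
diversity, nucleotide diversity π, and Tajima's D where n ≥ 4 (the n = 2
Mesolithic sample cannot support D); for each of the six population pairs,
Hudson's FST (1 − π_within/d_xy, clamped to [−1, 1], 0 when d_xy = 0) and
the mean between-population pairwise difference d_xy. The panel captures
within-population diversity on each branch and every pairwise affinity the
three models disagree about — above all whether modern islanders are
closer to the Mesolithic islanders or to the Neolithic continentals.
S = 0 yields D = 0 by convention, matching common ABC tooling. Hudson's
estimator is used because it is well defined for haploid sequence samples
without allele-frequency weighting assumptions.

## ABC machinery

**Model choice** (`model_posteriors()`) pools the candidate models'
tables, standardizes every statistic by its pooled standard deviation,
retains the simulations closest to the observation in Euclidean distance,
and fits a weighted multinomial logistic regression of the model label on
the standardized statistics (Epanechnikov weights 1 − (d/d_max)²,
evaluated at the observed point). Raw standardized statistics, not PLS
scores, are the covariates — the convention of widely used ABC model-choice
implementations; PLS components are fitted against parameters and are
therefore a parameter-estimation device. A ridge penalty of 1e-6
stabilizes the fit under complete separation (which is expected when one
model's cloud sits far from the observation); a model absent from the
retained set receives probability zero with a warning. Results are
reported across retention thresholds (default 1,000 / 5,000 / 10,000 /
50,000, capped at the pool) so the stability of the choice is visible.

**Parameter estimation** (`estimate_parameters()`) is Beaumont-style
local-linear adjustment: each parameter is mapped to the real line by the
logtan transform `ln(tan(π/2 (x − a)/(b − a)))` using its prior bounds, so
the back-transform confines every adjusted draw to the prior support;
the transformed parameter is regressed on the PLS scores of the retained
statistics with Epanechnikov weights; each retained draw is shifted along
the fitted plane to the observed point and back-transformed. PLS (NIPALS,
7 components by default) is fitted on a held-out slice of the table
(first 10,000 rows by default) against all logtan-transformed parameters
jointly. Summaries per parameter: weighted median; mode as the argmax of a
weighted Gaussian-kernel density (Silverman bandwidth, 512-point grid);
95% HPD as the smallest density-ordered region holding 95% of the weight;
and R² of the transformed parameter on the PLS scores over the retained
set — R² is computed on the transformed scale because bounded supports make
raw-scale R² ill-behaved near the bounds. Degenerate retained sets (all
weights on identical rows) fall back to plain rejection with a warning.

**Fit diagnostics.** `glm_ppp_value()` fits a multivariate normal to the
retained statistics and reports the fraction of retained simulations whose
density falls below the observed point's density — an observation the
retained cloud cannot reproduce scores near 0. `pca_fit_check()` projects
each model's best simulations onto their first two principal components
and reports the observed point's Mahalanobis percentile per model.

## The power study

`generate_pods()` + `model_choice_power()` reproduce the
pseudo-observed-data experiment: datasets simulated under a known model
are pushed through model choice, and the report counts, per model, how
often it is correctly selected (TPR) and how often it is selected for pods
generated under the other models (FPR, pooled across the alternative
models). Selection is "highest posterior probability", ties broken toward
the first model in table order. `parameter_recovery()` scores posterior
medians (bias, RMSE) and 95% HPD intervals (empirical coverage) over pods.

The package's desk-scale study conditions — used by the test suite and the
acceptance script — are 20,000-row reference tables per model, 200 pods
per model, and 2,000 retained simulations for model choice. The retained
fraction (2,000 of 60,000 pooled) matches the headline fraction of the
original-scale analysis (50,000 of 1,500,000); pod counts were chosen so a
rate of 0.1 carries a binomial standard error near 0.02. These sizes are
the package's defaults for a single-workstation replication; the full
500,000-simulation / 1,000-pod experiment is the same code with larger
arguments.

## What the synthetic data does and does not emulate

`make_study_dataset()` produces observed-like bundles (FASTA + metadata +
truth JSON) under any scenario; the `"paper-posterior"` preset uses the
point estimates of the admixture_tot posterior (Nas = 793, Ncs = 21,371,
Nan = 2,649, Ncn = 38,574, mut = 2.1e-8, rs = 1.647) with the colonization
time at the middle of its prior, 15,750 yBP, which the posterior leaves
essentially unconstrained. The generator emulates the *structure* of the
real data — sample sizes, sampling ages, locus length, serial placement —
and the coalescent signal of the chosen demography. It does not emulate
ancient-DNA damage, contamination, coverage gaps, site-specific rate
heterogeneity, or the real mitochondrial site-frequency landscape.
Passing tests therefore demonstrate that the inference machinery is
correct and well calibrated *under the model class it assumes*, not that
the historical conclusions for any real dataset are beyond doubt.

## Numerical choices and edge cases

* Distances use pooled-SD standardization; constant statistics are
  dropped with a warning rather than propagating NaNs.
* Epanechnikov weights give the farthest retained simulation weight 0; if
  every retained distance is 0 (duplicated tables), equal weights are
  used.
* logtan clamps inputs an epsilon — (b − a) × 1e-9 — inside their bounds,
  so prior draws that land exactly on a bound do not produce infinities.
* Weighted medians use the cumulative-weight step function; HPD intervals
  are reported as the envelope of the selected grid cells, which always
  contains the weighted median.
* Tie-breaking in model selection (`which.max`) prefers the
  earlier-listed model; the power-study report notes this convention.
* The schedule compiler refuses `Tcol` at or below the oldest sampling
  age ("colonization postdates sample").

## Known limitations

* Two demes, two pulse events, instantaneous size changes: no continuous
  migration, growth curves, or additional populations.
* The two-state mutation model ignores transition/transversion structure;
  the four-letter export is cosmetic.
* The multivariate-normal posterior-predictive p-value is a parametric
  stand-in for density-based goodness-of-fit scores used by some ABC
  toolkits; with 31 moderately correlated statistics it is conservative.
* Whole-panel PLS is fitted once per table; per-parameter PLS tuning
  (choosing k by cross-validation) is left to the user via the exposed
  `k` argument.
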