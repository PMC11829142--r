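---
title: "Methods: geographic access and representativeness in trial networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geographic access and representativeness in trial networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialaccess)
```

## The problem

Patients are usually treated at their nearest secondary-care provider, but
only some providers recruit to clinical trials. This package quantifies two
consequences of that mismatch for a cancer-like disease with several
subtypes (we use lymphoma subtypes — DLBCL, HL, FL, MCL, PTCL — as the
running example):

1. **Geographic barriers.** How far is each small area (an English LSOA-like
   unit of 1000–3000 residents, represented by its population-weighted
   centroid) from its nearest *research-active* provider, how much of that
   distance is *excess* over the nearest care provider, and which area
   characteristics predict the burden?
2. **Representation.** Do the patients enrolled in trials (as reported in
   publications, typically only age and sex) resemble the incident patient
   population held in a cancer registry?

All inputs are plain CSV tables: areas, facilities, trials, annual
recruitment per (trial, facility, year), registry patients with candidate
organisational records, and per-trial published summary statistics.

## Research-activity definitions

A facility is classified "research active" in five ways:

* **Definition 1 (primary).** Its *weighted recruitment* — total patients
  recruited divided by its mean annual incident patient population — is
  *strictly greater than the median* weighted recruitment across all
  facilities. We read "above the median" strictly: with `n` all-distinct
  values exactly `floor(n/2)` facilities are active, the median facility
  itself is inactive, and with every value tied nobody is active. With 127
  facilities of which 80 have distinct positive ratios and 47 have zero,
  this rule yields exactly 63 active facilities — the only reading of a
  midpoint split consistent with that count. The active set is invariant to
  any monotone rescaling of the ratios.
* **Definition 2.** Participation in at least one trial of any subtype,
  counting trials joined with zero recruits.
* **Definitions 3–5.** Participation in at least one DLBCL / HL / FL trial
  respectively. Activity under 3–5 implies activity under 2.

A facility that recruits patients while treating no incident patients makes
the weighting undefined; we surface this as an error rather than imputing.
The recruitment window and the incidence window are configured
independently (`activity_input(recruit_years = ...)`), since recruitment is
often observed over a longer period than incidence; provider renamings and
mergers are handled by an optional two-column lookup applied before
aggregation.

## Distance, travel time and excess distance

Distances are great-circle (haversine) distances between WGS84 decimal
degree coordinates on a sphere of radius 6371.0088 km (the IUGG mean
radius; the choice of radius is documented rather than inherited from any
routing engine). Population-weighted centroids are taken as given; no
polygon work is done. For each area we compute

* `d_care` — distance to the nearest care-providing facility,
* `d_active` — distance to the nearest research-active facility, and
* `excess = d_active − d_care` when the nearest care facility is inactive,
  0 otherwise,

so `d_active ≥ d_care ≥ 0`, `excess ≥ 0`, and `excess = 0` exactly when the
nearest care facility is active. Exact distance ties are broken towards the
lexicographically smallest facility id, making results independent of row
order. Travel time is a pluggable provider: the default converts distance
at a constant 50 km/h and is explicitly a straight-line stand-in, not road
routing; a provider failure propagates with the offending coordinates
rather than being imputed. Results export to CSV or to a GeoJSON
FeatureCollection of points for mapping.

## Patient assignment and group comparison

A registry patient's facility of care is resolved by a configurable
*cascade* of organisational record sources: the first record whose source
tag appears earliest in the cascade wins. The default order —
`decision_to_treat`, `treatment_record`, `diagnosis_record` — mirrors a
primary decision-to-treat record taking precedence over inferred records.
Patients matching no cascade tag are *unassigned*: counted, reported, and
excluded from incidence denominators rather than treated as an error.

Mean annual incidence per facility and subtype is the count of assigned
patients diagnosed in the window divided by the number of years. The share
of the incident population treated at active facilities and its complement
sum to 100 by construction. Patient characteristics between active and
inactive providers are compared with Welch's *t* (age), Pearson chi-squared
without continuity correction (sex, ethnicity), and a Cochran–Armitage
trend test with equally spaced scores across the five income-deprivation
quintiles. Two deprivation variables coexist deliberately: patients carry an
income-domain *quintile* while areas carry an overall deprivation *decile*
(1 = most deprived in both), because the two analyses conventionally use
different indices.

## Pooling published trial summaries

Per-trial published age summaries arrive either as mean/SD or as
median/quartiles. The latter are converted with the quantile-based
approximation of Wan et al. (2014), scenario C3:

\[
\bar{x} \approx \frac{q_1 + m + q_3}{3}, \qquad
s \approx \frac{q_3 - q_1}{2\, z\!\left(\frac{0.75n - 0.125}{n + 0.25}\right)},
\]

which tends to the familiar IQR/1.349 rule as \(n \to \infty\), is exact
for symmetric three-point inputs, and is location/scale equivariant. The
cited "common procedure" in the literature does not print formulas; Wan et
al. is the standard reading and is implemented as such. Converted trials
then pool by subtype with the exact grouped-data identity
\(\sum[(n_i-1)s_i^2 + n_i(\bar x_i - \bar x)^2]/(\sum n_i - 1)\), so that
when every trial reports exact raw-data statistics the pooled values equal
the statistics of the concatenated raw data.

The pooled enrolee population is compared with the registry by subtype:
Welch's *t* on mean age (computed from summary statistics, with
Welch–Satterthwaite degrees of freedom), and a two-sample 2×2 chi-squared
on the sex split — the registry side is treated as an independent sample,
not a known fixed proportion. Scenario filters restrict the pooled set to
first-line trials, trials without age-restricting eligibility, or phase II
trials; the registry comparator is not re-windowed to trial-open years by
default (both windows are available to the caller, and the default keeps
the full registry so scenarios differ only in the trial side).

### A note on the conversion's per-sample accuracy

The converted mean is *unbiased* but noisier than the sample mean: at
n = 200 from Normal(65, 12) its deviation from the sample mean has SD
≈ 0.34 years, so individual conversions land within 0.5 years of the
sample mean in roughly 84% of samples, and the converted SD within 1.5
years in roughly 94%. The tests therefore check the averaged (bias)
behaviour at tight tolerances and the per-sample behaviour at the rates a
direct simulation supports.

## Ecological regression

The area-level distance response is regressed by ordinary least squares on
exactly six regressors: area mean age, percentage male, percentage in the
majority ethnic group, deprivation decile (one linear term, not dummies),
rural flag and coastal/border flag, plus an intercept. Classical
(non-robust) standard errors; no spatial-autocorrelation correction, no
model selection; covariates enter in raw units without standardisation.
The fit is unweighted over areas by default — no weighting statement
accompanies the published convention we follow — with population weights
available behind a flag. Rank-deficient designs are rejected with the
collinear columns named. A travel-time response can be fitted through the
same interface.

## The synthetic-data generator

Real registry, recruitment and census extracts are access-restricted, so
the generator is a first-class module: every downstream stage is tested by
recovering parameters the generator planted.

* **Geography.** Facilities sit in a handful of urban cluster centres;
  urban areas scatter tightly (SD 0.15°) around the same centres while
  rural areas are uniform over an England-sized bounding box, so rurality
  has a true positive nearest-distance effect *by construction*. Area
  sociodemographics: mean age ~ Normal(41, 4) truncated to [25, 60], %
  male ~ Normal(49.5, 1.5), % majority ethnicity ~ Normal(85, 12) clamped
  to [0, 100], deprivation decile uniform on 1..10, rural and
  coastal/border flags Bernoulli (defaults 0.2 and 0.25).
* **Planted distance.** Each area also gets
  `d_planted = α + Xβ + Normal(0, noise_sd)`, the exact linear ground truth
  for regression recovery. Default β plants age +0.400, % male +0.386, %
  majority ethnicity +0.123, deprivation decile −0.216, rural +8.003 and
  coastal +2.750 km per unit with α = −22.189 km and 5 km noise — the
  direction and scale of effects the geometric construction also produces.
  At these defaults the linear predictor is negative with probability
  ~1e−4; values are floored at 0, a truncation far below the sampling
  noise of any recovery test.
* **Recruitment.** A planted subset (`frac_active`, default one half) of
  facilities carries all recruitment; the rest join no trial. Counts per
  trial-facility-year are Poisson with a shared per-facility gamma frailty
  of shape `recruit_shape` (a negative-binomial mixture) — a stand-in for
  an unobserved skewness mechanism, chosen because it nests both extremes:
  small shapes give the heavily skewed totals seen in practice, large
  shapes make facilities exchangeable. Zero-count rows are kept (they
  encode participation), and each active facility is guaranteed ≥ 1
  recruit so that the median split recovers the planted set exactly.
* **Patients.** Subtype-specific age normals (DLBCL-like Normal(69, 14),
  HL-like Normal(47, 20), FL-like Normal(65, 13), MCL-like Normal(72, 11),
  PTCL-like Normal(66, 14), truncated at 0) and male proportions; home
  area proportional to area population; deprivation quintile inherited as
  `ceiling(decile/2)`; 1–3 organisational records per patient whose
  priority-resolved facility is stored as ground truth, with occasional
  disagreeing fallback records so cascade order matters.
* **Trial summaries.** Enrolees are drawn from the subtype age model
  shifted younger by `repr_age_shift` (default 10 years) with the male
  share raised by `repr_male_shift` (default 3 points); odd-indexed trials
  report mean/SD, even-indexed trials report median/quartiles of the same
  simulated enrolees, exercising the conversion path. Trials with fewer
  than 2 enrolees are excluded with a message.

One master seed feeds a fixed per-table substream (`seed -> table index`),
so any table regenerates independently and bit-identically — test isolation
without cross-table coupling.

**What the generator does not emulate:** real road networks and coastline
geometry, spatial autocorrelation of deprivation and ethnicity, temporal
recruitment trends, within-area heterogeneity, and registry linkage error.
Passing recovery tests therefore demonstrate that the *estimators* are
correct under the stated model, not that real extracts would satisfy the
model.

## Numerical and design choices

* Strictly-greater-than-median rule for definition 1; ties at the median
  are inactive.
* Chi-squared tests default to no Yates continuity correction (large-sample
  practice at registry scale); a flag restores it.
* Welch's *t* with both SDs zero and equal means returns p = 1 by
  convention, with a message.
* Distance ties break lexicographically; all pipeline outputs are invariant
  to row permutations of their inputs.
* Simulation-based tests use fixed seeds and modest problem sizes chosen so
  the whole suite runs in about a minute: parameter-recovery replicates use
  5000 areas × 200 replicates for the regression, 2000 null replicates for
  Welch calibration, and 300–500 replicates elsewhere. These sizes were
  chosen once, from the precision the assertions need (e.g. a 3-sigma
  margin on a binomial rate), and are not tuned to outcomes.

## Known limitations

Straight-line travel at a constant speed understates true burden in exactly
the rural and coastal areas the analysis highlights; ecological regression
supports area-level, not individual-level, inference; the activity
dichotomies ignore temporal trajectories; and pooled trial summaries
inherit whatever reporting biases the underlying publications carry.
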