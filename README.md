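# trialaccess

Who gets to join a clinical trial often depends on where they live: most
patients are treated at their nearest secondary-care provider, and if that
provider does not recruit to trials they face both a knowledge barrier and
an extra journey. `trialaccess` is an R package for quantifying those
geographic barriers and for testing how well trial enrolees represent the
incident patient population, using the kind of data a national trial
portfolio, a cancer registry and a census provide: small areas with
population-weighted centroids and sociodemographics, facility coordinates,
per-facility annual trial recruitment, registry patients with candidate
organisational records, and published per-trial age/sex summaries. The
running example is lymphoma (subtypes DLBCL, HL, FL, MCL, PTCL), but
nothing in the machinery is disease-specific.

## What it computes

* **Research-activity classification.** Five definitions of a "research
  active" facility: (1) incidence-weighted recruitment — total recruits
  divided by mean annual incident patients, `w_i = R_i / I_i` — strictly
  above the median across facilities; (2) participation in ≥ 1 trial of
  any subtype; (3–5) participation in ≥ 1 DLBCL / HL / FL trial.
* **Access geometry.** Haversine distance (sphere radius 6371.0088 km)
  from each area centroid to its nearest care-providing and nearest
  research-active facility, the excess distance
  `excess = d_active − d_care` incurred when the nearest care provider is
  inactive, and travel time via a pluggable provider (default: straight
  line at 50 km/h).
* **Catchment comparison.** Registry patients assigned to a facility of
  care through a priority cascade of organisational records; per-facility
  mean annual incidence; the share of the incident population at active
  facilities; and active-vs-inactive comparisons of age (Welch's *t*),
  sex and ethnicity (Pearson chi-squared) and deprivation quintile
  (Cochran–Armitage trend).
* **Representativeness.** Published per-trial summaries — median/IQR
  reports converted to mean/SD by the Wan et al. (2014) approximation
  `mean ≈ (q1 + m + q3)/3`, `sd ≈ (q3 − q1) / (2 z((0.75n − 0.125)/(n + 0.25)))`
  — pooled per subtype with the exact grouped-data variance identity and
  tested against the registry population.
* **Ecological regression.** OLS of area distance on mean age, % male,
  % majority ethnicity, deprivation decile, rural and coastal/border
  flags.
* **Synthetic studies.** A generator with planted, recoverable ground
  truth (active sets, ecological coefficients, representativeness gaps)
  so the whole pipeline is testable without restricted data.

## Worked example

```r
library(trialaccess)

cfg <- synth_config(n_areas = 500, n_facilities = 16, n_patients = 4000, seed = 2024)
st  <- synth_study(cfg)

# assign registry patients to their facility of care, compute incidence,
# classify facilities under definition 1
pts <- st$patients
pts$facility_id <- assign_facility(st$org_records, patient_ids = pts$patient_id)$facility_id
inc <- mean_annual_incidence(pts, cfg$years)
ai  <- activity_input(st$recruitment, st$trials, inc[inc$subtype == "all", ])
lab <- classify_def1(ai$inputs)
sum(lab$active)                       # 8 of 16 facilities active
round(active_share(inc, lab), 1)      # active 45.8 / inactive 54.2 (% of patients)

# distance burden to the nearest research-active facility
acc <- access_table(st$areas, st$facilities, lab$facility_id[lab$active])
access_summary(acc)
#> median d_active 17.9 km (IQR 9.8-30.7, max 436.0)
#> 53.8% of areas have an inactive nearest care facility

# ecological regression on the planted linear distance
fit_distance_model(st$areas, response = "d_planted")
#> ecological OLS fit: 500 areas, R^2 = 0.370, residual SD = 5.26 km
#>                 term estimate std_error p_value
#>             mean_age    0.437     0.058 < 0.001
#>             pct_male    0.459     0.166 0.00577
#>  pct_ethnic_majority    0.130     0.021 < 0.001
#>           imd_decile   -0.200     0.084 0.01797
#>                rural    8.006     0.591 < 0.001
#>       coastal_border    2.671     0.550 < 0.001
#>             constant  -28.070     8.758 0.00144

# are trial enrolees representative? (a 10-year age gap and +3pp male
# share were planted)
representativeness_report(st$trial_summaries, st$patients, "all")
#>   subtype n_enrolled age_diff    age_p male_diff_pp male_p
#>     DLBCL        598   -10.21 1.17e-47         1.38  0.556
#>        FL        126    -9.77 7.79e-13         1.59  0.739
#>        HL        345   -10.43 1.73e-14         5.06  0.130
#>      PTCL        134   -10.29 1.46e-12         1.08  0.829
```

The regression recovers the planted coefficients (rural +8.0 km, coastal
+2.8 km, deprivation −0.22 km per decile) within sampling error; the
representativeness report recovers the planted ~10-year enrolee age
deficit in every subtype, while the +3-point male excess — realistically
small — is not individually significant at these trial sizes.

Every table also round-trips through plain CSV (`write_synth_csv()`,
`read_geo_csv()`), and access results export as a GeoJSON point layer
(`write_access_geojson()`) for mapping.

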