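test_that("configuration invariants are enforced", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(n_areas = 5, n_facilities = 10), "n_areas >= n_facilities")
  expect_error(synth_config(n_facilities = 1), "n_facilities >= 2")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_error(synth_config(frac_active = 0), "frac_active")
  expect_error(synth_config(frac_active = 1), "frac_active")
  expect_error(synth_config(bbox = c(lon_min = 0, lon_max = 0,
                                     lat_min = 50, lat_max = 55)), "degenerate bbox")
  expect_error(synth_config(recruit_shape = 0), "recruit_shape")
})

test_that("a fixed seed reproduces every table bit-identically", {
  cfg <- synth_config(n_areas = 120, n_facilities = 6, n_patients = 400,
                      n_trials = 8, seed = 33)
  s1 <- suppressMessages(synth_study(cfg))
  s2 <- suppressMessages(synth_study(cfg))
  for (tab in c("areas", "facilities", "trials", "recruitment", "patients",
                "org_records", "trial_summaries"))
    expect_identical(s1[[tab]], s2[[tab]])
  # per-table substreams: a table regenerated alone matches the full run
  expect_identical(generate_geography(cfg)$areas, s1$areas)
  expect_identical(suppressMessages(
    generate_trial_summaries(cfg, s1$patients, s1$trials)), s1$trial_summaries)
})

test_that("generated values respect their documented ranges", {
  st <- small_study()$st
  a <- st$areas
  expect_true(all(a$pct_male >= 0 & a$pct_male <= 100))
  expect_true(all(a$pct_ethnic_majority >= 0 & a$pct_ethnic_majority <= 100))
  expect_true(all(a$imd_decile %in% 1:10))
  expect_true(all(a$mean_age >= 25 & a$mean_age <= 60))
  expect_true(all(a$rural %in% 0:1 & a$coastal_border %in% 0:1))
  expect_true(all(a$d_planted >= 0))
  expect_true(all(st$recruitment$n_recruited >= 0))
  p <- st$patients
  expect_true(all(p$age >= 0))
  expect_true(all(p$imd_income_quintile %in% 1:5))
  expect_true(all(p$sex %in% c("M", "F")))
  n_rec <- table(st$org_records$patient_id)
  expect_true(all(n_rec >= 1 & n_rec <= 3))
  bb <- small_study()$cfg$bbox
  expect_true(all(a$lon >= bb["lon_min"] & a$lon <= bb["lon_max"]))
  expect_true(all(a$lat >= bb["lat_min"] & a$lat <= bb["lat_max"]))
})

test_that("all-rural geographies sit farther from facilities than all-urban", {
  c_r <- synth_config(n_areas = 400, n_facilities = 10, seed = 42, p_rural = 1 - 1e-9)
  c_u <- synth_config(n_areas = 400, n_facilities = 10, seed = 42, p_rural = 1e-9)
  m_rural <- mean(nearest_facility(generate_geography(c_r)$areas,
                                   generate_geography(c_r)$facilities)$km)
  m_urban <- mean(nearest_facility(generate_geography(c_u)$areas,
                                   generate_geography(c_u)$facilities)$km)
  expect_gt(m_rural, m_urban)
})

test_that("recruitment is conserved and confined to the planted active set", {
  s <- small_study()
  rec <- s$st$recruitment
  by_fac <- tapply(rec$n_recruited, rec$facility_id, sum)
  expect_equal(sum(by_fac), sum(rec$n_recruited))          # marginal conservation
  expect_setequal(names(by_fac), s$st$truth$active_ids)    # nobody else recruits
  expect_true(all(by_fac >= 1))                            # active facilities recruit
  expect_true(all(rec$year %in% s$cfg$years))
})

test_that("large frailty shape makes facility recruitment rates homogeneous", {
  cfg_skew <- synth_config(n_areas = 50, n_facilities = 20, n_trials = 15,
                           seed = 13, recruit_shape = 0.3)
  cfg_flat <- synth_config(n_areas = 50, n_facilities = 20, n_trials = 15,
                           seed = 13, recruit_shape = 1e6)
  rate <- function(cfg) {
    g <- generate_geography(cfg)
    rec <- generate_recruitment(cfg, g$facilities)
    tapply(rec$n_recruited, rec$facility_id, sum) /
      tapply(rec$n_recruited, rec$facility_id, length)
  }
  r_skew <- rate(cfg_skew); r_flat <- rate(cfg_flat)
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(r_flat), cv(r_skew))
  # with the frailty degenerate, per-row rates hover around the base rate 2
  expect_true(all(abs(r_flat - 2) < 1))
})

test_that("patient ages follow the configured subtype distribution", {
  cfg <- synth_config(n_areas = 200, n_facilities = 8, n_patients = 10000, seed = 77)
  g <- generate_geography(cfg)
  p <- suppressMessages(generate_patients(cfg, g$areas, g$facilities))$patients
  d <- p[p$subtype == "DLBCL", ]
  # CLT bound: empirical mean within 3 SE of the configured mean 69 (SD 14)
  expect_lt(abs(mean(d$age) - 69), 3 * 14 / sqrt(nrow(d)))
})

test_that("trial summaries mix reporting styles and exclude tiny trials", {
  s <- small_study()
  ts <- s$st$trial_summaries
  by_mean <- !is.na(ts$age_mean) & !is.na(ts$age_sd)
  by_iqr <- !is.na(ts$age_median) & !is.na(ts$age_q1) & !is.na(ts$age_q3)
  expect_true(all(xor(by_mean, by_iqr)))
  expect_true(any(by_mean) && any(by_iqr))
  expect_true(all(ts$n_male >= 0 & ts$n_male <= ts$n))
  expect_true(all(ts$age_q1[by_iqr] <= ts$age_median[by_iqr] &
                    ts$age_median[by_iqr] <= ts$age_q3[by_iqr]))
  # enrolment near zero: trials with < 2 enrolees are excluded with a message
  tiny <- synth_config(n_areas = 50, n_facilities = 4, n_patients = 100,
                       n_trials = 10, seed = 3, enrol_mean = 0.5)
  gt <- generate_geography(tiny)
  pt <- suppressMessages(generate_patients(tiny, gt$areas, gt$facilities))$patients
  expect_message(ts2 <- generate_trial_summaries(tiny, pt), "excluded")
  expect_true(is.null(ts2) || all(ts2$n >= 2))
})

test_that("zero planted shifts keep the representativeness test at nominal level", {
  base <- synth_config(n_areas = 200, n_facilities = 8, n_patients = 4000,
                       seed = 500, repr_age_shift = 0, repr_male_shift = 0)
  geo <- generate_geography(base)
  trials <- generate_trials(base)
  pop <- suppressMessages(generate_patients(base, geo$areas, geo$facilities))$patients
  rej <- logical(300)
  for (r in seq_len(300)) {
    cfg <- synth_config(n_areas = 200, n_facilities = 8, n_patients = 4000,
                        seed = 10000 + r, repr_age_shift = 0, repr_male_shift = 0)
    ts <- suppressMessages(generate_trial_summaries(cfg, pop, trials))
    rep_ <- representativeness_report(ts, pop, "all")
    rej[r] <- rep_$age_p[rep_$subtype == "DLBCL"] < 0.05
  }
  # close to the nominal 5% (slightly conservative: the median/IQR conversion
  # adds variance the pooled SE does not model)
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.09)
})

test_that("planted representativeness gaps are recovered with high power", {
  base <- synth_config(n_areas = 200, n_facilities = 8, n_patients = 4000,
                       seed = 500, repr_age_shift = 0, repr_male_shift = 0)
  geo <- generate_geography(base)
  trials <- generate_trials(base)
  pop <- suppressMessages(generate_patients(base, geo$areas, geo$facilities))$patients

  # 10-year age gap: detected essentially always, estimate within 1 year
  hit <- logical(100); diffs <- numeric(100)
  for (r in seq_len(100)) {
    cfg <- synth_config(n_areas = 200, n_facilities = 8, n_patients = 4000,
                        seed = 20000 + r, repr_age_shift = 10)
    ts <- suppressMessages(generate_trial_summaries(cfg, pop, trials))
    rep_ <- representativeness_report(ts, pop, "all")
    i <- rep_$subtype == "DLBCL"
    hit[r] <- rep_$age_p[i] < 0.05
    diffs[r] <- rep_$age_diff[i]
  }
  expect_gt(mean(hit), 0.9)
  expect_lt(abs(mean(diffs) + 10), 1)

  # +5pp male share with large enrolment: positive and significant > 95%
  hit_m <- logical(100)
  for (r in seq_len(100)) {
    cfg <- synth_config(n_areas = 200, n_facilities = 8, n_patients = 4000,
                        seed = 30000 + r, repr_age_shift = 0,
                        repr_male_shift = 5, enrol_mean = 300)
    ts <- suppressMessages(generate_trial_summaries(cfg, pop, trials))
    rep_ <- representativeness_report(ts, pop, "all")
    i <- rep_$subtype == "DLBCL"
    hit_m[r] <- rep_$male_p[i] < 0.05 && rep_$male_diff_pp[i] > 0
  }
  expect_gt(mean(hit_m), 0.95)
})

test_that("the study round-trips through its CSV schemas", {
  cfg <- synth_config(n_areas = 60, n_facilities = 4, n_patients = 150,
                      n_trials = 6, seed = 9)
  st <- suppressMessages(synth_study(cfg))
  dir <- file.path(tempdir(), "trialaccess-synth-csv")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  paths <- write_synth_csv(st, dir)
  expect_true(all(file.exists(paths)))
  a2 <- read_geo_csv(file.path(dir, "areas.csv"))
  expect_equal(a2$lon, st$areas$lon, tolerance = 1e-12)
  expect_identical(a2$area_id, st$areas$area_id)
  r2 <- utils::read.csv(file.path(dir, "recruitment.csv"))
  expect_equal(sum(r2$n_recruited), sum(st$recruitment$n_recruited))
})
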