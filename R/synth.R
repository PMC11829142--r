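# Synthetic study generator. Every downstream stage of the pipeline is tested
# against data generated here with known (planted) parameters: a linear
# distance-sociodemographics model, an exclusively-recruiting active facility
# subset, a skewed recruitment distribution, and planted age/sex gaps between
# trial enrolees and the incident population.

.subtypes <- c("DLBCL", "HL", "FL", "MCL", "PTCL")
.subtype_prob <- c(DLBCL = 0.45, HL = 0.15, FL = 0.21, MCL = 0.10, PTCL = 0.09)
# diagnosis-age normal parameters and male proportion per subtype
.subtype_age_mean <- c(DLBCL = 69, HL = 47, FL = 65, MCL = 72, PTCL = 66)
.subtype_age_sd   <- c(DLBCL = 14, HL = 20, FL = 13, MCL = 11, PTCL = 14)
.subtype_p_male   <- c(DLBCL = 0.552, HL = 0.558, FL = 0.483, MCL = 0.70, PTCL = 0.60)

#' Configuration for the synthetic study generator
#'
#' Bundles every ground-truth parameter of the synthetic study: geography and
#' facility counts, the planted ecological coefficients linking area
#' sociodemographics to distance, the research-active facility fraction, the
#' skewness of recruitment across facilities, and the planted enrolee-vs-
#' population age and sex gaps.
#'
#' @param n_areas Number of small areas (default 1000).
#' @param n_facilities Number of care-providing facilities (default 40).
#' @param bbox Named numeric `c(lon_min, lon_max, lat_min, lat_max)` in
#'   decimal degrees; defaults to an England-sized rectangle.
#' @param seed Integer master seed; each generated table draws from its own
#'   deterministic substream of this seed, so tables can be regenerated
#'   independently and an identical seed yields bit-identical tables.
#' @param beta Named vector of true ecological coefficients (km per unit) for
#'   `mean_age`, `pct_male`, `pct_ethnic_majority`, `imd_decile`, `rural`,
#'   `coastal_border`. Defaults plant a positive age and rural effect and a
#'   negative deprivation-decile effect.
#' @param alpha Intercept (km) of the planted linear distance model.
#' @param noise_sd Residual SD (km) of the planted distance model.
#' @param frac_active Fraction of facilities planted as research active,
#'   in (0, 1).
#' @param recruit_shape Shape of the per-facility gamma frailty on recruitment
#'   counts; small values give a highly skewed distribution across
#'   facilities, `Inf`-like large values make facilities near-exchangeable.
#' @param repr_age_shift Years by which trial enrolees are younger than the
#'   incident population of the same subtype (planted gap, default 10).
#' @param repr_male_shift Percentage points by which the enrolee male
#'   proportion exceeds the population proportion (default 3).
#' @param years Inclusive year range for diagnoses and recruitment.
#' @param n_trials,n_patients Sizes of the trial and patient registry tables.
#' @param enrol_mean Mean number of enrolees per trial (Poisson).
#' @param p_rural,p_coastal Bernoulli probabilities of the area rural and
#'   coastal/border flags.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_areas = 1000, n_facilities = 40,
                         bbox = c(lon_min = -5.5, lon_max = 1.5,
                                  lat_min = 50.0, lat_max = 55.5),
                         seed = 1L,
                         beta = c(mean_age = 0.400, pct_male = 0.386,
                                  pct_ethnic_majority = 0.123,
                                  imd_decile = -0.216, rural = 8.003,
                                  coastal_border = 2.750),
                         alpha = -22.189,
                         noise_sd = 5, frac_active = 0.5, recruit_shape = 1.5,
                         repr_age_shift = 10, repr_male_shift = 3,
                         years = 2014:2021,
                         n_trials = 20, n_patients = 5000, enrol_mean = 60,
                         p_rural = 0.2, p_coastal = 0.25) {
  cfg <- list(n_areas = as.integer(n_areas), n_facilities = as.integer(n_facilities),
              bbox = bbox, seed = as.integer(seed), beta = beta, alpha = alpha,
              noise_sd = noise_sd, frac_active = frac_active,
              recruit_shape = recruit_shape, repr_age_shift = repr_age_shift,
              repr_male_shift = repr_male_shift, years = as.integer(years),
              n_trials = as.integer(n_trials), n_patients = as.integer(n_patients),
              enrol_mean = enrol_mean, p_rural = p_rural, p_coastal = p_coastal)
  if (cfg$n_facilities < 2 || cfg$n_areas < cfg$n_facilities)
    stop("need n_areas >= n_facilities >= 2")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$frac_active <= 0 || cfg$frac_active >= 1)
    stop("frac_active must be in (0, 1)")
  if (cfg$recruit_shape <= 0) stop("recruit_shape must be > 0")
  if (diff(cfg$bbox[c("lon_min", "lon_max")]) <= 0 ||
      diff(cfg$bbox[c("lat_min", "lat_max")]) <= 0)
    stop("degenerate bbox: zero width or height")
  req <- c("mean_age", "pct_male", "pct_ethnic_majority", "imd_decile",
           "rural", "coastal_border")
  if (!all(req %in% names(cfg$beta))) stop("beta must name all six regressors")
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synthetic study configuration\n")
  cat(sprintf("  %d areas, %d facilities (%.0f%% active), %d trials, %d patients\n",
              x$n_areas, x$n_facilities, 100 * x$frac_active, x$n_trials, x$n_patients))
  cat(sprintf("  years %d-%d, seed %d\n", min(x$years), max(x$years), x$seed))
  cat("  planted beta (km/unit):\n")
  print(round(x$beta, 3))
  invisible(x)
}

# Deterministic per-table substream: every generator seeds its own stream from
# the master seed and a fixed table index, so tables regenerate independently.
.seed_stream <- function(cfg, k) {
  s <- (abs(as.numeric(cfg$seed)) * 7919 + k * 104729) %% 2147483647
  set.seed(as.integer(s))
}

# inverse-CDF truncated normal
.rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stats::qnorm(stats::runif(n, stats::pnorm(lower, mean, sd),
                            stats::pnorm(upper, mean, sd)), mean, sd)
}

#' Generate a synthetic geography of areas and facilities
#'
#' Facilities are placed in a small number of urban cluster centres; urban
#' areas scatter tightly around those same centres while rural areas are
#' uniform over the bounding box, so rurality carries a true positive
#' nearest-facility distance effect by construction. Each area additionally
#' gets a planted linear distance `d_planted = alpha + X beta + noise`, the
#' ground truth against which the ecological regression is tested.
#'
#' @param cfg A [synth_config()].
#' @return List with `areas` (area_id, lon, lat, population, mean_age,
#'   pct_male, pct_ethnic_majority, imd_decile, rural, coastal_border,
#'   d_planted) and `facilities` (facility_id, lon, lat, provides_care).
#' @export
generate_geography <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  .seed_stream(cfg, 1L)
  bb <- cfg$bbox
  w <- bb[["lon_max"]] - bb[["lon_min"]]; h <- bb[["lat_max"]] - bb[["lat_min"]]

  n_clust <- max(2L, ceiling(cfg$n_facilities / 4))
  cl_lon <- stats::runif(n_clust, bb[["lon_min"]] + 0.1 * w, bb[["lon_max"]] - 0.1 * w)
  cl_lat <- stats::runif(n_clust, bb[["lat_min"]] + 0.1 * h, bb[["lat_max"]] - 0.1 * h)

  fcl <- sample.int(n_clust, cfg$n_facilities, replace = TRUE)
  facilities <- data.frame(
    facility_id = sprintf("F%03d", seq_len(cfg$n_facilities)),
    lon = stats::rnorm(cfg$n_facilities, cl_lon[fcl], 0.05),
    lat = stats::rnorm(cfg$n_facilities, cl_lat[fcl], 0.05),
    provides_care = TRUE,
    stringsAsFactors = FALSE
  )

  n <- cfg$n_areas
  rural <- stats::rbinom(n, 1, cfg$p_rural)
  coastal <- stats::rbinom(n, 1, cfg$p_coastal)
  acl <- sample.int(n_clust, n, replace = TRUE)
  lon <- ifelse(rural == 1, stats::runif(n, bb[["lon_min"]], bb[["lon_max"]]),
                stats::rnorm(n, cl_lon[acl], 0.15))
  lat <- ifelse(rural == 1, stats::runif(n, bb[["lat_min"]], bb[["lat_max"]]),
                stats::rnorm(n, cl_lat[acl], 0.15))
  lon <- pmin(pmax(lon, bb[["lon_min"]]), bb[["lon_max"]])
  lat <- pmin(pmax(lat, bb[["lat_min"]]), bb[["lat_max"]])

  areas <- data.frame(
    area_id = sprintf("A%05d", seq_len(n)),
    lon = lon, lat = lat,
    population = sample(1000:3000, n, replace = TRUE),
    mean_age = .rtnorm(n, 41, 4, 25, 60),
    pct_male = pmin(100, pmax(0, stats::rnorm(n, 49.5, 1.5))),
    pct_ethnic_majority = pmin(100, pmax(0, stats::rnorm(n, 85, 12))),
    imd_decile = sample.int(10, n, replace = TRUE),
    rural = rural, coastal_border = coastal,
    stringsAsFactors = FALSE
  )
  X <- as.matrix(areas[, names(cfg$beta)])
  areas$d_planted <- pmax(0, cfg$alpha + drop(X %*% cfg$beta) +
                               stats::rnorm(n, 0, cfg$noise_sd))
  list(areas = areas, facilities = facilities)
}

#' Generate a synthetic trial table
#'
#' @param cfg A [synth_config()].
#' @return Data frame: trial_id, subtype, first_line, phase, age_restricted,
#'   open_year, close_year. The first three trials are forced to DLBCL, HL
#'   and FL so the subtype-specific activity definitions are always
#'   exercised.
#' @export
generate_trials <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  .seed_stream(cfg, 2L)
  n <- cfg$n_trials
  subtype <- sample(.subtypes, n, replace = TRUE,
                    prob = c(0.35, 0.20, 0.20, 0.15, 0.10))
  subtype[seq_len(min(3, n))] <- c("DLBCL", "HL", "FL")[seq_len(min(3, n))]
  open <- sample(cfg$years[-length(cfg$years)], n, replace = TRUE)
  data.frame(
    trial_id = sprintf("T%03d", seq_len(n)),
    subtype = subtype,
    first_line = stats::rbinom(n, 1, 0.5) == 1,
    phase = sample(c("II", "III"), n, replace = TRUE, prob = c(0.55, 0.45)),
    age_restricted = stats::rbinom(n, 1, 0.3) == 1,
    open_year = open,
    close_year = pmin(open + sample(1:3, n, replace = TRUE), max(cfg$years)),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic annual recruitment
#'
#' A planted subset of `frac_active * n_facilities` facilities carries all
#' recruitment; every other facility joins no trial and recruits nobody, so
#' the activity classification has exact ground truth. Counts per
#' (trial, facility, year) are Poisson with a shared per-facility gamma
#' frailty of shape `recruit_shape` (a negative-binomial mixture), giving a
#' right-skewed recruitment distribution across facilities. Zero-count rows
#' are retained: presence of a row records trial participation even without
#' recruits. Every planted-active facility is guaranteed at least one
#' recruit in total.
#'
#' @param cfg A [synth_config()].
#' @param facilities Facility table from [generate_geography()].
#' @param trials Optional trial table; generated from `cfg` if missing.
#' @return Data frame (trial_id, facility_id, year, n_recruited) with
#'   attributes `active_ids` (the planted active set) and `participation`
#'   (facility_id x subtype truth table).
#' @export
generate_recruitment <- function(cfg, facilities, trials = NULL) {
  stopifnot(inherits(cfg, "synth_config"), nrow(facilities) > 0)
  if (is.null(trials)) trials <- generate_trials(cfg)
  .seed_stream(cfg, 3L)
  n_fac <- nrow(facilities)
  k <- max(1L, round(cfg$frac_active * n_fac))
  active_ids <- sort(sample(facilities$facility_id, k))

  frailty <- stats::rgamma(k, shape = cfg$recruit_shape, rate = cfg$recruit_shape)
  names(frailty) <- active_ids

  rows <- list()
  for (fid in active_ids) {
    joins <- stats::rbinom(nrow(trials), 1, 0.4) == 1
    if (!any(joins)) joins[sample.int(nrow(trials), 1)] <- TRUE
    for (ti in which(joins)) {
      yrs <- trials$open_year[ti]:trials$close_year[ti]
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = trials$trial_id[ti], facility_id = fid, year = yrs,
        n_recruited = stats::rpois(length(yrs), 2 * frailty[[fid]]),
        stringsAsFactors = FALSE
      )
    }
  }
  rec <- do.call(rbind, rows)
  # guarantee positive total recruitment for every planted-active facility
  tot <- tapply(rec$n_recruited, rec$facility_id, sum)
  for (fid in names(tot)[tot == 0]) {
    i <- which(rec$facility_id == fid)[1]
    rec$n_recruited[i] <- 1L
  }
  rownames(rec) <- NULL
  part <- unique(merge(rec[, c("trial_id", "facility_id")],
                       trials[, c("trial_id", "subtype")], by = "trial_id")
                 [, c("facility_id", "subtype")])
  part <- part[order(part$facility_id, part$subtype), ]
  rownames(part) <- NULL
  attr(rec, "active_ids") <- active_ids
  attr(rec, "participation") <- part
  rec
}

#' Generate a synthetic patient registry
#'
#' Patients get a subtype (with subtype-specific age and sex distributions),
#' a home area drawn proportional to area population (inheriting the area's
#' ethnicity mix and deprivation), a diagnosis year, and 1-3 candidate
#' organisational records pointing at facilities, ordered by a known source
#' priority so the assignment cascade has exact ground truth. The true
#' facility of care is the facility nearest the home area; fallback records
#' occasionally point elsewhere so the cascade order matters.
#'
#' @param cfg A [synth_config()].
#' @param areas,facilities Tables from [generate_geography()].
#' @return List with `patients` (patient_id, subtype, diagnosis_year, age,
#'   sex, ethnic_majority, imd_income_quintile, area_id, facility_id_truth)
#'   and `org_records` (patient_id, source_tag, facility_id) in priority
#'   order within patient.
#' @export
generate_patients <- function(cfg, areas, facilities) {
  stopifnot(inherits(cfg, "synth_config"), nrow(areas) > 0, nrow(facilities) > 0)
  .seed_stream(cfg, 4L)
  n <- cfg$n_patients
  subtype <- sample(.subtypes, n, replace = TRUE, prob = .subtype_prob)
  age <- .rtnorm(n, .subtype_age_mean[subtype], .subtype_age_sd[subtype], lower = 0)
  sex <- ifelse(stats::runif(n) < .subtype_p_male[subtype], "M", "F")
  ai <- sample.int(nrow(areas), n, replace = TRUE, prob = areas$population)

  nearest <- nearest_facility(areas, facilities)
  true_fac <- nearest$facility_id[ai]
  other_fac <- function(fid) {
    pool <- setdiff(facilities$facility_id, fid)
    pool[sample.int(length(pool), 1)]
  }

  cascade <- c("decision_to_treat", "treatment_record", "diagnosis_record")
  has <- cbind(stats::runif(n) < 0.90, stats::runif(n) < 0.60, stats::runif(n) < 0.40)
  none <- rowSums(has) == 0
  has[none, 3] <- TRUE
  stray <- stats::runif(n) < 0.10  # fallback records sometimes disagree

  recs <- vector("list", n)
  for (i in seq_len(n)) {
    tags <- cascade[has[i, ]]
    fac <- rep(true_fac[i], length(tags))
    if (stray[i] && length(tags) > 0 && tags[1] != "decision_to_treat")
      fac[length(fac)] <- other_fac(true_fac[i])
    recs[[i]] <- data.frame(patient_id = sprintf("P%06d", i), source_tag = tags,
                            facility_id = fac, stringsAsFactors = FALSE)
  }
  org <- do.call(rbind, recs)
  rownames(org) <- NULL
  truth <- vapply(recs, function(r) r$facility_id[1], character(1))

  patients <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    subtype = subtype,
    diagnosis_year = sample(cfg$years, n, replace = TRUE),
    age = age, sex = sex,
    ethnic_majority = stats::runif(n) < areas$pct_ethnic_majority[ai] / 100,
    imd_income_quintile = ceiling(areas$imd_decile[ai] / 2),
    area_id = areas$area_id[ai],
    facility_id_truth = truth,
    stringsAsFactors = FALSE
  )
  list(patients = patients, org_records = org)
}

#' Generate published per-trial summary statistics
#'
#' For each trial, simulated enrolees are drawn from the subtype age
#' distribution shifted younger by `repr_age_shift` years, with the male
#' proportion raised by `repr_male_shift` percentage points. Half the trials
#' report the enrolee mean/SD, the other half report median and quartiles
#' computed from the same simulated enrolees, so the median/IQR-to-mean/SD
#' conversion path is exercised. Trials drawing fewer than 2 enrolees are
#' excluded with a message.
#'
#' @param cfg A [synth_config()].
#' @param patients Unused except to assert the registry is nonempty (the
#'   enrolee model is the subtype population model, not a resample).
#' @param trials Optional trial table; generated from `cfg` if missing.
#' @return Data frame: trial_id, subtype, n, age_mean, age_sd, age_median,
#'   age_q1, age_q3, n_male, first_line, age_restricted, phase. Exactly one
#'   of (age_mean, age_sd) / (age_median, age_q1, age_q3) is non-NA per row.
#' @export
generate_trial_summaries <- function(cfg, patients, trials = NULL) {
  stopifnot(inherits(cfg, "synth_config"), nrow(patients) > 0)
  if (is.null(trials)) trials <- generate_trials(cfg)
  .seed_stream(cfg, 5L)
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    s <- trials$subtype[i]
    n_enr <- stats::rpois(1, cfg$enrol_mean)
    if (n_enr < 2) {
      message(sprintf("trial %s excluded: %d enrolee(s)", trials$trial_id[i], n_enr))
      next
    }
    ages <- .rtnorm(n_enr, .subtype_age_mean[[s]] - cfg$repr_age_shift,
                    .subtype_age_sd[[s]], lower = 0)
    p_male <- min(1, max(0, .subtype_p_male[[s]] + cfg$repr_male_shift / 100))
    n_male <- stats::rbinom(1, n_enr, p_male)
    row <- data.frame(
      trial_id = trials$trial_id[i], subtype = s, n = n_enr,
      age_mean = NA_real_, age_sd = NA_real_,
      age_median = NA_real_, age_q1 = NA_real_, age_q3 = NA_real_,
      n_male = n_male,
      first_line = trials$first_line[i],
      age_restricted = trials$age_restricted[i],
      phase = trials$phase[i],
      stringsAsFactors = FALSE
    )
    if (i %% 2 == 1) {
      row$age_mean <- mean(ages); row$age_sd <- stats::sd(ages)
    } else {
      q <- stats::quantile(ages, c(0.25, 0.5, 0.75), names = FALSE)
      row$age_q1 <- q[1]; row$age_median <- q[2]; row$age_q3 <- q[3]
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a complete synthetic study
#'
#' Runs all generators with a shared configuration and returns every table
#' plus the planted ground truth.
#'
#' @param cfg A [synth_config()].
#' @return List: `areas`, `facilities`, `trials`, `recruitment`, `patients`,
#'   `org_records`, `trial_summaries`, and `truth` (list with `active_ids`,
#'   `participation`, `beta`, `alpha`, `repr_age_shift`, `repr_male_shift`).
#' @export
synth_study <- function(cfg = synth_config()) {
  geo <- generate_geography(cfg)
  trials <- generate_trials(cfg)
  rec <- generate_recruitment(cfg, geo$facilities, trials)
  pat <- generate_patients(cfg, geo$areas, geo$facilities)
  ts <- generate_trial_summaries(cfg, pat$patients, trials)
  list(areas = geo$areas, facilities = geo$facilities, trials = trials,
       recruitment = rec, patients = pat$patients, org_records = pat$org_records,
       trial_summaries = ts,
       truth = list(active_ids = attr(rec, "active_ids"),
                    participation = attr(rec, "participation"),
                    beta = cfg$beta, alpha = cfg$alpha,
                    repr_age_shift = cfg$repr_age_shift,
                    repr_male_shift = cfg$repr_male_shift))
}

#' Write a synthetic study to CSV files
#'
#' One UTF-8 CSV per table (areas, facilities, trials, recruitment, patients,
#' org_records, trial_summaries), with a single header row; coordinates are
#' WGS84 decimal degrees.
#'
#' @param study Result of [synth_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_synth_csv <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("areas", "facilities", "trials", "recruitment", "patients",
            "org_records", "trial_summaries")
  paths <- file.path(dir, paste0(tabs, ".csv"))
  for (i in seq_along(tabs))
    utils::write.csv(study[[tabs[i]]], paths[i], row.names = FALSE)
  invisible(paths)
}
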