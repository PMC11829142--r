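# Facility-of-care assignment, per-facility incident populations, and the
# comparison of patient characteristics between research-active and
# research-inactive providers.

#' Assign each patient a facility of care through a source cascade
#'
#' Each patient may carry several candidate organisational records
#' (source_tag, facility_id). The record whose source tag appears earliest in
#' `cascade` wins; patients with no record matching any cascade tag are
#' unassigned (`NA`), counted and reported with a message — unassigned is a
#' value, not an error. The result does not depend on row order of
#' `org_records`beyond the within-patient priority resolved by the cascade.
#'
#' @param org_records Data frame (patient_id, source_tag, facility_id).
#' @param cascade Character vector of source tags in priority order. The
#'   default mirrors a decision-to-treat record taking precedence over
#'   inferred treatment and diagnosis records.
#' @param patient_ids Optional vector of all patient ids, so patients with no
#'   records at all appear as unassigned.
#' @return Data frame (patient_id, facility_id), facility_id `NA` when
#'   unassigned.
#' @export
assign_facility <- function(org_records,
                            cascade = c("decision_to_treat", "treatment_record",
                                        "diagnosis_record"),
                            patient_ids = NULL) {
  if (length(cascade) == 0) stop("cascade must be nonempty")
  r <- org_records
  r$.rank <- match(r$source_tag, cascade)
  r <- r[!is.na(r$.rank), , drop = FALSE]
  r <- r[order(r$patient_id, r$.rank), , drop = FALSE]
  r <- r[!duplicated(r$patient_id), , drop = FALSE]
  ids <- if (is.null(patient_ids)) unique(org_records$patient_id) else patient_ids
  out <- data.frame(patient_id = ids,
                    facility_id = r$facility_id[match(ids, r$patient_id)],
                    stringsAsFactors = FALSE)
  n_un <- sum(is.na(out$facility_id))
  if (n_un > 0)
    message(sprintf("%d patient(s) unassignable under the cascade", n_un))
  out
}

#' Mean annual incident patients per facility and subtype
#'
#' Counts assigned patients diagnosed within the year range and divides by
#' the number of years, per facility and subtype; an extra subtype `"all"`
#' row per facility aggregates across subtypes. Unassigned patients
#' (`facility_id` `NA`) are excluded with a message.
#'
#' @param patients Data frame with `facility_id`, `subtype`,
#'   `diagnosis_year` (e.g. the registry joined with [assign_facility()]).
#' @param years Integer vector of diagnosis years defining the window.
#' @return Data frame (facility_id, subtype, patient_count,
#'   mean_annual_incidence).
#' @export
mean_annual_incidence <- function(patients, years) {
  if (length(years) == 0) stop("year range must be nonempty")
  un <- is.na(patients$facility_id)
  if (any(un)) {
    message(sprintf("%d unassigned patient(s) excluded from incidence", sum(un)))
    patients <- patients[!un, , drop = FALSE]
  }
  p <- patients[patients$diagnosis_year %in% years, , drop = FALSE]
  cnt <- stats::aggregate(list(patient_count = p$patient_id),
                          by = list(facility_id = p$facility_id, subtype = p$subtype),
                          FUN = length)
  tot <- stats::aggregate(list(patient_count = p$patient_id),
                          by = list(facility_id = p$facility_id), FUN = length)
  tot$subtype <- "all"
  out <- rbind(cnt[, c("facility_id", "subtype", "patient_count")],
               tot[, c("facility_id", "subtype", "patient_count")])
  out$mean_annual_incidence <- out$patient_count / length(years)
  out <- out[order(out$facility_id, out$subtype), ]
  rownames(out) <- NULL
  out
}

#' Share of the incident population treated in research-active facilities
#'
#' @param summary Result of [mean_annual_incidence()].
#' @param labels Data frame (facility_id, active) covering every facility in
#'   `summary`.
#' @param subtype Subtype to evaluate (`"all"` for the total population).
#' @return Named numeric `c(active = , inactive = )`, percentages summing
#'   to 100.
#' @export
active_share <- function(summary, labels, subtype = "all") {
  s <- summary[summary$subtype == subtype, , drop = FALSE]
  if (nrow(s) == 0) stop(sprintf("no incidence rows for subtype '%s'", subtype))
  miss <- setdiff(s$facility_id, labels$facility_id)
  if (length(miss) > 0)
    stop(sprintf("labels missing for %d facility(ies), e.g. %s",
                 length(miss), miss[1]))
  act <- labels$active[match(s$facility_id, labels$facility_id)]
  total <- sum(s$mean_annual_incidence)
  if (total == 0) stop("zero total incidence")
  a <- 100 * sum(s$mean_annual_incidence[act]) / total
  c(active = a, inactive = 100 - a)
}

#' Compare registry patient characteristics between active and inactive
#' facilities
#'
#' For one subtype, splits assigned patients by the research-activity label
#' of their facility of care and reports, per group: n, mean (SD) age,
#' % male, % ethnic-majority, and % in the two most deprived income
#' quintiles. P-values: Welch's t for age, Pearson chi-squared (no
#' continuity correction) for the binary proportions, and a Cochran-Armitage
#' trend test across the five income quintiles for deprivation.
#'
#' @param patients Registry with `facility_id` (assigned), `subtype`, `age`,
#'   `sex`, `ethnic_majority`, `imd_income_quintile`.
#' @param labels Data frame (facility_id, active).
#' @param subtype Subtype to compare.
#' @return Data frame with one row per characteristic and columns
#'   `characteristic`, `active`, `inactive`, `p_value`. If a group has fewer
#'   than 2 patients the age test is an error; proportions are still
#'   reported.
#' @export
compare_groups <- function(patients, labels, subtype) {
  p <- patients[patients$subtype == subtype & !is.na(patients$facility_id), , drop = FALSE]
  act <- labels$active[match(p$facility_id, labels$facility_id)]
  if (any(is.na(act))) stop("labels must cover all assigned facilities")
  g1 <- p[act, , drop = FALSE]; g0 <- p[!act, , drop = FALSE]
  if (nrow(g1) == 0 || nrow(g0) == 0) stop("both groups must be nonempty")

  fmt_mean_sd <- function(g) sprintf("%.1f (%.1f)", mean(g$age), stats::sd(g$age))
  pct <- function(x) 100 * mean(x)

  age_p <- if (nrow(g1) < 2 || nrow(g0) < 2)
    stop("a group has n < 2: age comparison undefined")
  else welch_t(mean(g1$age), stats::sd(g1$age), nrow(g1),
               mean(g0$age), stats::sd(g0$age), nrow(g0))$p.value

  tab2 <- function(x1, x0) {
    m <- rbind(c(sum(x1), sum(!x1)), c(sum(x0), sum(!x0)))
    chisq_2xk(m)$p.value
  }
  male_p <- tab2(g1$sex == "M", g0$sex == "M")
  eth_p <- tab2(as.logical(g1$ethnic_majority), as.logical(g0$ethnic_majority))
  q <- rbind(tabulate(g1$imd_income_quintile, nbins = 5),
             tabulate(g0$imd_income_quintile, nbins = 5))
  imd_p <- chisq_2xk(q, trend = TRUE)$p.value

  data.frame(
    characteristic = c("n", "age_mean_sd", "pct_male", "pct_ethnic_majority",
                       "pct_two_most_deprived_quintiles"),
    active = c(nrow(g1), fmt_mean_sd(g1), sprintf("%.1f", pct(g1$sex == "M")),
               sprintf("%.1f", pct(as.logical(g1$ethnic_majority))),
               sprintf("%.1f", pct(g1$imd_income_quintile <= 2))),
    inactive = c(nrow(g0), fmt_mean_sd(g0), sprintf("%.1f", pct(g0$sex == "M")),
                 sprintf("%.1f", pct(as.logical(g0$ethnic_majority))),
                 sprintf("%.1f", pct(g0$imd_income_quintile <= 2))),
    p_value = c(NA, age_p, male_p, eth_p, imd_p),
    stringsAsFactors = FALSE
  )
}
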