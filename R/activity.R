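# Research-activity classification of facilities. Five definitions:
# (1) incidence-weighted recruitment strictly above the median across all
#     facilities;
# (2) participation in at least one trial of any subtype;
# (3-5) participation in at least one DLBCL / HL / FL trial.
# Participation counts trials joined even with zero recruits.

#' Incidence-weighted recruitment ratio
#'
#' Total patients recruited by a facility divided by the mean annual number
#' of incident patients under its care. Facilities that recruit patients but
#' treat no incident patients are an error (the weighting is undefined);
#' facilities with neither recruitment nor incidence get ratio 0 with a
#' message.
#'
#' @param total_recruited Numeric vector of recruitment totals.
#' @param mean_annual_incidence Numeric vector of mean annual incident
#'   patients, same length.
#' @return Numeric vector of dimensionless ratios.
#' @examples
#' weighted_recruitment(36, 12)  # 3
#' @export
weighted_recruitment <- function(total_recruited, mean_annual_incidence) {
  stopifnot(length(total_recruited) == length(mean_annual_incidence))
  if (any(total_recruited < 0) || any(mean_annual_incidence < 0))
    stop("counts and incidence must be >= 0")
  bad <- mean_annual_incidence == 0 & total_recruited > 0
  if (any(bad))
    stop(sprintf("%d facility(ies) recruit patients but have zero incident patients; weighted recruitment undefined",
                 sum(bad)))
  zero <- mean_annual_incidence == 0
  if (any(zero))
    message(sprintf("%d facility(ies) with zero recruitment and zero incidence: ratio set to 0", sum(zero)))
  out <- numeric(length(total_recruited))
  out[!zero] <- total_recruited[!zero] / mean_annual_incidence[!zero]
  out
}

#' Assemble classification inputs from recruitment, trials and incidence
#'
#' Joins the recruitment table (optionally restricted to a year window) with
#' trial subtypes and per-facility incidence into the two inputs the
#' classifiers need: per-facility recruitment totals with incidence, and the
#' facility-by-subtype participation table. Facilities present in `incidence`
#' but absent from recruitment get total 0 and no participation. The
#' recruitment and incidence windows are deliberately independent (activity
#' may be judged on a longer recruitment window than the incidence window).
#'
#' @param recruitment Data frame (trial_id, facility_id, year, n_recruited).
#' @param trials Data frame (trial_id, subtype, ...).
#' @param incidence Data frame (facility_id, mean_annual_incidence), e.g. the
#'   subtype "all" rows of [mean_annual_incidence()].
#' @param recruit_years Optional integer vector restricting which recruitment
#'   years count towards the totals (participation is not restricted).
#' @param facility_map Optional two-column data frame (old_id, new_id)
#'   applied to recruitment facility ids before aggregation, for provider
#'   renamings and mergers.
#' @return List with `inputs` (facility_id, total_recruited,
#'   mean_annual_incidence) and `participation` (facility_id, subtype).
#' @export
activity_input <- function(recruitment, trials, incidence, recruit_years = NULL,
                           facility_map = NULL) {
  if (!is.null(facility_map)) {
    i <- match(recruitment$facility_id, facility_map[[1]])
    recruitment$facility_id[!is.na(i)] <- facility_map[[2]][i[!is.na(i)]]
  }
  rec <- recruitment
  if (!is.null(recruit_years)) rec <- rec[rec$year %in% recruit_years, , drop = FALSE]
  tot <- stats::aggregate(n_recruited ~ facility_id, data = rec, FUN = sum)
  inputs <- merge(incidence[, c("facility_id", "mean_annual_incidence")], tot,
                  by = "facility_id", all.x = TRUE)
  inputs$n_recruited[is.na(inputs$n_recruited)] <- 0
  names(inputs)[names(inputs) == "n_recruited"] <- "total_recruited"
  inputs <- inputs[order(inputs$facility_id),
                   c("facility_id", "total_recruited", "mean_annual_incidence")]
  rownames(inputs) <- NULL
  part <- unique(merge(recruitment[, c("trial_id", "facility_id")],
                       trials[, c("trial_id", "subtype")],
                       by = "trial_id")[, c("facility_id", "subtype")])
  part <- part[order(part$facility_id, part$subtype), ]
  rownames(part) <- NULL
  list(inputs = inputs, participation = part)
}

#' Definition 1: weighted recruitment strictly above the median
#'
#' Orders facilities by incidence-weighted recruitment and labels as research
#' active those strictly above the median ratio across all facilities. With
#' an odd number of all-distinct ratios the median facility itself is
#' inactive; with all ratios equal nobody is active.
#'
#' @param inputs Data frame (facility_id, total_recruited,
#'   mean_annual_incidence), as from [activity_input()].
#' @return Data frame (facility_id, weighted_recruitment, active).
#' @export
classify_def1 <- function(inputs) {
  if (nrow(inputs) < 2) stop("need at least 2 facilities")
  wr <- weighted_recruitment(inputs$total_recruited, inputs$mean_annual_incidence)
  data.frame(facility_id = inputs$facility_id,
             weighted_recruitment = wr,
             active = wr > stats::median(wr),
             stringsAsFactors = FALSE)
}

#' Definitions 2-5: trial participation, overall or by subtype
#'
#' A facility is research active if it joined at least one trial (subtype
#' `"any"`, definition 2) or at least one trial of the given subtype
#' (definitions 3-5: DLBCL, HL, FL). Participation counts trials joined even
#' with zero recruits.
#'
#' @param participation Data frame (facility_id, subtype), one row per
#'   facility-subtype participation, as from [activity_input()].
#' @param facility_ids Character vector of all facilities to label
#'   (participation only lists participants).
#' @param subtype `"any"` or a subtype label present in the data or among
#'   DLBCL/HL/FL; anything else is an error.
#' @return Data frame (facility_id, active).
#' @export
classify_participation <- function(participation, facility_ids, subtype = "any") {
  known <- union(c("any", "DLBCL", "HL", "FL"), unique(participation$subtype))
  if (!subtype %in% known)
    stop(sprintf("unknown subtype label '%s'", subtype))
  part <- if (identical(subtype, "any")) participation
          else participation[participation$subtype == subtype, , drop = FALSE]
  data.frame(facility_id = sort(unique(facility_ids)),
             active = sort(unique(facility_ids)) %in% part$facility_id,
             stringsAsFactors = FALSE)
}

#' Classify facilities as research active under one of five definitions
#'
#' @param definition Integer 1-5.
#' @param inputs,participation,facility_ids See [classify_def1()] and
#'   [classify_participation()].
#' @return Data frame with `facility_id`, `active` (and
#'   `weighted_recruitment` for definition 1).
#' @export
classify_activity <- function(definition, inputs = NULL, participation = NULL,
                              facility_ids = NULL) {
  definition <- as.integer(definition)
  if (definition == 1L) {
    if (is.null(inputs)) stop("definition 1 needs `inputs`")
    return(classify_def1(inputs))
  }
  if (!definition %in% 2:5) stop("definition must be in 1..5")
  if (is.null(participation) || is.null(facility_ids))
    stop("definitions 2-5 need `participation` and `facility_ids`")
  subtype <- c("any", "DLBCL", "HL", "FL")[definition - 1L]
  classify_participation(participation, facility_ids, subtype)
}
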