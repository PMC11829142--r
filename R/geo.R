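# Great-circle geometry: haversine distance, nearest-facility search and the
# excess-distance decomposition between care-providing and research-active
# facilities.

# IUGG mean Earth radius, km.
.R_EARTH_KM <- 6371.0088

#' Great-circle distance by the haversine formula
#'
#' Distance in kilometres between points given in WGS84 decimal degrees, on a
#' sphere of radius 6371.0088 km (the IUGG mean radius). Vectorised over all
#' four arguments with the usual recycling rules.
#'
#' @param lon1,lat1 Coordinates of the first point(s), decimal degrees.
#' @param lon2,lat2 Coordinates of the second point(s), decimal degrees.
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(-1.25, 51.75, -1.89, 52.48)
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  if (!all(is.finite(lon1), is.finite(lat1), is.finite(lon2), is.finite(lat2)))
    stop("haversine_km: coordinates must be finite")
  if (any(abs(lat1) > 90) || any(abs(lat2) > 90))
    stop("haversine_km: |latitude| must be <= 90")
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad; phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * .R_EARTH_KM * asin(pmin(1, sqrt(a)))
}

# n_areas x n_facilities distance matrix; columns in the order of `facilities`.
.distance_matrix <- function(areas, facilities) {
  n <- nrow(areas); m <- nrow(facilities)
  d <- matrix(NA_real_, n, m, dimnames = list(areas$area_id, facilities$facility_id))
  for (j in seq_len(m))
    d[, j] <- haversine_km(areas$lon, areas$lat, facilities$lon[j], facilities$lat[j])
  d
}

#' Nearest facility to each area centroid
#'
#' For each area, finds the facility minimising the haversine distance among
#' an eligible subset. Exact distance ties are broken towards the
#' lexicographically smallest `facility_id`, so results do not depend on row
#' order of the facility table.
#'
#' @param areas Data frame with columns `area_id`, `lon`, `lat`.
#' @param facilities Data frame with columns `facility_id`, `lon`, `lat`.
#' @param eligible Optional filter: either a character vector of facility ids
#'   or a predicate `function(facilities)` returning a logical vector. `NULL`
#'   keeps every facility.
#' @return Data frame with one row per area: `area_id`, `facility_id`, `km`.
#' @export
nearest_facility <- function(areas, facilities, eligible = NULL) {
  if (is.function(eligible)) {
    facilities <- facilities[eligible(facilities), , drop = FALSE]
  } else if (!is.null(eligible)) {
    facilities <- facilities[facilities$facility_id %in% eligible, , drop = FALSE]
  }
  if (nrow(facilities) == 0L) stop("no eligible facility")
  # sort by id so that "first minimum" is the lexicographic tie-break
  facilities <- facilities[order(facilities$facility_id), , drop = FALSE]
  d <- .distance_matrix(areas, facilities)
  j <- max.col(-d, ties.method = "first")
  data.frame(
    area_id = areas$area_id,
    facility_id = facilities$facility_id[j],
    km = d[cbind(seq_len(nrow(areas)), j)],
    stringsAsFactors = FALSE
  )
}

#' Per-area access to care-providing and research-active facilities
#'
#' Computes, for every area, the nearest care-providing facility, the nearest
#' research-active facility, and the excess distance a patient would incur
#' because their nearest care facility is not research active:
#' `excess = d_active - d_care` when the nearest care facility is inactive,
#' and 0 when it is active. Active facilities must be a subset of
#' care-providing ones.
#'
#' @param areas Area table (`area_id`, `lon`, `lat`, ...).
#' @param facilities Facility table (`facility_id`, `lon`, `lat`, optional
#'   logical `provides_care`; missing means all provide care).
#' @param active_ids Character vector of research-active facility ids.
#' @param provider Travel-time provider as returned by
#'   [travel_speed_provider()], or `NULL` to skip travel times.
#' @return Data frame with columns `area_id`, `nearest_care_id`, `d_care`,
#'   `nearest_active_id`, `d_active`, `nearest_care_active`, `excess` and
#'   (unless `provider` is `NULL`) `t_active` in minutes. Summarise with
#'   [access_summary()].
#' @seealso [access_summary()], [write_access_geojson()]
#' @export
access_table <- function(areas, facilities, active_ids,
                         provider = travel_speed_provider()) {
  if (!"provides_care" %in% names(facilities)) facilities$provides_care <- TRUE
  care <- facilities[facilities$provides_care, , drop = FALSE]
  if (nrow(care) == 0L) stop("no care-providing facility")
  if (length(active_ids) == 0L) stop("no eligible facility: active set is empty")
  active <- care[care$facility_id %in% active_ids, , drop = FALSE]
  if (nrow(active) == 0L) stop("no eligible facility: no active facility provides care")

  nc <- nearest_facility(areas, care)
  na_ <- nearest_facility(areas, active)
  inactive_nearest <- !(nc$facility_id %in% active$facility_id)
  out <- data.frame(
    area_id = areas$area_id,
    nearest_care_id = nc$facility_id,
    d_care = nc$km,
    nearest_active_id = na_$facility_id,
    d_active = na_$km,
    nearest_care_active = !inactive_nearest,
    excess = ifelse(inactive_nearest, na_$km - nc$km, 0),
    stringsAsFactors = FALSE
  )
  if (!is.null(provider)) {
    fi <- match(out$nearest_active_id, facilities$facility_id)
    out$t_active <- travel_time_min(provider, areas$lon, areas$lat,
                                    facilities$lon[fi], facilities$lat[fi])
  }
  out
}

#' Summary of an access table
#'
#' Median, quartiles and maximum of the distance (and, if present, travel
#' time) to the nearest research-active facility, plus the fraction of areas
#' whose nearest care-providing facility is not research active.
#'
#' @param access Result of [access_table()].
#' @return Named list: `d_active` and optionally `t_active` (each with
#'   `median`, `q1`, `q3`, `max`), and `frac_nearest_inactive`.
#' @export
access_summary <- function(access) {
  qs <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    list(median = q[2], q1 = q[1], q3 = q[3], max = max(x))
  }
  out <- list(d_active = qs(access$d_active),
              frac_nearest_inactive = mean(!access$nearest_care_active))
  if ("t_active" %in% names(access)) out$t_active <- qs(access$t_active)
  out
}

#' Constant-speed travel-time provider
#'
#' Returns a provider function mapping a coordinate pair to minutes of travel
#' assuming straight-line (haversine) travel at a constant speed. This is a
#' stand-in for road routing: outputs using it should be labelled as
#' straight-line estimates. External providers with the same signature
#' (`function(lon1, lat1, lon2, lat2) -> minutes`) can be plugged into
#' [access_table()] without changing callers.
#'
#' @param speed_kmh Assumed speed in km/h (default 50).
#' @export
travel_speed_provider <- function(speed_kmh = 50) {
  stopifnot(is.numeric(speed_kmh), speed_kmh > 0)
  function(lon1, lat1, lon2, lat2) {
    haversine_km(lon1, lat1, lon2, lat2) / speed_kmh * 60
  }
}

#' Travel time in minutes through a provider
#'
#' Thin wrapper that invokes a travel-time provider and rethrows any provider
#' failure with the offending coordinates attached.
#'
#' @param provider A function as returned by [travel_speed_provider()].
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @export
travel_time_min <- function(provider, lon1, lat1, lon2, lat2) {
  stopifnot(is.function(provider))
  tryCatch(provider(lon1, lat1, lon2, lat2), error = function(e) {
    stop(sprintf("travel-time provider failed for (%s,%s)->(%s,%s): %s",
                 lon1[1], lat1[1], lon2[1], lat2[1], conditionMessage(e)),
         call. = FALSE)
  })
}
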