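# Independent oracles and fixture builders used across the suite.

# Spherical law of cosines distance (independent of the haversine route),
# same IUGG mean radius.
slc_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  c0 <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371.0088 * acos(pmin(1, pmax(-1, c0)))
}

# Haversine written in a different algebraic form (atan2 variant), used as a
# second independent implementation for the brute-force nearest search.
hav_ref_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  a <- sin((lat2 - lat1) * r / 2)^2 +
    cos(lat1 * r) * cos(lat2 * r) * sin((lon2 - lon1) * r / 2)^2
  6371.0088 * 2 * atan2(sqrt(a), sqrt(1 - a))
}

# Exhaustive per-area argmin with lexicographic tie-break, via plain loops.
brute_nearest <- function(areas, facilities) {
  ord <- order(facilities$facility_id)
  f <- facilities[ord, , drop = FALSE]
  t(vapply(seq_len(nrow(areas)), function(i) {
    d <- hav_ref_km(areas$lon[i], areas$lat[i], f$lon, f$lat)
    j <- which.min(d)
    c(j = j, km = d[j])
  }, c(j = 0, km = 0)))
}

random_geo <- function(n_areas, n_facilities, seed) {
  set.seed(seed)
  list(
    areas = data.frame(area_id = sprintf("A%04d", seq_len(n_areas)),
                       lon = runif(n_areas, -6, 2), lat = runif(n_areas, 50, 56)),
    facilities = data.frame(facility_id = sprintf("F%03d", seq_len(n_facilities)),
                            lon = runif(n_facilities, -6, 2),
                            lat = runif(n_facilities, 50, 56))
  )
}

# 127 facilities: 80 with distinct positive weighted-recruitment ratios (unit
# incidence so the ratio equals the recruitment total), 47 with ratio zero.
fixture_127 <- function(seed = 1) {
  set.seed(seed)
  pos <- sample(seq(1, 400), 80) + runif(80, 0, 0.5)  # distinct positives
  data.frame(
    facility_id = sprintf("F%03d", 1:127),
    total_recruited = c(pos, rep(0, 47)),
    mean_annual_incidence = rep(1, 127),
    stringsAsFactors = FALSE
  )
}

# Small complete synthetic study shared by recovery tests.
small_study <- function(seed = 7) {
  cfg <- synth_config(n_areas = 300, n_facilities = 12, n_patients = 2000,
                      seed = seed)
  list(cfg = cfg, st = synth_study(cfg))
}
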