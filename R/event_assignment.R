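#' @title Assigning violent events to cities
#' @description Events are attributed to the nearest city centre when their
#'   great-circle distance to it is strictly below a threshold delta (in
#'   km); events at or beyond delta from every city are rural.  Per-city
#'   aggregates count events and sum fatalities, distinguishing all
#'   casualty-bearing categories (L) from violence against civilians
#'   alone (V).
#' @name event_assignment
NULL

.EARTH_RADIUS_KM <- 6371.0

#' Great-circle distance in km
#'
#' Haversine formula on a sphere of radius 6371 km.  Vectorised with
#' recycling.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (WGS84).
#' @return distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  .check_lonlat(lon1, lat1)
  .check_lonlat(lon2, lat2)
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * .EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Assignment parameters
#'
#' @param delta_km distance threshold in km (> 0); the analysis sweeps 1-30.
#' @param window_start,window_end inclusive date window (Date or ISO
#'   string); `NULL` disables the respective bound.
#' @param categories event categories retained before assignment; defaults
#'   to all six classes (category filtering of the casualty sums happens at
#'   aggregation).
#' @return list of class `assignment_params`.
#' @export
assignment_params <- function(delta_km = 10,
                              window_start = NULL, window_end = NULL,
                              categories = .EVENT_CATEGORIES) {
  if (!is.finite(delta_km) || delta_km <= 0)
    .stopf("delta_km must be > 0")
  if (!is.null(window_start)) window_start <- as.Date(window_start)
  if (!is.null(window_end)) window_end <- as.Date(window_end)
  if (!is.null(window_start) && !is.null(window_end) &&
      window_start > window_end)
    .stopf("window_start must be <= window_end")
  if (!all(categories %in% .EVENT_CATEGORIES))
    .stopf("unknown category in assignment params")
  structure(list(delta_km = delta_km, window_start = window_start,
                 window_end = window_end, categories = categories),
            class = "assignment_params")
}

.filter_events <- function(events, params) {
  keep <- events$category %in% params$categories
  if (!is.null(params$window_start))
    keep <- keep & events$date >= params$window_start
  if (!is.null(params$window_end))
    keep <- keep & events$date <= params$window_end
  events[keep, , drop = FALSE]
}

#' Assign events to their nearest city
#'
#' Each in-window, in-category event is mapped to the city whose centre is
#' nearest by great-circle distance; it is assigned if that distance is
#' strictly below `delta_km`, otherwise labelled `"RURAL"`.  Equidistant
#' nearest cities are broken in favour of the smallest `city_id`.
#'
#' @param events validated event table.
#' @param cities validated city table (nonempty).
#' @param params an [assignment_params()].
#' @return data.frame `event_id`, `assigned_city`, `distance_km` (distance
#'   to the nearest city, also for rural events), one row per retained
#'   event; carries the params as attribute `params`.
#' @export
assign_events <- function(events, cities, params = assignment_params()) {
  cities <- validate_cities(cities)
  events <- validate_events(events)
  if (!nrow(cities)) .stopf("assign_events: empty city table")
  events <- .filter_events(events, params)
  ord <- order(cities$city_id, method = "radix")  # tie rule: smallest id wins
  cid <- cities$city_id[ord]
  n <- nrow(events)
  nn <- .cpp_nearest_city(events$lon, events$lat,
                          cities$lon[ord], cities$lat[ord])
  dist_km <- nn$distance_km
  assigned <- ifelse(n > 0 & dist_km < params$delta_km, cid[nn$index], .RURAL)
  out <- data.frame(event_id = events$event_id,
                    assigned_city = if (n) assigned else character(0),
                    distance_km = dist_km,
                    stringsAsFactors = FALSE)
  attr(out, "params") <- params
  out
}

#' Aggregate per-city violence measures
#'
#' For every city (including those with no events) counts assigned events
#' and sums fatalities: `casualties_all` over `casualty_categories`
#' (default: battles, violence against civilians, explosions/remote
#' violence, strategic developments — the four casualty-bearing classes)
#' and `casualties_vac` over violence against civilians only.
#'
#' @param assignments output of [assign_events()] under the same `params`.
#' @param events the event table the assignments were computed from.
#' @param cities validated city table.
#' @param params the [assignment_params()] used; must match the ones the
#'   assignments carry.
#' @param casualty_categories categories entering `casualties_all`.
#' @return data.frame `city_id`, `population`, `n_events`,
#'   `casualties_all`, `casualties_vac`, `delta_km`, `window_start`,
#'   `window_end`.
#' @export
aggregate_city_violence <- function(assignments, events, cities,
                                    params = attr(assignments, "params"),
                                    casualty_categories =
                                      .CASUALTY_CATEGORIES) {
  cities <- validate_cities(cities)
  events <- validate_events(events)
  ap <- attr(assignments, "params")
  if (!is.null(ap) && !identical(unclass(ap), unclass(params)))
    .stopf("aggregate_city_violence: params do not match the assignments")
  if (is.null(params)) .stopf("aggregate_city_violence: params required")
  ev <- events[match(assignments$event_id, events$event_id), , drop = FALSE]
  if (anyNA(ev$event_id))
    .stopf("aggregate_city_violence: assignment references unknown event_id")
  urban <- assignments$assigned_city != .RURAL
  city_f <- factor(assignments$assigned_city[urban], levels = cities$city_id)
  if (anyNA(city_f))
    .stopf("aggregate_city_violence: assignment references unknown city_id")
  n_events <- as.integer(table(city_f))
  in_all <- ev$category[urban] %in% casualty_categories
  in_vac <- ev$category[urban] == "violence_against_civilians"
  sum_by <- function(x, keep) {
    v <- rep(0, nrow(cities))
    if (any(keep)) {
      s <- rowsum(x[keep], group = city_f[keep])
      v[match(rownames(s), cities$city_id)] <- s[, 1]
    }
    v
  }
  out <- data.frame(
    city_id = cities$city_id,
    population = cities$population,
    n_events = n_events,
    casualties_all = sum_by(ev$fatalities[urban], in_all),
    casualties_vac = sum_by(ev$fatalities[urban], in_vac),
    delta_km = params$delta_km,
    window_start = if (is.null(params$window_start)) as.Date(NA) else
      params$window_start,
    window_end = if (is.null(params$window_end)) as.Date(NA) else
      params$window_end,
    stringsAsFactors = FALSE)
  attr(out, "params") <- params
  attr(out, "casualty_categories") <- casualty_categories
  out
}

#' Urban share of events and casualties
#'
#' Fraction of the retained events — and of their fatalities — that were
#' assigned to some city (as opposed to rural).
#'
#' @param assignments output of [assign_events()].
#' @param events the matching event table.
#' @return list with `share_events` and `share_casualties`.
#' @export
urban_share <- function(assignments, events) {
  events <- validate_events(events)
  ev <- events[match(assignments$event_id, events$event_id), , drop = FALSE]
  if (!nrow(ev)) .stopf("urban_share: no events")
  urban <- assignments$assigned_city != .RURAL
  total_f <- sum(ev$fatalities)
  if (total_f <= 0) .stopf("urban_share: zero total fatalities")
  list(share_events = mean(urban),
       share_casualties = sum(ev$fatalities[urban]) / total_f)
}
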