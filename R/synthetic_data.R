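#' @title Synthetic city systems with planted effects
#' @description Generates city tables, sparse highway networks and event
#'   streams that reproduce the stylised facts the pipeline assumes: a
#'   heavily skewed city-size distribution, a sparse connected road graph in
#'   which most cities have degree <= 2, and a heavy-tailed casualty
#'   process.  The generator plants a known scaling exponent (expected
#'   casualties scale as alpha * P^beta) and a known lethality multiplier
#'   between high- and low-isolation cities, so the full downstream pipeline
#'   can be checked for recovery of ground truth.
#' @name synthetic_data
NULL

#' Synthetic-world configuration
#'
#' Defaults describe a continental system: 2000 cities in a 4000 km square
#' split into 12 countries, populations with a Zipf-like tail (floor
#' 10,000, tail index `zipf_exponent - 1`), a minimum-spanning-tree highway
#' network plus 25\% extra gravity-weighted short edges travelled at 80 km/h with 30\%
#' multiplicative time noise, and an event stream over the Jan 2000 - Oct
#' 2022 window averaging 2.5 fatalities per event (negative binomial with
#' moderate overdispersion, size 1; the extreme-concentration regime is
#' reached by choosing a small size such as 0.2) totalling about 560,000
#' expected urban casualties, with half of the events rural.
#'
#' @param n_cities number of cities (>= 10).
#' @param n_countries number of contiguous country blocks.
#' @param region_size_km side of the square region.
#' @param pop_min population floor.
#' @param pop_cap population cap (truncated tail); keeps the largest
#'   synthetic city at a realistic megacity scale.
#' @param zipf_exponent population tail exponent s (density ~ P^-s); 2
#'   mirrors the classic rank-size rule.
#' @param min_city_spacing_km hard-core minimum distance between city
#'   centres; distinct agglomerations are separated on the ground (closer
#'   built-up areas would be merged into one city), and spacing well above
#'   the event jitter keeps an event's nearest city its own.
#' @param extra_edge_fraction extra edges added to the spanning tree, as a
#'   fraction of `n_cities`; candidates are ranked by gravity-discounted
#'   length d / sqrt(P_i P_j), so added highways concentrate on large
#'   cities.
#' @param speed_kmh travel speed converting edge length to hours.
#' @param travel_time_noise_cv coefficient of variation of multiplicative
#'   lognormal travel-time noise (mean 1).
#' @param beta_true planted scaling exponent.
#' @param alpha_true planted prefactor; `NA` (default) calibrates it so the
#'   expected total urban casualties equal `target_casualties`.
#' @param target_casualties expected total urban casualties used to
#'   calibrate `alpha_true` when it is `NA`.
#' @param isolation_multiplier planted lethality ratio of high- vs
#'   low-isolation cities (>= 1); medium-isolation cities get the geometric
#'   midpoint.
#' @param mean_fatalities mean fatalities per event.
#' @param fatality_dispersion negative-binomial size parameter of per-event
#'   fatalities; small values concentrate casualties in few events.
#' @param event_jitter_km sd of the isotropic Gaussian jitter of event
#'   coordinates around the city centre.
#' @param rural_fraction fraction of all events placed > 50 km from every
#'   city, in [0, 1).
#' @param category_probs named probabilities over event categories;
#'   defaults to the four casualty-bearing classes at their continental
#'   proportions.
#' @param window_start,window_end event date window.
#' @param seed integer seed; every draw derives from it.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cities = 2000,
                             n_countries = 12,
                             region_size_km = 4000,
                             pop_min = 10000,
                             pop_cap = 2.5e7,
                             zipf_exponent = 2.0,
                             min_city_spacing_km = 15,
                             extra_edge_fraction = 0.25,
                             speed_kmh = 80,
                             travel_time_noise_cv = 0.3,
                             beta_true = 0.49,
                             alpha_true = NA_real_,
                             target_casualties = 560000,
                             isolation_multiplier = 1,
                             mean_fatalities = 2.5,
                             fatality_dispersion = 1,
                             event_jitter_km = 2,
                             rural_fraction = 0.5,
                             category_probs = c(
                               battle = 0.390,
                               violence_against_civilians = 0.387,
                               explosion_remote = 0.119,
                               strategic_development = 0.104),
                             window_start = "2000-01-01",
                             window_end = "2022-10-25",
                             seed = 1) {
  cfg <- list(n_cities = n_cities, n_countries = n_countries,
              region_size_km = region_size_km, pop_min = pop_min,
              pop_cap = pop_cap, zipf_exponent = zipf_exponent,
              min_city_spacing_km = min_city_spacing_km,
              extra_edge_fraction = extra_edge_fraction,
              speed_kmh = speed_kmh,
              travel_time_noise_cv = travel_time_noise_cv,
              beta_true = beta_true, alpha_true = alpha_true,
              target_casualties = target_casualties,
              isolation_multiplier = isolation_multiplier,
              mean_fatalities = mean_fatalities,
              fatality_dispersion = fatality_dispersion,
              event_jitter_km = event_jitter_km,
              rural_fraction = rural_fraction,
              category_probs = category_probs / sum(category_probs),
              window_start = as.Date(window_start),
              window_end = as.Date(window_end),
              seed = as.integer(seed))
  if (cfg$n_cities < 10) .stopf("n_cities must be >= 10")
  if (cfg$window_start >= cfg$window_end)
    .stopf("window_start must be before window_end")
  if (cfg$zipf_exponent <= 1) .stopf("zipf_exponent must be > 1")
  if (cfg$pop_cap <= cfg$pop_min) .stopf("pop_cap must exceed pop_min")
  if (cfg$min_city_spacing_km < 0) .stopf("min_city_spacing_km must be >= 0")
  if (cfg$extra_edge_fraction < 0 || cfg$extra_edge_fraction > 1)
    .stopf("extra_edge_fraction must be in [0, 1]")
  if (cfg$rural_fraction < 0 || cfg$rural_fraction >= 1)
    .stopf("rural_fraction must be in [0, 1)")
  if (cfg$isolation_multiplier < 1)
    .stopf("isolation_multiplier must be >= 1")
  if (!all(names(cfg$category_probs) %in% .EVENT_CATEGORIES))
    .stopf("unknown category in category_probs")
  if (cfg$speed_kmh <= 0 || cfg$region_size_km <= 0 ||
      cfg$travel_time_noise_cv < 0 || cfg$event_jitter_km < 0 ||
      cfg$fatality_dispersion <= 0 || cfg$mean_fatalities <= 0)
    .stopf("invalid synthetic_config numeric field")
  structure(cfg, class = "synthetic_config")
}

.KM_PER_DEG <- .EARTH_RADIUS_KM * pi / 180  # km per degree of latitude

# dart-throwing hard-core point process: uniform in the square, proposals
# closer than `spacing` to an accepted point are rejected
.hardcore_positions <- function(n, L, spacing) {
  x <- numeric(n); y <- numeric(n)
  k <- 0L
  attempts <- 0L
  while (k < n) {
    m <- max(64L, n - k)
    px <- runif(m, 0, L); py <- runif(m, 0, L)
    for (i in seq_len(m)) {
      if (k == 0L ||
          min((x[seq_len(k)] - px[i])^2 + (y[seq_len(k)] - py[i])^2) >=
            spacing^2) {
        k <- k + 1L
        x[k] <- px[i]; y[k] <- py[i]
        if (k == n) break
      }
    }
    attempts <- attempts + 1L
    if (attempts > 1000L)
      .stopf("generate_city_system: cannot place %d cities at %g km spacing in a %g km square",
             n, spacing, L)
  }
  list(x = x, y = y)
}

# planar km offsets around a reference point -> lon/lat
.km_to_lonlat <- function(x_km, y_km, lon0 = 10, lat0 = 0) {
  lat <- lat0 + y_km / .KM_PER_DEG
  lon <- lon0 + x_km / (.KM_PER_DEG * cos(lat * pi / 180))
  list(lon = lon, lat = lat)
}

#' Generate a synthetic city system and highway network
#'
#' Populations are drawn from a Pareto tail with floor `pop_min` and tail
#' index `zipf_exponent - 1` (floored to integers); positions are uniform
#' in the square region and projected to WGS84 around a reference point;
#' countries are the nearest of `n_countries` random seed points.  The
#' network is the great-circle minimum spanning tree over the cities plus
#' `extra_edge_fraction * n_cities` extra non-tree edges with the smallest
#' gravity-discounted length d / sqrt(P_i P_j); each edge's
#' travel time is its length over `speed_kmh` times lognormal noise with
#' mean 1 and CV `travel_time_noise_cv`.  The result is connected by
#' construction and fully reproducible from the seed.
#'
#' @param config a [synthetic_config()].
#' @return list: `cities` (validated city table), `network`
#'   ([urban_network()]), `truth` (partial planted-truth record echoing the
#'   config).
#' @export
generate_city_system <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_cities
  .with_seed(config$seed, {
    # truncated Pareto tail via inverse CDF
    sh <- config$zipf_exponent - 1
    trunc <- 1 - (config$pop_min / config$pop_cap)^sh
    pop <- floor(config$pop_min * (1 - runif(n) * trunc)^(-1 / sh))
    L <- config$region_size_km
    xy <- .hardcore_positions(n, L, config$min_city_spacing_km)
    x <- xy$x; y <- xy$y
    cx <- runif(config$n_countries, 0, L)
    cy <- runif(config$n_countries, 0, L)
    country_idx <- max.col(-outer(x, cx, "-")^2 - outer(y, cy, "-")^2,
                           ties.method = "first")
    ll <- .km_to_lonlat(x - L / 2, y - L / 2)
    cities <- data.frame(
      city_id = sprintf("c%05d", seq_len(n)),
      name = sprintf("City %d", seq_len(n)),
      lon = ll$lon, lat = ll$lat,
      country = sprintf("C%02d", country_idx),
      population = pop, stringsAsFactors = FALSE)
    cities <- validate_cities(cities)

    # great-circle distance matrix and MST
    D <- .pairwise_haversine(cities$lon, cities$lat)
    g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    tree <- igraph::mst(g, algorithm = "prim")
    if (igraph::components(tree)$no != 1L)
      .stopf("generate_city_system: network could not be connected")
    te <- igraph::as_edgelist(tree, names = FALSE)
    tree_key <- paste(pmin(te[, 1], te[, 2]), pmax(te[, 1], te[, 2]))
    n_extra <- round(config$extra_edge_fraction * n)
    if (n_extra > 0) {
      # candidate extra edges ranked by gravity-discounted length
      # d / sqrt(P_i P_j): short links between large cities first.  This
      # concentrates the added highways on big cities, so the degree >= 6
      # (low isolation) class is small in number but large in population,
      # as observed continentally.
      ut <- which(upper.tri(D), arr.ind = TRUE)
      score <- D[ut] / sqrt(pop[ut[, 1]] * pop[ut[, 2]])
      cand <- ut[order(score), , drop = FALSE]
      key <- paste(cand[, 1], cand[, 2])
      cand <- cand[!(key %in% tree_key), , drop = FALSE]
      extra <- cand[seq_len(min(n_extra, nrow(cand))), , drop = FALSE]
      ei <- rbind(te, extra)
    } else {
      ei <- te
    }
    len_km <- D[cbind(ei[, 1], ei[, 2])]
    cv <- config$travel_time_noise_cv
    noise <- if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      exp(rnorm(nrow(ei), -sdlog^2 / 2, sdlog))
    } else rep(1, nrow(ei))
    nodes <- data.frame(node_id = sub("^c", "n", cities$city_id),
                        kind = "city", lon = cities$lon, lat = cities$lat,
                        country = cities$country, city_ref = cities$city_id,
                        stringsAsFactors = FALSE)
    edges <- data.frame(from_node = nodes$node_id[ei[, 1]],
                        to_node = nodes$node_id[ei[, 2]],
                        travel_time_h = len_km / config$speed_kmh * noise,
                        stringsAsFactors = FALSE)
    network <- urban_network(nodes, edges)
    list(cities = cities, network = network,
         truth = list(beta_true = config$beta_true,
                      isolation_multiplier = config$isolation_multiplier,
                      config = config))
  })
}

# symmetric great-circle distance matrix (km), zero diagonal
.pairwise_haversine <- function(lon, lat) {
  to_rad <- pi / 180
  phi <- lat * to_rad; lam <- lon * to_rad
  dphi <- outer(phi, phi, "-"); dlam <- outer(lam, lam, "-")
  a <- sin(dphi / 2)^2 + (cos(phi) %o% cos(phi)) * sin(dlam / 2)^2
  a[a > 1] <- 1
  a[a < 0] <- 0
  D <- 2 * .EARTH_RADIUS_KM * asin(sqrt(a))
  diag(D) <- 0
  D
}

# minimum haversine distance from each point to any city
.nearest_city_km <- function(lon, lat, cities) {
  .cpp_nearest_city(lon, lat, cities$lon, cities$lat)$distance_km
}

#' Generate a synthetic event stream with planted effects
#'
#' Per-city expected casualties are \eqn{\lambda_j = \alpha P_j^{\beta}
#' m_j}, where the multiplier m_j realises the planted effect: for
#' `effect_on = "isolation"` (default) high-isolation cities get
#' `isolation_multiplier`, low-isolation cities 1, medium the geometric
#' midpoint; for `effect_on = "centrality"` the multiplier decays
#' geometrically from the lowest to the highest centrality quartile.  Event
#' counts are Poisson with mean \eqn{\lambda_j / } `mean_fatalities`;
#' per-event fatalities are negative binomial with mean `mean_fatalities`
#' and size `fatality_dispersion`; coordinates are the city centre plus
#' isotropic Gaussian jitter.  A `rural_fraction` of all events is placed
#' uniformly at more than 50 km from every city (so no threshold in the
#' 1-30 km sweep captures them); dates are uniform in the window and
#' categories are drawn from `category_probs`.
#'
#' @param cities city table from [generate_city_system()].
#' @param network matching [urban_network()].
#' @param config the [synthetic_config()].
#' @param metrics optional per-city metric table; required with
#'   `effect_on = "centrality"` (needs `centrality_class`).  When `NULL`,
#'   degree-based isolation classes are computed from the network.
#' @param effect_on `"isolation"` or `"centrality"`: which classification
#'   the planted multiplier keys on.
#' @return list: `events` (validated event table), `truth` (planted truth:
#'   `alpha`, `beta_true`, multiplier, per-city `expected_casualties` and
#'   `expected_events`, `expected_rural_events`, `multiplier` vector).
#' @export
generate_events <- function(cities, network, config, metrics = NULL,
                            effect_on = c("isolation", "centrality")) {
  stopifnot(inherits(config, "synthetic_config"))
  effect_on <- match.arg(effect_on)
  cities <- validate_cities(cities)
  if (is.null(metrics)) {
    if (effect_on == "centrality")
      .stopf("generate_events: metrics with centrality_class required for effect_on='centrality'")
    deg <- compute_degree(network)
    if (!all(cities$city_id %in% names(deg)))
      .stopf("generate_events: city missing from network")
    iso <- classify_isolation(deg)[cities$city_id]
  } else {
    .require_columns(metrics, "city_id", "metrics")
    row <- match(cities$city_id, metrics$city_id)
    if (anyNA(row)) .stopf("generate_events: metrics missing cities")
    if (effect_on == "isolation") {
      if (is.null(metrics$isolation_class))
        .stopf("generate_events: metrics lack isolation_class")
      iso <- metrics$isolation_class[row]
    } else {
      if (is.null(metrics$centrality_class))
        .stopf("generate_events: metrics lack centrality_class")
      qcl <- metrics$centrality_class[row]
    }
  }
  mult <- config$isolation_multiplier
  m_j <- if (effect_on == "isolation") {
    c(high = mult, medium = sqrt(mult), low = 1)[iso]
  } else {
    c(Q1_lowest = mult, Q2 = mult^(2 / 3), Q3 = mult^(1 / 3),
      Q4_highest = 1)[qcl]
  }
  m_j <- unname(m_j)
  pb <- cities$population^config$beta_true
  alpha <- config$alpha_true
  if (is.na(alpha)) alpha <- config$target_casualties / sum(pb * m_j)
  lambda <- alpha * pb * m_j              # expected urban casualties
  mu <- lambda / config$mean_fatalities   # expected urban events

  .with_seed(config$seed + 1L, {
    n_ev <- rpois(length(mu), mu)
    city_row <- rep(seq_len(nrow(cities)), n_ev)
    n_urban <- length(city_row)
    # rural stream sized so rural events are rural_fraction of the total
    mu_rural <- sum(mu) * config$rural_fraction / (1 - config$rural_fraction)
    n_rural <- rpois(1, mu_rural)

    # urban coordinates: city centre + isotropic jitter (km -> degrees)
    clat <- cities$lat[city_row]; clon <- cities$lon[city_row]
    dy <- rnorm(n_urban, 0, config$event_jitter_km)
    dx <- rnorm(n_urban, 0, config$event_jitter_km)
    elat <- clat + dy / .KM_PER_DEG
    elon <- clon + dx / (.KM_PER_DEG * cos(clat * pi / 180))

    # rural coordinates: uniform in the margin-extended region, rejected
    # until > 50 km from every city
    L <- config$region_size_km
    rlon <- numeric(0); rlat <- numeric(0)
    tries <- 0L
    while (length(rlon) < n_rural) {
      need <- n_rural - length(rlon)
      m <- max(100L, 2L * need)
      px <- runif(m, -100, L + 100) - L / 2
      py <- runif(m, -100, L + 100) - L / 2
      ll <- .km_to_lonlat(px, py)
      ok <- .nearest_city_km(ll$lon, ll$lat, cities) > 50
      rlon <- c(rlon, ll$lon[ok]); rlat <- c(rlat, ll$lat[ok])
      tries <- tries + 1L
      if (tries > 200L)
        .stopf("generate_events: could not place rural events > 50 km from all cities")
    }
    rlon <- rlon[seq_len(n_rural)]; rlat <- rlat[seq_len(n_rural)]

    n_tot <- n_urban + n_rural
    fat <- rnbinom(n_tot, size = config$fatality_dispersion,
                   mu = config$mean_fatalities)
    day_span <- as.integer(config$window_end - config$window_start)
    dates <- config$window_start + sample.int(day_span + 1L, n_tot,
                                              replace = TRUE) - 1L
    cats <- sample(names(config$category_probs), n_tot, replace = TRUE,
                   prob = config$category_probs)
    events <- data.frame(
      event_id = sprintf("e%07d", seq_len(n_tot)),
      date = dates,
      category = cats,
      lon = c(elon, rlon), lat = c(elat, rlat),
      fatalities = fat, stringsAsFactors = FALSE)
    events <- validate_events(events)
    truth <- list(alpha = alpha, beta_true = config$beta_true,
                  effect_on = effect_on,
                  isolation_multiplier = config$isolation_multiplier,
                  multiplier = setNames(m_j, cities$city_id),
                  expected_casualties = setNames(lambda, cities$city_id),
                  expected_events = setNames(mu, cities$city_id),
                  expected_rural_events = mu_rural,
                  source_city = c(cities$city_id[city_row],
                                  rep(.RURAL, n_rural)))
    list(events = events, truth = truth)
  })
}

#' Parse a flat key=value configuration file
#'
#' Lines of the form `key = value` (comments with `#`) are coerced onto
#' [synthetic_config()] arguments; numeric-looking values are converted.
#'
#' @param path file path.
#' @return a [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  if (!file.exists(path)) .err("urbiso_io_error", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) .err("urbiso_schema_error", "config: malformed line: %s",
                     lines[bad][1])
  vals <- lapply(kv, function(p) {
    v <- p[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[[`, "", 1L)
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    .err("urbiso_schema_error", "config: unknown key(s): %s",
         paste(unknown, collapse = ", "))
  do.call(synthetic_config, vals)
}
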