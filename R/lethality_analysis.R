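#' @title Lethality rates and isolation / centrality impacts
#' @description The lethality of a city is its assigned casualties per
#'   100,000 inhabitants (optionally per year); the collective lethality of
#'   a group of cities divides the group's total casualties by its combined
#'   population.  The isolation impact theta is the ratio of the collective
#'   lethality of high- versus low-isolation cities; the centrality impact
#'   compares the bottom versus top centrality quartiles.  A half-event
#'   subsampling procedure checks that the ratios are not driven by a few
#'   extreme events.
#' @name lethality_analysis
NULL

#' Window length in years
#'
#' @param params an [assignment_params()]; returns
#'   `(window_end - window_start) / 365.25` days, or 1 when the window is
#'   open-ended (raw, non-annualised rates).
#' @return years as a number.
#' @export
window_years <- function(params) {
  if (is.null(params$window_start) || is.null(params$window_end)) return(1)
  as.numeric(params$window_end - params$window_start) / 365.25
}

#' Lethality of a single city
#'
#' Casualties per 100,000 inhabitants per year: `casualties /
#' (population / 1e5) / years`.  With `years = 1` this is the raw
#' casualties-over-population ratio expressed per 100,000.
#'
#' @param casualties non-negative casualty count.
#' @param population city population (>= 1).
#' @param years length of the observation window in years (> 0).
#' @return rate per 100,000 persons per year (vectorised).
#' @export
city_lethality <- function(casualties, population, years = 1) {
  if (any(years <= 0)) .stopf("years must be > 0")
  if (any(population < 1)) .stopf("population must be >= 1")
  if (any(casualties < 0)) .stopf("casualties must be >= 0")
  casualties / (population / 1e5) / years
}

#' Collective lethality of a group of cities
#'
#' Total casualties over the group divided by its combined population (per
#' 100,000, per year) — not the mean of the member cities' rates.
#'
#' @param group character vector of city_ids (nonempty, all present in
#'   `table`).
#' @param table city-violence table from [aggregate_city_violence()].
#' @param years window length in years.
#' @param measure casualty column used (default `"casualties_all"`).
#' @return rate per 100,000 persons per year.
#' @export
group_lethality <- function(group, table, years = 1,
                            measure = c("casualties_all", "casualties_vac",
                                        "n_events")) {
  measure <- match.arg(measure)
  if (!length(group)) .stopf("group_lethality: empty group")
  rows <- match(group, table$city_id)
  if (anyNA(rows))
    .stopf("group_lethality: unknown city_id: %s",
           paste(head(group[is.na(rows)], 5), collapse = ", "))
  city_lethality(sum(table[[measure]][rows]),
                 sum(table$population[rows]), years)
}

.theta_ratio <- function(num, den) {
  if (den == 0) {
    if (num == 0) .stopf("impact undefined: both groups have zero lethality")
    return(Inf)
  }
  num / den
}

#' Isolation impact theta
#'
#' Ratio of the collective lethality of high-isolation cities to that of
#' low-isolation cities.  Equals 1 when isolation carries no signal; values
#' above 1 mean isolated cities are more lethal per capita.  Returns `Inf`
#' when the low-isolation group has zero casualties but the high group does
#' not.
#'
#' @param table city-violence table.
#' @param metrics per-city metric table from [city_network_metrics()] (or
#'   any data.frame with `city_id` and `isolation_class`).
#' @param years window length in years (cancels in the ratio).
#' @param measure casualty column used.
#' @return the ratio theta.
#' @export
isolation_impact <- function(table, metrics, years = 1,
                             measure = "casualties_all") {
  hi <- metrics$city_id[metrics$isolation_class == "high"]
  lo <- metrics$city_id[metrics$isolation_class == "low"]
  if (!length(hi) || !length(lo))
    .stopf("isolation_impact: empty isolation group (high: %d, low: %d)",
           length(hi), length(lo))
  .theta_ratio(group_lethality(hi, table, years, measure),
               group_lethality(lo, table, years, measure))
}

#' Centrality impact theta^c
#'
#' Ratio of the collective lethality of the 25\% of cities with the lowest
#' centrality to that of the 25\% with the highest centrality.
#'
#' @inheritParams isolation_impact
#' @param metrics data.frame with `city_id` and `centrality_class`.
#' @return the ratio theta^c.
#' @export
centrality_impact <- function(table, metrics, years = 1,
                              measure = "casualties_all") {
  lo_c <- metrics$city_id[metrics$centrality_class == "Q1_lowest"]
  hi_c <- metrics$city_id[metrics$centrality_class == "Q4_highest"]
  if (!length(lo_c) || !length(hi_c))
    .stopf("centrality_impact: empty centrality quartile")
  .theta_ratio(group_lethality(lo_c, table, years, measure),
               group_lethality(hi_c, table, years, measure))
}

#' Half-event subsampling distribution of theta
#'
#' Repeatedly keeps a uniform random fraction of the events (default one
#' half, without replacement), re-derives the per-city casualty totals and
#' recomputes the impact ratio, testing whether the full-data theta is
#' carried by a few extreme events.  Per-event nearest-city assignment does
#' not depend on which other events are sampled, so events are assigned
#' once and each replicate re-aggregates the sampled subset — numerically
#' identical to re-running the assignment per replicate.
#'
#' @param events validated event table.
#' @param cities validated city table.
#' @param metrics per-city metric table.
#' @param params an [assignment_params()].
#' @param frac fraction of events kept per replicate, in (0, 1].
#' @param reps number of replicates (default 1000).
#' @param seed integer seed.
#' @param impact `"isolation"` or `"centrality"`.
#' @param measure casualty column used.
#' @return list of class `subsample_distribution`: `theta_samples`
#'   (length `reps`), `theta_full`, `frac`, `reps`, `seed`, `impact`,
#'   `measure`.
#' @export
subsample_events_theta <- function(events, cities, metrics,
                                   params = assignment_params(),
                                   frac = 0.5, reps = 1000, seed = 1,
                                   impact = c("isolation", "centrality"),
                                   measure = "casualties_all") {
  impact <- match.arg(impact)
  if (reps < 1) .stopf("reps must be >= 1")
  if (frac <= 0 || frac > 1) .stopf("frac must be in (0, 1]")
  events <- validate_events(events)
  asg <- assign_events(events, cities, params)
  if (nrow(asg) < 2) .stopf("need >= 2 events")
  tab <- aggregate_city_violence(asg, events, cities, params)
  years <- window_years(params)
  theta_fun <- if (impact == "isolation") isolation_impact else
    centrality_impact
  theta_full <- theta_fun(tab, metrics, years, measure)

  # per-event contribution to the two groups' casualty totals
  ev <- events[match(asg$event_id, events$event_id), , drop = FALSE]
  cats <- attr(tab, "casualty_categories")
  if (measure == "casualties_vac") cats <- "violence_against_civilians"
  counted <- ev$category %in% cats & asg$assigned_city != .RURAL
  if (impact == "isolation") {
    g_num <- metrics$city_id[metrics$isolation_class == "high"]
    g_den <- metrics$city_id[metrics$isolation_class == "low"]
  } else {
    g_num <- metrics$city_id[metrics$centrality_class == "Q1_lowest"]
    g_den <- metrics$city_id[metrics$centrality_class == "Q4_highest"]
  }
  pop <- setNames(tab$population, tab$city_id)
  pop_num <- sum(pop[g_num]); pop_den <- sum(pop[g_den])
  f_num <- ifelse(counted & asg$assigned_city %in% g_num, ev$fatalities, 0)
  f_den <- ifelse(counted & asg$assigned_city %in% g_den, ev$fatalities, 0)
  n <- nrow(asg)
  m <- round(frac * n)
  samples <- .with_seed(seed, vapply(seq_len(reps), function(r) {
    idx <- sample.int(n, m)
    .theta_ratio(sum(f_num[idx]) / pop_num, sum(f_den[idx]) / pop_den)
  }, numeric(1)))
  structure(list(theta_samples = samples, theta_full = theta_full,
                 frac = frac, reps = reps, seed = seed, impact = impact,
                 measure = measure),
            class = "subsample_distribution")
}

#' @export
print.subsample_distribution <- function(x, ...) {
  q <- quantile(x$theta_samples, c(0.025, 0.5, 0.975))
  cat(sprintf(
    "<subsample_distribution> %s theta, %d reps at frac %.2f: full %.3f, 2.5/50/97.5%% = %.3f/%.3f/%.3f\n",
    x$impact, x$reps, x$frac, x$theta_full, q[1], q[2], q[3]))
  invisible(x)
}

#' Impact ratios across a sweep of assignment thresholds
#'
#' Re-runs assignment, aggregation and both impact ratios for each distance
#' threshold, producing the curve of theta against delta.
#'
#' @param events validated event table.
#' @param cities validated city table.
#' @param metrics per-city metric table.
#' @param deltas numeric vector of thresholds in km (all > 0; the standard
#'   sweep is 1-30).
#' @param params an [assignment_params()] supplying window and categories;
#'   its `delta_km` is replaced per sweep point.
#' @param measure casualty column used.
#' @return data.frame `delta_km`, `theta_isolation`, `theta_centrality`.
#' @export
delta_sweep <- function(events, cities, metrics, deltas = c(1, 5, 10, 20, 30),
                        params = assignment_params(),
                        measure = "casualties_all") {
  if (!length(deltas)) .stopf("deltas must be nonempty")
  if (any(deltas <= 0)) .stopf("all deltas must be > 0")
  years <- window_years(params)
  rows <- lapply(deltas, function(d) {
    p <- assignment_params(delta_km = d, window_start = params$window_start,
                           window_end = params$window_end,
                           categories = params$categories)
    asg <- assign_events(events, cities, p)
    tab <- aggregate_city_violence(asg, events, cities, p)
    data.frame(delta_km = d,
               theta_isolation = isolation_impact(tab, metrics, years,
                                                  measure),
               theta_centrality = centrality_impact(tab, metrics, years,
                                                    measure))
  })
  do.call(rbind, rows)
}
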