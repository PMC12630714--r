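#' @title Urban-scaling fits and robustness checks
#' @description The scaling relation \eqn{V_i = \alpha P_i^\beta} between a
#'   per-city violence measure and population is estimated by ordinary
#'   least squares of log10 measure on log10 population.  \eqn{\beta < 1}
#'   (sublinear) means smaller cities carry more violence per capita.
#'   Robustness checks refit after removing the most populous cities
#'   ("dragon-kings"), over random city subsamples, and over truncated time
#'   windows.
#' @name scaling_analysis
NULL

.MEASURES <- c("casualties_all", "casualties_vac", "n_events")

# run expr under a local RNG stream without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Fit the urban-scaling relation V = alpha * P^beta
#'
#' OLS of `log10(measure)` on `log10(population)` over cities with a
#' strictly positive measure; zero-measure cities are excluded and counted
#' (`zero_handling = "exclude"`, the default) or kept via a `log10(V+1)`
#' sensitivity fit (`"add_one"`).
#'
#' @param table a city-violence table from [aggregate_city_violence()], or
#'   any data.frame with `population` and the measure column.
#' @param measure one of `"casualties_all"`, `"casualties_vac"`,
#'   `"n_events"`.
#' @param zero_handling `"exclude"` or `"add_one"`.
#' @return object of class `scaling_fit`: `alpha`, `beta`, `beta_se`
#'   (analytic OLS standard error of the slope), `n_cities_used`,
#'   `n_zero_excluded`, `measure`, `delta_km`, `window`.
#' @export
fit_scaling <- function(table, measure = .MEASURES,
                        zero_handling = c("exclude", "add_one")) {
  measure <- match.arg(measure)
  zero_handling <- match.arg(zero_handling)
  .require_columns(table, c("population", measure), "city violence table")
  v <- table[[measure]]
  p <- table$population
  if (zero_handling == "add_one") {
    keep <- rep(TRUE, length(v))
    y <- log10(v + 1)
  } else {
    keep <- v > 0
    y <- log10(v[keep])
  }
  x <- log10(p[keep])
  if (sum(keep) < 3)
    .stopf("fit_scaling: need >= 3 cities with positive %s, got %d",
           measure, sum(keep))
  fit <- lm(y ~ x)
  # a noise-free power law is legitimate input; silence the perfect-fit note
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(alpha = 10^unname(coef(fit)[1]),
                 beta = unname(coef(fit)[2]),
                 beta_se = unname(sm["x", "Std. Error"]),
                 n_cities_used = sum(keep),
                 n_zero_excluded = sum(!keep),
                 measure = measure,
                 zero_handling = zero_handling,
                 delta_km = if (!is.null(table$delta_km))
                   table$delta_km[1] else NA_real_,
                 window = c(start = as.character(table$window_start[1]),
                            end = as.character(table$window_end[1]))),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "<scaling_fit> %s: beta = %.4f +/- %.4f, alpha = %.4g (n = %d, %d zero excluded)\n",
    x$measure, x$beta, x$beta_se, x$alpha, x$n_cities_used,
    x$n_zero_excluded))
  invisible(x)
}

#' Dragon-king sensitivity: drop the largest cities and refit
#'
#' Refits the scaling relation after removing the `1..k` most populous
#' cities, testing whether the exponent is driven by a few megacities.
#'
#' @inheritParams fit_scaling
#' @param k maximum number of top-population cities to drop; must leave at
#'   least 3 positive cities.
#' @return list: `baseline_beta`, `betas_without_top_k` (numeric vector of
#'   length `k`, entry j = beta after dropping the j most populous cities).
#' @export
drop_dragon_kings <- function(table, measure = .MEASURES, k = 1) {
  measure <- match.arg(measure)
  base <- fit_scaling(table, measure)
  if (k < 0 || k != floor(k)) .stopf("k must be a non-negative integer")
  if (k >= base$n_cities_used - 3)
    .stopf("k = %d leaves fewer than 3 positive cities (have %d)", k,
           base$n_cities_used)
  ord <- order(table$population, decreasing = TRUE)
  betas <- vapply(seq_len(k), function(j) {
    fit_scaling(table[-ord[seq_len(j)], , drop = FALSE], measure)$beta
  }, numeric(1))
  list(baseline_beta = base$beta, betas_without_top_k = betas,
       measure = measure)
}

#' Random city-subsample sensitivity
#'
#' Refits the scaling relation on `reps` independent uniform subsamples of
#' a fraction `frac` of the cities.
#'
#' @inheritParams fit_scaling
#' @param frac fraction of cities kept per replicate, in (0, 1].
#' @param reps number of replicates.
#' @param seed integer seed; the result is reproducible from it.
#' @return list: `baseline_beta`, `subsample_betas` (length `reps`),
#'   `frac`, `reps`, `seed`.
#' @export
subsample_cities <- function(table, measure = .MEASURES, frac = 0.5,
                             reps = 100, seed = 1) {
  measure <- match.arg(measure)
  if (frac <= 0 || frac > 1) .stopf("frac must be in (0, 1]")
  if (reps < 1) .stopf("reps must be >= 1")
  base <- fit_scaling(table, measure)
  n <- nrow(table)
  m <- round(frac * n)
  if (m < 3) .stopf("frac too small: subsamples of %d cities", m)
  betas <- .with_seed(seed, vapply(seq_len(reps), function(r) {
    idx <- sample.int(n, m)
    fit_scaling(table[idx, , drop = FALSE], measure)$beta
  }, numeric(1)))
  list(baseline_beta = base$beta, subsample_betas = betas, frac = frac,
       reps = reps, seed = seed, measure = measure)
}

#' Scaling exponents as a function of the window start year
#'
#' Re-runs assignment, aggregation and the scaling fit with the window
#' start moved to January 1 of each requested year (window end fixed),
#' returning the casualty exponent beta_L and the violence-against-
#' civilians exponent beta_V per start year.
#'
#' @param events validated event table.
#' @param cities validated city table.
#' @param params an [assignment_params()]; its `window_start` is replaced
#'   per year.
#' @param start_years integer vector of years.
#' @return data.frame `start_year`, `beta_L`, `beta_V`, `n_cities_L`,
#'   `error` (NA, or the error message for years whose truncated window
#'   cannot be fitted).
#' @export
beta_by_start_year <- function(events, cities, params = assignment_params(),
                               start_years) {
  if (!length(start_years)) .stopf("start_years must be nonempty")
  rows <- lapply(start_years, function(y) {
    p <- assignment_params(delta_km = params$delta_km,
                           window_start = as.Date(sprintf("%d-01-01", y)),
                           window_end = params$window_end,
                           categories = params$categories)
    tryCatch({
      asg <- assign_events(events, cities, p)
      tab <- aggregate_city_violence(asg, events, cities, p)
      data.frame(start_year = y,
                 beta_L = fit_scaling(tab, "casualties_all")$beta,
                 beta_V = fit_scaling(tab, "casualties_vac")$beta,
                 n_cities_L = fit_scaling(tab, "casualties_all")$n_cities_used,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(start_year = y, beta_L = NA_real_, beta_V = NA_real_,
                 n_cities_L = NA_integer_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}
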