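viol_table <- function(city_id, population, casualties,
                       vac = casualties) {
  data.frame(city_id = city_id, population = population,
             n_events = 1L, casualties_all = casualties,
             casualties_vac = vac, delta_km = 10,
             window_start = as.Date("2000-01-01"),
             window_end = as.Date("2000-12-31"),
             stringsAsFactors = FALSE)
}

test_that("city lethality is casualties per 100k per year", {
  expect_equal(city_lethality(5, 100000, 1), 5)
  expect_equal(city_lethality(0, 123456, 7), 0)
  expect_equal(city_lethality(39, 50000, 2), 39)
  expect_error(city_lethality(1, 1000, 0), "years")
  expect_error(city_lethality(1, 0, 1), "population")
})

test_that("group lethality pools casualties over pooled population", {
  tab <- viol_table(c("a", "b"), c(100000, 300000), c(5, 3))
  expect_equal(group_lethality(c("a", "b"), tab), 2)
  expect_equal(group_lethality("a", tab), city_lethality(5, 100000, 1))
  expect_equal(group_lethality("b", viol_table(c("a", "b"),
                                               c(1e5, 3e5), c(5, 0))), 0)
  expect_error(group_lethality(character(0), tab), "empty")
  expect_error(group_lethality(c("a", "zz"), tab), "zz")

  # identity: the group rate is the population-weighted mean of city rates
  set.seed(3)
  tab2 <- viol_table(sprintf("c%02d", 1:20),
                     sample(1e4:1e6, 20), rpois(20, 40))
  rates <- city_lethality(tab2$casualties_all, tab2$population, 1)
  grp <- sample(tab2$city_id, 9)
  idx <- match(grp, tab2$city_id)
  want <- sum(rates[idx] * tab2$population[idx]) / sum(tab2$population[idx])
  expect_equal(group_lethality(grp, tab2), want, tolerance = 1e-12)
})

test_that("impact ratios compare the stated groups, with infinity sentinel", {
  metrics <- data.frame(
    city_id = c("h1", "h2", "m1", "l1", "l2"),
    isolation_class = c("high", "high", "medium", "low", "low"),
    centrality_class = c("Q1_lowest", "Q1_lowest", "Q2", "Q4_highest",
                         "Q4_highest"),
    stringsAsFactors = FALSE)
  # identical planted rates: theta exactly 1
  tab <- viol_table(metrics$city_id, rep(1e5, 5), rep(4, 5))
  expect_equal(isolation_impact(tab, metrics), 1)
  expect_equal(centrality_impact(tab, metrics), 1)
  # 2x rate in the high/low-centrality group
  tab2 <- viol_table(metrics$city_id, rep(1e5, 5), c(8, 8, 4, 4, 4))
  expect_equal(isolation_impact(tab2, metrics), 2)
  expect_equal(centrality_impact(tab2, metrics), 2)
  # zero in the reference group -> +Inf, both-zero -> error
  tab3 <- viol_table(metrics$city_id, rep(1e5, 5), c(8, 8, 4, 0, 0))
  expect_identical(isolation_impact(tab3, metrics), Inf)
  tab4 <- viol_table(metrics$city_id, rep(1e5, 5), 0)
  expect_error(isolation_impact(tab4, metrics), "zero")
  # degenerate metrics without both groups
  expect_error(isolation_impact(tab, metrics[1:3, ]), "empty")
})

test_that("planted centrality effect is recovered through the full pipeline", {
  cfg <- synthetic_config(n_cities = 400, region_size_km = 3000,
                          beta_true = 1, isolation_multiplier = 15,
                          target_casualties = 80000, seed = 27)
  sys <- generate_city_system(cfg)
  metrics <- city_network_metrics(sys$network, sys$cities)
  ev <- generate_events(sys$cities, sys$network, cfg, metrics = metrics,
                        effect_on = "centrality")
  p <- assignment_params(10, cfg$window_start, cfg$window_end)
  asg <- assign_events(ev$events, sys$cities, p)
  tab <- aggregate_city_violence(asg, ev$events, sys$cities, p)
  th <- centrality_impact(tab, metrics, window_years(p))
  expect_gt(th, 12)
  expect_lt(th, 19)
})

test_that("half-event subsampling is reproducible and consistent", {
  cfg <- synthetic_config(n_cities = 250, region_size_km = 2500,
                          beta_true = 1, isolation_multiplier = 5.4,
                          target_casualties = 30000, seed = 15)
  sys <- generate_city_system(cfg)
  metrics <- city_network_metrics(sys$network, sys$cities)
  ev <- generate_events(sys$cities, sys$network, cfg, metrics = metrics)
  p <- assignment_params(10, cfg$window_start, cfg$window_end)

  # frac = 1 reproduces the full-data theta in every replicate
  s1 <- subsample_events_theta(ev$events, sys$cities, metrics, p,
                               frac = 1, reps = 3, seed = 2)
  expect_true(all(abs(s1$theta_samples - s1$theta_full) < 1e-12))

  s2 <- subsample_events_theta(ev$events, sys$cities, metrics, p,
                               frac = 0.5, reps = 60, seed = 8)
  s3 <- subsample_events_theta(ev$events, sys$cities, metrics, p,
                               frac = 0.5, reps = 60, seed = 8)
  expect_identical(s2$theta_samples, s3$theta_samples)
  expect_length(s2$theta_samples, 60)
  # planted multiplier: every half-sample ratio stays above one
  expect_gt(min(s2$theta_samples), 1)
  # and the subsample distribution brackets the full-data value
  expect_gt(quantile(s2$theta_samples, 0.975), s2$theta_full)
  expect_lt(quantile(s2$theta_samples, 0.025), s2$theta_full)

  expect_error(subsample_events_theta(ev$events, sys$cities, metrics, p,
                                      reps = 0), "reps")
})

test_that("delta sweep matches direct impacts and stays above one when planted", {
  cfg <- synthetic_config(n_cities = 250, region_size_km = 2500,
                          beta_true = 1, isolation_multiplier = 5.4,
                          target_casualties = 30000, seed = 16)
  sys <- generate_city_system(cfg)
  metrics <- city_network_metrics(sys$network, sys$cities)
  ev <- generate_events(sys$cities, sys$network, cfg, metrics = metrics)
  p <- assignment_params(10, cfg$window_start, cfg$window_end)
  sw <- delta_sweep(ev$events, sys$cities, metrics, deltas = c(5, 10, 30),
                    params = p)
  expect_identical(sw$delta_km, c(5, 10, 30))
  expect_true(all(sw$theta_isolation > 1))
  # single-delta sweep equals the direct ratio
  asg <- assign_events(ev$events, sys$cities, p)
  tab <- aggregate_city_violence(asg, ev$events, sys$cities, p)
  expect_equal(sw$theta_isolation[sw$delta_km == 10],
               isolation_impact(tab, metrics, window_years(p)),
               tolerance = 1e-12)
  expect_error(delta_sweep(ev$events, sys$cities, metrics, deltas = c(0, 5),
                           params = p), "delta")
})

test_that("null subsample band brackets one across generator seeds", {
  # isolation_multiplier = 1: the 2.5-97.5% band of subsampled theta should
  # contain 1 for the vast majority of generated worlds
  hits <- 0L
  tried <- 0L
  n_seeds <- 50L
  for (s in seq_len(n_seeds)) {
    cfg <- synthetic_config(n_cities = 150, region_size_km = 2500,
                            beta_true = 1, isolation_multiplier = 1,
                            target_casualties = 4000, seed = 6000 + s)
    sys <- generate_city_system(cfg)
    deg <- compute_degree(sys$network)
    metrics <- data.frame(city_id = names(deg), degree = unname(deg),
                          isolation_class = unname(classify_isolation(deg)),
                          stringsAsFactors = FALSE)
    if (!any(metrics$isolation_class == "low")) next  # degenerate world
    tried <- tried + 1L
    ev <- generate_events(sys$cities, sys$network, cfg, metrics = metrics)
    p <- assignment_params(10, cfg$window_start, cfg$window_end)
    sub <- subsample_events_theta(ev$events, sys$cities, metrics, p,
                                  frac = 0.5, reps = 200, seed = s)
    band <- quantile(sub$theta_samples, c(0.025, 0.975))
    if (band[1] <= 1 && 1 <= band[2]) hits <- hits + 1L
  }
  expect_gte(tried, 25L)          # most generated worlds are usable
  expect_gte(hits, 0.9 * tried)
})

test_that("theta estimation error shrinks with total casualties", {
  err_at <- function(target) {
    errs <- vapply(1:4, function(s) {
      cfg <- synthetic_config(n_cities = 400, region_size_km = 3000,
                              beta_true = 1, isolation_multiplier = 5.4,
                              target_casualties = target, seed = 700 + s)
      sys <- generate_city_system(cfg)
      deg <- compute_degree(sys$network)
      metrics <- data.frame(city_id = names(deg), degree = unname(deg),
                            isolation_class =
                              unname(classify_isolation(deg)),
                            stringsAsFactors = FALSE)
      ev <- generate_events(sys$cities, sys$network, cfg, metrics = metrics)
      p <- assignment_params(10, cfg$window_start, cfg$window_end)
      asg <- assign_events(ev$events, sys$cities, p)
      tab <- aggregate_city_violence(asg, ev$events, sys$cities, p)
      abs(isolation_impact(tab, metrics) - 5.4)
    }, numeric(1))
    mean(errs)
  }
  e <- c(err_at(1500), err_at(15000), err_at(150000))
  expect_lt(e[3], e[1])   # two orders of magnitude more data: smaller error
  expect_lt(e[3], 0.4)    # and small in absolute terms at the largest size
})
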