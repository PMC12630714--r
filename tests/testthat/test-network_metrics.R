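test_that("degrees count incident edges, including parallels and junctions", {
  fx <- path_fixture()
  expect_identical(compute_degree(fx$network), c(A = 1L, B = 2L, C = 1L))

  # star: hub with 6 spokes -> hub degree 6; isolated city -> 0
  ids <- c("hub", sprintf("s%d", 1:6), "lone")
  nodes <- data.frame(node_id = paste0("n", ids), kind = "city",
                      lon = seq_along(ids), lat = 0, country = "X",
                      city_ref = ids, stringsAsFactors = FALSE)
  edges <- data.frame(from_node = "nhub", to_node = paste0("ns", 1:6),
                      travel_time_h = 1, stringsAsFactors = FALSE)
  deg <- compute_degree(urban_network(nodes, edges))
  expect_identical(deg[["hub"]], 6L)
  expect_identical(deg[["lone"]], 0L)

  # parallel edges count separately: D counts highways, not neighbours
  par_edges <- rbind(edges[1, ], edges[1, ])
  deg2 <- compute_degree(urban_network(nodes, par_edges))
  expect_identical(deg2[["hub"]], 2L)

  # degree sum identity
  fx2 <- random_graph_fixture(20, 8, seed = 99)
  d_all <- table(c(fx2$network$edges$from_node, fx2$network$edges$to_node))
  expect_identical(sum(d_all), 2L * nrow(fx2$network$edges))
})

test_that("isolation classes follow the degree thresholds", {
  expect_identical(unname(classify_isolation(c(0, 1, 2, 3, 4, 5, 6, 10))),
                   c("high", "high", "high", "medium", "medium", "medium",
                     "low", "low"))
  expect_error(classify_isolation(-1))
})

test_that("gravity flow evaluates the interaction law", {
  expect_equal(gravity_flow(1, 1, 1), 1.0)
  expect_equal(gravity_flow(100, 200, 10), 20000 / 10^2.8,
               tolerance = 1e-12)
  # doubling travel time divides flow by 2^gamma
  f1 <- gravity_flow(500, 700, 3)
  f2 <- gravity_flow(500, 700, 6)
  expect_equal(f1 / f2, 2^2.8, tolerance = 1e-12)
  expect_error(gravity_flow(1, 1, 0))
})

test_that("fastest paths honour border penalties and the lexicographic tie rule", {
  fx <- path_fixture()
  fp <- fastest_paths(fx$network)
  expect_equal(fp$times["A", "C"], 2)
  expect_identical(fp$paths[["A"]][["C"]], c("nA", "nB", "nC"))

  # border-crossing edge costs travel_time + penalty
  nodes <- data.frame(node_id = c("n1", "n2"), kind = "city", lon = c(0, 1),
                      lat = 0, country = c("A", "B"),
                      city_ref = c("c1", "c2"), stringsAsFactors = FALSE)
  edges <- data.frame(from_node = "n1", to_node = "n2", travel_time_h = 1)
  net <- urban_network(nodes, edges)
  expect_equal(fastest_paths(net)$times["c1", "c2"], 3)
  expect_equal(fastest_paths(net, gravity_params(border_penalty_h = 0)
                             )$times["c1", "c2"], 1)

  # two equal-time routes: the lexicographically smaller node sequence wins
  nodes2 <- data.frame(node_id = c("na", "nb", "nz", "ny"), kind = "city",
                       lon = c(0, 2, 1, 1), lat = c(0, 0, 1, -1),
                       country = "X",
                       city_ref = c("a", "b", "z", "y"),
                       stringsAsFactors = FALSE)
  edges2 <- data.frame(from_node = c("na", "nz", "na", "ny"),
                       to_node = c("nz", "nb", "ny", "nb"),
                       travel_time_h = 1, stringsAsFactors = FALSE)
  net2 <- urban_network(nodes2, edges2)
  fp2 <- fastest_paths(net2)
  expect_identical(fp2$paths[["a"]][["b"]], c("na", "ny", "nb"))
  fp2b <- fastest_paths(net2)
  expect_identical(fp2$paths, fp2b$paths)  # identical across runs
})

test_that("centrality matches the hand example and basic conventions", {
  fx <- path_fixture()
  cen <- compute_centrality(fx$network, fx$cities)
  expect_equal(cen[["B"]], 2^-2.8, tolerance = 1e-12)
  expect_equal(cen[["A"]], 0)
  expect_equal(cen[["C"]], 0)
  # endpoint-inclusive convention credits every pair's flow to its ends
  cen2 <- compute_centrality(fx$network, fx$cities, include_endpoints = TRUE)
  expect_equal(cen2[["A"]], 1 + 2^-2.8, tolerance = 1e-12)
  # leaf cities on any tree have zero intermediacy
  fx2 <- random_graph_fixture(15, 6, seed = 3)
  deg <- compute_degree(fx2$network)
  cen3 <- compute_centrality(fx2$network, fx2$cities)
  leaf <- names(deg)[deg == 1 & names(deg) %in% fx2$cities$city_id]
  skip_if(length(leaf) == 0)
  # a leaf can only be an endpoint, never intermediate
  expect_true(all(cen3[leaf] == 0))
})

test_that("centrality equals the brute-force oracle on random graphs", {
  set.seed(2024)
  n_graphs <- 60
  for (k in seq_len(n_graphs)) {
    n_nodes <- sample(5:30, 1)
    n_cities <- sample(2:min(12, n_nodes), 1)
    fx <- random_graph_fixture(n_nodes, n_cities, seed = 10000 + k)
    got <- compute_centrality(fx$network, fx$cities)
    want <- oracle_centrality(fx$network, fx$cities)
    expect_equal(unclass(got)[names(want)], want, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("centrality scale property: populations x c scale C_j by c^2", {
  fx <- random_graph_fixture(25, 10, seed = 42)
  base <- compute_centrality(fx$network, fx$cities)
  scaled_cities <- transform(fx$cities, population = population * 7)
  scaled <- compute_centrality(fx$network, scaled_cities)
  expect_equal(unclass(scaled), unclass(base) * 49, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a strictly faster route through a city never lowers its centrality", {
  # square a-b-c-d; route a->c initially around via d; adding a fast
  # b-corridor pulls a-c flow through b
  nodes <- data.frame(node_id = paste0("n", letters[1:4]), kind = "city",
                      lon = c(0, 1, 2, 1), lat = c(0, 1, 0, -1),
                      country = "X", city_ref = letters[1:4],
                      stringsAsFactors = FALSE)
  cities <- make_cities(letters[1:4], lon = nodes$lon, lat = nodes$lat,
                        population = c(10, 10, 10, 10))
  edges <- data.frame(from_node = c("na", "nd", "na", "nb"),
                      to_node = c("nd", "nc", "nb", "nc"),
                      travel_time_h = c(2, 2, 3, 3),
                      stringsAsFactors = FALSE)
  slow <- compute_centrality(urban_network(nodes, edges), cities)
  fast_edges <- edges
  fast_edges$travel_time_h[3:4] <- 1   # now a-b-c is the fastest a->c route
  fast <- compute_centrality(urban_network(nodes, fast_edges), cities)
  expect_gt(fast[["b"]], slow[["b"]])
})

test_that("centrality quartiles partition deterministically", {
  cen <- setNames(c(8, 7, 6, 5, 4, 3, 2, 1), sprintf("c%d", 1:8))
  cls <- classify_centrality_quartiles(cen)
  expect_identical(as.integer(table(cls)[c("Q1_lowest", "Q2", "Q3",
                                           "Q4_highest")]),
                   rep(2L, 4))
  expect_identical(unname(cls[c("c8", "c1")]), c("Q1_lowest", "Q4_highest"))

  # all-equal centralities: deterministic split by city_id order
  tied <- setNames(rep(1, 8), sprintf("c%d", 1:8))
  cls2 <- classify_centrality_quartiles(tied)
  expect_identical(unname(cls2[c("c1", "c2", "c3", "c4", "c5", "c6", "c7",
                                 "c8")]),
                   c("Q1_lowest", "Q1_lowest", "Q2", "Q2", "Q3", "Q3",
                     "Q4_highest", "Q4_highest"))
  expect_identical(classify_centrality_quartiles(tied), cls2)

  # n = 10: equal-as-possible sizes, identical across runs
  cen10 <- setNames(runif(10), sprintf("c%02d", 1:10))
  s <- table(classify_centrality_quartiles(cen10))
  expect_identical(sort(as.integer(s)), c(2L, 2L, 3L, 3L))
  expect_error(classify_centrality_quartiles(cen[1:3]), "4 cities")
})

test_that("city_network_metrics assembles a consistent table", {
  fx <- random_graph_fixture(25, 8, seed = 77)
  m <- city_network_metrics(fx$network, fx$cities)
  expect_identical(m$city_id, fx$cities$city_id)
  expect_true(all(m$isolation_class ==
                    unname(classify_isolation(m$degree))))
  expect_true(all(m$centrality >= 0))
  expect_identical(sort(unique(m$centrality_class)),
                   sort(unique(c("Q1_lowest", "Q2", "Q3", "Q4_highest"))))
})
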