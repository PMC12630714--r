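# Fixture builders shared across the suite.  Everything is constructed in
# code; no binary fixtures.

make_cities <- function(ids, lon, lat, population = 1,
                        country = "X", name = ids) {
  data.frame(city_id = ids, name = name, lon = lon, lat = lat,
             country = country, population = population,
             stringsAsFactors = FALSE)
}

# path network A - B - C on the equator, unit populations and edge times
path_fixture <- function() {
  cities <- make_cities(c("A", "B", "C"), lon = c(0, 0.5, 1), lat = 0)
  nodes <- data.frame(node_id = c("nA", "nB", "nC"), kind = "city",
                      lon = c(0, 0.5, 1), lat = 0, country = "X",
                      city_ref = c("A", "B", "C"), stringsAsFactors = FALSE)
  edges <- data.frame(from_node = c("nA", "nB"), to_node = c("nB", "nC"),
                      travel_time_h = c(1, 1), stringsAsFactors = FALSE)
  list(cities = cities, network = urban_network(nodes, edges))
}

make_events <- function(lon, lat, fatalities = 0,
                        category = "violence_against_civilians",
                        date = "2010-06-15") {
  n <- length(lon)
  data.frame(event_id = sprintf("e%04d", seq_len(n)), date = date,
             category = category, lon = lon, lat = lat,
             fatalities = fatalities, stringsAsFactors = FALSE)
}

# random connected network: spanning tree plus extra edges, a random subset
# of nodes promoted to cities.  Continuous weights make exact ties
# measure-zero.
random_graph_fixture <- function(n_nodes, n_cities, seed,
                                 p_border = 0.2) {
  set.seed(seed)
  stopifnot(n_cities <= n_nodes)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  parent <- c(NA, vapply(2:n_nodes, function(i) sample.int(i - 1L, 1),
                         integer(1)))
  edges <- data.frame(from_node = ids[parent[-1]], to_node = ids[-1],
                      stringsAsFactors = FALSE)
  n_extra <- sample.int(max(1L, n_nodes %/% 2L), 1)
  for (k in seq_len(n_extra)) {
    ij <- sample.int(n_nodes, 2)
    key <- paste(sort(ids[ij]), collapse = "-")
    existing <- paste(pmin(edges$from_node, edges$to_node),
                      pmax(edges$from_node, edges$to_node), sep = "-")
    if (!(key %in% existing))
      edges <- rbind(edges, data.frame(from_node = ids[ij[1]],
                                       to_node = ids[ij[2]],
                                       stringsAsFactors = FALSE))
  }
  edges$travel_time_h <- runif(nrow(edges), 0.5, 5)
  city_nodes <- sort(sample(ids, n_cities))
  kind <- ifelse(ids %in% city_nodes, "city", "junction")
  country <- sample(c("A", "B"), n_nodes, replace = TRUE,
                    prob = c(1 - p_border, p_border))
  nodes <- data.frame(node_id = ids, kind = kind,
                      lon = runif(n_nodes, -5, 5),
                      lat = runif(n_nodes, -5, 5), country = country,
                      city_ref = ifelse(kind == "city", sub("^n", "c", ids),
                                        NA_character_),
                      stringsAsFactors = FALSE)
  cities <- make_cities(sub("^n", "c", city_nodes),
                        lon = nodes$lon[match(city_nodes, nodes$node_id)],
                        lat = nodes$lat[match(city_nodes, nodes$node_id)],
                        population = sample(1:1000, n_cities, replace = TRUE),
                        country = nodes$country[match(city_nodes,
                                                      nodes$node_id)])
  list(cities = cities, network = urban_network(nodes, edges))
}

# Brute-force gravity-flow centrality oracle, independent of the package's
# Dijkstra: igraph enumerates every shortest path of each city pair; the
# lexicographically smallest node-id sequence is selected and its flow
# accumulated on intermediate cities.
oracle_centrality <- function(network, cities, params = gravity_params(),
                              include_endpoints = FALSE) {
  w <- network$edges$travel_time_h +
    params$border_penalty_h * as.numeric(network$edges$crosses_border)
  g <- igraph::graph_from_data_frame(
    data.frame(from = network$edges$from_node, to = network$edges$to_node),
    directed = FALSE, vertices = network$nodes$node_id)
  cent <- setNames(numeric(nrow(cities)), cities$city_id)
  node_of <- setNames(network$nodes$node_id,
                      ifelse(network$nodes$kind == "city",
                             network$nodes$city_ref, NA))
  city_of <- setNames(ifelse(network$nodes$kind == "city",
                             network$nodes$city_ref, NA),
                      network$nodes$node_id)
  dmat <- igraph::distances(g, weights = w)
  for (i in seq_len(nrow(cities) - 1)) {
    for (j in (i + 1):nrow(cities)) {
      no <- node_of[[cities$city_id[i]]]
      nd <- node_of[[cities$city_id[j]]]
      t_od <- dmat[no, nd]
      if (!is.finite(t_od)) next
      asp <- igraph::all_shortest_paths(g, from = no, to = nd, weights = w)
      seqs <- lapply(asp$vpaths, function(p) names(p))
      keys <- vapply(seqs, paste, "", collapse = "\r")
      route <- seqs[[order(keys, method = "radix")[1]]]
      flow <- cities$population[i] * cities$population[j] /
        t_od^params$gamma
      mid <- route[-c(1, length(route))]
      members <- stats::na.omit(city_of[mid])
      for (cc in members) cent[[cc]] <- cent[[cc]] + flow
      if (include_endpoints) {
        cent[[cities$city_id[i]]] <- cent[[cities$city_id[i]]] + flow
        cent[[cities$city_id[j]]] <- cent[[cities$city_id[j]]] + flow
      }
    }
  }
  cent
}

# small synthetic config for fast end-to-end tests
small_config <- function(...) {
  synthetic_config(n_cities = 300, region_size_km = 3000, ...)
}
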