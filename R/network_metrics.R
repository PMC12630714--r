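#' @title Isolation and centrality metrics on the urban network
#' @description A city's isolation is measured two ways: by its degree (the
#'   number of highway edges meeting its node) and by a gravity-flow
#'   centrality, a flow-weighted betweenness.  The flow between an origin
#'   and destination city is \eqn{F_{o,d} = P_o P_d / N_{o,d}^\gamma} where
#'   \eqn{N_{o,d}} is the travel time of the fastest route (each
#'   border-crossing edge is surcharged a fixed penalty), and the centrality
#'   of city j accumulates the flow of every city pair whose fastest route
#'   passes through j.
#' @name network_metrics
NULL

#' Gravity-model parameters
#'
#' @param gamma travel-time decay exponent \eqn{\gamma \ge 0}; the default
#'   2.8 reflects high travel frictions on sparse continental road networks.
#' @param border_penalty_h hours added to each border-crossing edge
#'   (default 2).
#' @return list of class `gravity_params`.
#' @export
gravity_params <- function(gamma = 2.8, border_penalty_h = 2.0) {
  if (!is.finite(gamma) || gamma < 0)
    .stopf("gamma must be a finite number >= 0")
  if (!is.finite(border_penalty_h) || border_penalty_h < 0)
    .stopf("border_penalty_h must be a finite number >= 0")
  structure(list(gamma = gamma, border_penalty_h = border_penalty_h),
            class = "gravity_params")
}

#' City degrees on the urban network
#'
#' The degree D_j of a city is the number of highway edges incident to its
#' node.  Edges terminating at junctions count; parallel edges count
#' separately (D counts highways, not distinct neighbours).
#'
#' @param network an [urban_network()].
#' @return named integer vector, one entry per city node, names = city_id.
#' @export
compute_degree <- function(network) {
  stopifnot(inherits(network, "urban_network"))
  nodes <- network$nodes
  inc <- table(c(network$edges$from_node, network$edges$to_node))
  deg <- rep(0L, nrow(nodes))
  names(deg) <- nodes$node_id
  deg[names(inc)] <- as.integer(inc)
  city <- nodes$kind == "city"
  setNames(deg[city], nodes$city_ref[city])
}

#' Degree-based isolation class
#'
#' High isolation: D <= 2; medium: 3 <= D <= 5; low: D >= 6.  The
#' thresholds split a continental system into groups of roughly equal total
#' population.
#'
#' @param degree integer vector of city degrees (>= 0).
#' @return character vector in `c("high", "medium", "low")`, same names.
#' @export
classify_isolation <- function(degree) {
  if (any(!is.finite(degree) | degree < 0))
    .stopf("degree must be >= 0")
  out <- ifelse(degree <= 2, "high", ifelse(degree <= 5, "medium", "low"))
  setNames(out, names(degree))
}

#' Gravity-model flow between two cities
#'
#' \eqn{F_{o,d} = P_o P_d / N_{o,d}^\gamma}.
#'
#' @param pop_o,pop_d origin and destination populations (persons, >= 1).
#' @param travel_time route travel time in hours (> 0).
#' @param params a [gravity_params()].
#' @return dimensionless flow (vectorised).
#' @export
gravity_flow <- function(pop_o, pop_d, travel_time,
                         params = gravity_params()) {
  if (any(travel_time <= 0)) .stopf("travel_time must be > 0")
  if (any(pop_o < 1) || any(pop_d < 1)) .stopf("populations must be >= 1")
  pop_o * pop_d / travel_time^params$gamma
}

# nodes sorted by node_id in byte order so that integer index order equals
# lexicographic id order (the deterministic tie rule for equal-cost routes)
.network_index <- function(network, params) {
  nodes <- network$nodes
  ord <- order(nodes$node_id, method = "radix")
  nodes <- nodes[ord, , drop = FALSE]
  idx <- setNames(seq_len(nrow(nodes)) - 1L, nodes$node_id)  # 0-based
  e <- network$edges
  w <- e$travel_time_h + params$border_penalty_h * as.numeric(e$crosses_border)
  list(nodes = nodes, idx = idx,
       from = unname(idx[e$from_node]), to = unname(idx[e$to_node]),
       weight = w)
}

#' All-pairs fastest routes between cities
#'
#' Single-source shortest paths by total travel time, with
#' `border_penalty_h` added to every border-crossing edge.  Ties between
#' equal-time routes are broken deterministically in favour of the
#' lexicographically smallest node-id sequence.  Unreachable pairs are
#' reported and carry an infinite time.
#'
#' @param network an [urban_network()].
#' @param params a [gravity_params()].
#' @return list with `times` (city x city matrix of route hours, dimnames =
#'   city_id), `paths` (nested list: `paths[[o]][[d]]` is the node-id
#'   sequence of the fastest o -> d route), and `unreachable` (data.frame of
#'   skipped pairs).  Intended for moderate n; centrality does not
#'   materialise paths.
#' @export
fastest_paths <- function(network, params = gravity_params()) {
  nx <- .network_index(network, params)
  city_rows <- which(nx$nodes$kind == "city")
  city_ids <- nx$nodes$city_ref[city_rows]
  n <- nrow(nx$nodes)
  nc <- length(city_rows)
  times <- matrix(Inf, nc, nc, dimnames = list(city_ids, city_ids))
  diag(times) <- 0
  paths <- setNames(vector("list", nc), city_ids)
  for (i in seq_len(nc)) {
    res <- .cpp_dijkstra(n, nx$from, nx$to, nx$weight, city_rows[i] - 1L)
    times[i, ] <- res$dist[city_rows]
    pred <- res$pred
    pl <- setNames(vector("list", nc), city_ids)
    for (j in seq_len(nc)) {
      if (!is.finite(times[i, j])) next
      node <- city_rows[j] - 1L
      seqr <- node
      while (pred[node + 1L] >= 0L) {
        node <- pred[node + 1L]
        seqr <- c(node, seqr)
      }
      pl[[j]] <- nx$nodes$node_id[seqr + 1L]
    }
    paths[[i]] <- pl
  }
  unreach <- which(!is.finite(times), arr.ind = TRUE)
  unreachable <- data.frame(from = city_ids[unreach[, 1]],
                            to = city_ids[unreach[, 2]],
                            stringsAsFactors = FALSE)
  if (nrow(unreachable))
    message(sprintf("fastest_paths: %d unreachable city pair(s) skipped",
                    nrow(unreachable) / 2L))
  list(times = times, paths = paths, unreachable = unreachable)
}

#' Gravity-flow centrality of cities
#'
#' For every unordered pair of distinct cities the gravity flow
#' \eqn{F_{o,d}} is routed along the fastest path and accumulated on the
#' cities the route passes through: \eqn{C_j = \sum_{\{o,d\}} F_{o,d}
#' H_{o,d}(j)}.  By default the route's endpoints do not count
#' (`include_endpoints = FALSE`): C_j measures journeys passing *through*
#' j, the standard intermediacy convention.  Junction nodes accumulate
#' nothing; unreachable pairs contribute zero and are counted.
#'
#' @param network an [urban_network()].
#' @param cities city table supplying populations; every `city_id` must
#'   appear as a city node of the network.
#' @param params a [gravity_params()].
#' @param include_endpoints if `TRUE`, each pair's flow is also credited to
#'   its own endpoints.
#' @return named numeric vector city_id -> centrality, in `cities` row
#'   order, with attribute `n_unreachable_pairs`.
#' @export
compute_centrality <- function(network, cities, params = gravity_params(),
                               include_endpoints = FALSE) {
  cities <- validate_cities(cities)
  nx <- .network_index(network, params)
  # map city_id -> node row (city nodes only)
  city_rows <- match(cities$city_id,
                     ifelse(nx$nodes$kind == "city", nx$nodes$city_ref, NA))
  if (anyNA(city_rows))
    .stopf("city missing from network: %s",
           paste(head(cities$city_id[is.na(city_rows)], 5), collapse = ", "))
  res <- .cpp_centrality(nrow(nx$nodes), nx$from, nx$to, nx$weight,
                         city_rows - 1L, cities$population, params$gamma,
                         include_endpoints)
  out <- setNames(res$centrality, cities$city_id)
  attr(out, "n_unreachable_pairs") <- res$n_unreachable_pairs
  out
}

#' Centrality quartile classes
#'
#' Cities are split into four classes of (as near as possible) equal size by
#' ranking centrality; ties and boundary cases are resolved by city_id byte
#' order, so the partition is deterministic.  Class `Q1_lowest` holds the
#' 25\% of cities with the lowest centrality, `Q4_highest` the top 25\%.
#'
#' @param centrality named numeric vector (names = city_id).
#' @return named character vector in
#'   `c("Q1_lowest","Q2","Q3","Q4_highest")`.
#' @export
classify_centrality_quartiles <- function(centrality) {
  n <- length(centrality)
  if (n < 4) .stopf("need at least 4 cities for quartile classes, got %d", n)
  if (is.null(names(centrality)) || anyDuplicated(names(centrality)))
    .stopf("centrality must be named by unique city_id")
  ord <- order(centrality, names(centrality), method = "radix")
  grp <- ceiling(4 * seq_len(n) / n)
  labels <- c("Q1_lowest", "Q2", "Q3", "Q4_highest")
  out <- character(n)
  out[ord] <- labels[grp]
  setNames(out, names(centrality))
}

#' Full per-city network metric table
#'
#' Convenience wrapper combining [compute_degree()],
#' [classify_isolation()], [compute_centrality()] and
#' [classify_centrality_quartiles()].
#'
#' @inheritParams compute_centrality
#' @return data.frame: `city_id`, `degree`, `isolation_class`, `centrality`,
#'   `centrality_class`, in `cities` row order.
#' @export
city_network_metrics <- function(network, cities,
                                 params = gravity_params(),
                                 include_endpoints = FALSE) {
  cities <- validate_cities(cities)
  deg <- compute_degree(network)
  if (!all(cities$city_id %in% names(deg)))
    .stopf("city missing from network: %s",
           paste(head(setdiff(cities$city_id, names(deg)), 5),
                 collapse = ", "))
  cent <- compute_centrality(network, cities, params, include_endpoints)
  data.frame(city_id = cities$city_id,
             degree = unname(deg[cities$city_id]),
             isolation_class = unname(classify_isolation(deg)[cities$city_id]),
             centrality = unname(cent[cities$city_id]),
             centrality_class =
               unname(classify_centrality_quartiles(cent)[cities$city_id]),
             stringsAsFactors = FALSE)
}
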