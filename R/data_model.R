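#' @title Domain tables: cities, networks, violent events
#' @description Readers, writers and validators for the three inputs of the
#'   pipeline: a city table (id, name, coordinates, country, population), an
#'   urban road network (nodes that are cities or junctions, edges carrying
#'   travel times in hours), and a table of violent events (date, category,
#'   coordinates, fatalities).  All coordinates are WGS84 decimal degrees;
#'   distances are km and travel times hours throughout the package.
#' @name data_model
NULL

.err <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "urbiso_error", "error")))
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    .err("urbiso_schema_error", "%s: missing required column(s): %s",
         what, paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Validate a city table
#'
#' Checks the invariants of the city schema: unique `city_id`, WGS84
#' coordinate ranges, and integer populations of at least 1.
#'
#' @param cities data.frame with columns `city_id`, `name`, `lon`, `lat`,
#'   `country`, `population`.
#' @return The validated data.frame (row order preserved), invisibly
#'   coerced: ids/names/countries as character, population as numeric whole
#'   numbers.
#' @export
validate_cities <- function(cities) {
  .require_columns(cities, c("city_id", "name", "lon", "lat", "country",
                             "population"), "cities")
  cities$city_id <- as.character(cities$city_id)
  cities$name <- as.character(cities$name)
  cities$country <- as.character(cities$country)
  cities$lon <- as.numeric(cities$lon)
  cities$lat <- as.numeric(cities$lat)
  cities$population <- as.numeric(cities$population)
  if (anyDuplicated(cities$city_id))
    .err("urbiso_validation_error", "cities: duplicate city_id: %s",
         paste(unique(cities$city_id[duplicated(cities$city_id)]),
               collapse = ", "))
  .check_lonlat(cities$lon, cities$lat, "city coordinate")
  bad <- !is.finite(cities$population) | cities$population < 1 |
    cities$population != floor(cities$population)
  if (any(bad))
    .err("urbiso_validation_error",
         "cities: population must be an integer >= 1 (offending city_id: %s)",
         paste(head(cities$city_id[bad], 5), collapse = ", "))
  cities
}

#' Read a city table from CSV or GeoJSON
#'
#' @param path file path.
#' @param format `"csv"` (native schema
#'   `city_id,name,lon,lat,country,population`) or `"geojson"` (point
#'   features whose properties carry the non-coordinate fields).
#' @return validated city data.frame.
#' @export
read_cities <- function(path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  if (!file.exists(path))
    .err("urbiso_io_error", "file not found: %s", path)
  if (format == "csv") {
    df <- .read_csv(path)
  } else {
    df <- .read_geojson_points(path,
                               c("city_id", "name", "country", "population"))
  }
  validate_cities(df)
}

#' Write a city table to the native CSV schema
#' @param cities validated city data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cities <- function(cities, path, ...) {
  cities <- validate_cities(cities)
  .write_csv_precise(cities[, c("city_id", "name", "lon", "lat", "country",
                                "population")], path, ...)
}

# -- network ----------------------------------------------------------------

#' Construct and validate an urban road network
#'
#' Nodes are cities or road junctions; edges are undirected highway segments
#' with a positive travel time in hours.  `crosses_border` is derived from
#' endpoint countries when not supplied.
#'
#' @param nodes data.frame: `node_id`, `kind` ("city"/"junction"), `lon`,
#'   `lat`, `country`, `city_ref` (city_id for city nodes, NA otherwise).
#' @param edges data.frame: `from_node`, `to_node`, `travel_time_h`, and
#'   optionally `crosses_border`.
#' @return object of class `urban_network`: a list with validated `nodes`
#'   and `edges`.
#' @export
urban_network <- function(nodes, edges) {
  .require_columns(nodes, c("node_id", "kind", "lon", "lat", "country"),
                   "nodes")
  .require_columns(edges, c("from_node", "to_node", "travel_time_h"),
                   "edges")
  nodes$node_id <- as.character(nodes$node_id)
  nodes$kind <- as.character(nodes$kind)
  nodes$country <- as.character(nodes$country)
  nodes$lon <- as.numeric(nodes$lon)
  nodes$lat <- as.numeric(nodes$lat)
  if (is.null(nodes$city_ref)) nodes$city_ref <- NA_character_
  nodes$city_ref <- as.character(nodes$city_ref)
  nodes$city_ref[!is.na(nodes$city_ref) & nodes$city_ref == ""] <-
    NA_character_
  if (anyDuplicated(nodes$node_id))
    .err("urbiso_validation_error", "network: duplicate node_id")
  if (!all(nodes$kind %in% c("city", "junction")))
    .err("urbiso_validation_error",
         "network: node kind must be 'city' or 'junction'")
  .check_lonlat(nodes$lon, nodes$lat, "node coordinate")
  is_city <- nodes$kind == "city"
  if (any(is_city & (is.na(nodes$city_ref) | nodes$city_ref == "")))
    .err("urbiso_validation_error", "network: city node without city_ref")
  if (any(!is_city & !is.na(nodes$city_ref) & nodes$city_ref != ""))
    .err("urbiso_validation_error", "network: junction node with a city_ref")

  edges$from_node <- as.character(edges$from_node)
  edges$to_node <- as.character(edges$to_node)
  edges$travel_time_h <- as.numeric(edges$travel_time_h)
  dangling <- !(edges$from_node %in% nodes$node_id) |
    !(edges$to_node %in% nodes$node_id)
  if (any(dangling))
    .err("urbiso_referential_error",
         "network: edge(s) with unknown endpoint: %s",
         paste(head(paste0(edges$from_node[dangling], "--",
                           edges$to_node[dangling]), 5), collapse = ", "))
  if (any(edges$from_node == edges$to_node))
    .err("urbiso_validation_error", "network: self-loop edge not allowed")
  if (any(!is.finite(edges$travel_time_h) | edges$travel_time_h <= 0))
    .err("urbiso_validation_error",
         "network: travel_time_h must be finite and > 0")
  ctry <- setNames(nodes$country, nodes$node_id)
  derived <- ctry[edges$from_node] != ctry[edges$to_node]
  if (is.null(edges$crosses_border)) {
    edges$crosses_border <- unname(derived)
  } else {
    edges$crosses_border <- as.logical(edges$crosses_border)
    edges$crosses_border[is.na(edges$crosses_border)] <-
      derived[is.na(edges$crosses_border)]
  }
  structure(list(nodes = nodes,
                 edges = edges[, c("from_node", "to_node", "travel_time_h",
                                   "crosses_border")]),
            class = "urban_network")
}

#' @export
print.urban_network <- function(x, ...) {
  cat(sprintf("<urban_network> %d nodes (%d cities, %d junctions), %d edges\n",
              nrow(x$nodes), sum(x$nodes$kind == "city"),
              sum(x$nodes$kind == "junction"), nrow(x$edges)))
  invisible(x)
}

#' Read an urban network from node and edge CSV files
#' @param nodes_path CSV with `node_id,kind,lon,lat,country,city_ref`.
#' @param edges_path CSV with `from_node,to_node,travel_time_h[,crosses_border]`.
#' @return an [urban_network()] object.
#' @export
read_network <- function(nodes_path, edges_path) {
  for (p in c(nodes_path, edges_path))
    if (!file.exists(p)) .err("urbiso_io_error", "file not found: %s", p)
  urban_network(.read_csv(nodes_path),
                .read_csv(edges_path))
}

#' Write an urban network to node and edge CSV files
#' @param network an [urban_network()] object.
#' @param nodes_path,edges_path output paths.
#' @return invisibly, the two paths.
#' @export
write_network <- function(network, nodes_path, edges_path, ...) {
  stopifnot(inherits(network, "urban_network"))
  .write_csv_precise(network$nodes, nodes_path, ...)
  .write_csv_precise(network$edges, edges_path, ...)
  invisible(c(nodes_path, edges_path))
}

# -- events -----------------------------------------------------------------

.ACLED_TYPE_MAP <- c(
  "Battles"                    = "battle",
  "Violence against civilians" = "violence_against_civilians",
  "Explosions/Remote violence" = "explosion_remote",
  "Strategic developments"     = "strategic_development",
  "Riots"                      = "riot",
  "Protests"                   = "protest")

#' Validate an event table
#'
#' @param events data.frame with `event_id`, `date`, `category`, `lon`,
#'   `lat`, `fatalities`.
#' @return validated data.frame; `date` coerced to `Date`, `fatalities` to
#'   non-negative whole numbers, `category` restricted to the six ACLED
#'   classes.
#' @export
validate_events <- function(events) {
  .require_columns(events, c("event_id", "date", "category", "lon", "lat",
                             "fatalities"), "events")
  events$event_id <- as.character(events$event_id)
  events$category <- as.character(events$category)
  events$date <- as.Date(events$date)
  events$lon <- as.numeric(events$lon)
  events$lat <- as.numeric(events$lat)
  events$fatalities <- as.numeric(events$fatalities)
  if (anyDuplicated(events$event_id))
    .err("urbiso_validation_error", "events: duplicate event_id")
  if (any(is.na(events$date)))
    .err("urbiso_validation_error", "events: unparseable date")
  if (!all(events$category %in% .EVENT_CATEGORIES))
    .err("urbiso_validation_error", "events: unknown category: %s",
         paste(unique(setdiff(events$category, .EVENT_CATEGORIES)),
               collapse = ", "))
  .check_lonlat(events$lon, events$lat, "event coordinate")
  bad <- !is.finite(events$fatalities) | events$fatalities < 0 |
    events$fatalities != floor(events$fatalities)
  if (any(bad))
    .err("urbiso_validation_error",
         "events: fatalities must be an integer >= 0")
  events
}

#' Read a violent-event table
#'
#' The `"native"` dialect expects
#' `event_id,date,category,lon,lat,fatalities` with ISO-8601 dates and the
#' six-class category enum.  The `"acled"` dialect maps a standard ACLED
#' export (`event_id_cnty`/`data_id`, `event_date`, `event_type`,
#' `latitude`, `longitude`, `fatalities`) onto the native schema.  Rows that
#' violate an invariant (unknown event type, negative fatalities,
#' out-of-range coordinates, unparseable date) are rejected per row; the
#' rejection count is attached as attribute `n_rejected` and reported via a
#' message.
#'
#' @param path CSV or GeoJSON file path.
#' @param dialect `"native"` or `"acled"`.
#' @param format `"csv"` or `"geojson"` (native dialect only).
#' @return validated event data.frame with attribute `n_rejected`.
#' @export
read_events <- function(path, dialect = c("native", "acled"),
                        format = c("csv", "geojson")) {
  dialect <- match.arg(dialect)
  format <- match.arg(format)
  if (!file.exists(path))
    .err("urbiso_io_error", "file not found: %s", path)
  if (format == "geojson") {
    df <- .read_geojson_points(path, c("event_id", "date", "category",
                                       "fatalities"))
  } else {
    df <- .read_csv(path)
  }
  if (dialect == "acled") {
    id_col <- intersect(c("event_id_cnty", "data_id", "event_id"), names(df))
    .require_columns(df, c("event_date", "event_type", "latitude",
                           "longitude", "fatalities"), "acled events")
    if (!length(id_col))
      .err("urbiso_schema_error",
           "acled events: no event id column (event_id_cnty or data_id)")
    df <- data.frame(event_id = as.character(df[[id_col[1]]]),
                     date = df$event_date,
                     category = unname(.ACLED_TYPE_MAP[df$event_type]),
                     lon = df$longitude, lat = df$latitude,
                     fatalities = df$fatalities,
                     stringsAsFactors = FALSE)
  }
  .require_columns(df, c("event_id", "date", "category", "lon", "lat",
                         "fatalities"), "events")
  # per-row rejection of malformed events, with a counted summary
  date <- as.Date(as.character(df$date), optional = TRUE)
  fat <- suppressWarnings(as.numeric(df$fatalities))
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  ok <- !is.na(date) & df$category %in% .EVENT_CATEGORIES &
    is.finite(fat) & fat >= 0 & fat == floor(fat) &
    is.finite(lon) & is.finite(lat) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  ok[is.na(ok)] <- FALSE
  n_rejected <- sum(!ok)
  if (n_rejected)
    message(sprintf("read_events: rejected %d malformed row(s) of %d",
                    n_rejected, nrow(df)))
  out <- validate_events(df[ok, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write an event table to the native CSV schema
#' @param events validated event data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, ...) {
  events <- validate_events(events)
  out <- events[, c("event_id", "date", "category", "lon", "lat",
                    "fatalities")]
  out$date <- format(out$date, "%Y-%m-%d")
  .write_csv_precise(out, path, ...)
}

# -- shared IO helpers ------------------------------------------------------

# CSV writer that round-trips doubles exactly: numeric columns are printed
# with 17 significant digits (enough to recover the same IEEE double).
# An optional "# ..." provenance line precedes the header; the package's
# readers skip such lines via comment.char.
.write_csv_precise <- function(df, path, header_comment = NULL) {
  for (nm in names(df)) {
    if (is.double(df[[nm]]))
      df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  write.csv(df, con, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

.read_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

# minimal GeoJSON point-feature reader (coordinates + properties)
.read_geojson_points <- function(path, property_cols) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else
    .err("urbiso_schema_error", "%s: not a GeoJSON FeatureCollection", path)
  rows <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "Point"))
      .err("urbiso_schema_error", "geojson: only Point features supported")
    props <- f$properties
    c(list(lon = f$geometry$coordinates[[1]],
           lat = f$geometry$coordinates[[2]]),
      lapply(setNames(property_cols, property_cols),
             function(p) props[[p]] %||% NA))
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  df
}
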