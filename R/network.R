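#' @name network
#' @title Supply network representation
#'
#' @description A `vax_network` describes the four-tier supply chain:
#' locations (central, regional, district, clinic) holding cold-storage
#' devices, and routes along which a transport device moves vials at a
#' fixed shipping frequency. Routes are either `delivery` (the origin
#' pushes, possibly along a multi-stop loop) or `collection` (the
#' destination fetches when it reaches its reorder point). The object is a
#' list with data frames `locations`, `devices`, `routes` and a list
#' `stops` (ordered destination ids per route).
NULL

storage_kinds <- c(cold_room = "refrigerated", refrigerator = "refrigerated",
                   freezer = "frozen")
transport_kinds <- c("cold_truck", "four_by_four", "cold_box", "vaccine_carrier")
location_levels <- c("central", "regional", "district", "clinic")

#' Load and validate a supply network
#'
#' @param path Path to a JSON or YAML network description with top-level
#'   keys `locations` (each with `id`, `level`, optional `devices`,
#'   optional `share` demand weight for clinics, optional
#'   `reorder_point_fraction`/`buffer_fraction`) and `routes` (each with
#'   `id`, `origin`, `stops`, `vehicle` (`kind`, `capacity_cm3`),
#'   `trips_per_year`, `mode`, `loss_prob`).
#' @return A validated `vax_network`.
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  network_from_list(raw)
}

#' Build a network object from an R list
#'
#' Same schema as [load_network()]; used by the synthetic-network
#' generator and by tests that construct networks in code.
#'
#' @param raw A list with `locations` and `routes`.
#' @return A validated `vax_network`.
#' @export
network_from_list <- function(raw) {
  locs <- raw$locations
  if (is.null(locs) || !length(locs)) stop("schema error: no locations")
  loc_df <- data.frame(
    id = vapply(locs, function(l) as.character(l$id), ""),
    level = vapply(locs, function(l) as.character(l$level), ""),
    share = vapply(locs, function(l) as.numeric(l$share %||% NA_real_), 0),
    reorder_point_fraction = vapply(
      locs, function(l) as.numeric(l$reorder_point_fraction %||% 0.25), 0),
    buffer_fraction = vapply(
      locs, function(l) as.numeric(l$buffer_fraction %||% 0.25), 0),
    stringsAsFactors = FALSE
  )
  dev_rows <- lapply(locs, function(l) {
    if (!length(l$devices)) return(NULL)
    data.frame(
      location_id = as.character(l$id),
      device_id = vapply(l$devices, function(d) as.character(d$id), ""),
      kind = vapply(l$devices, function(d) as.character(d$kind), ""),
      capacity_cm3 = vapply(l$devices, function(d) as.numeric(d$capacity_cm3), 0),
      stringsAsFactors = FALSE
    )
  })
  dev_df <- do.call(rbind, dev_rows)
  if (is.null(dev_df)) {
    dev_df <- data.frame(location_id = character(), device_id = character(),
                         kind = character(), capacity_cm3 = numeric(),
                         stringsAsFactors = FALSE)
  }
  routes <- raw$routes %||% list()
  route_df <- data.frame(
    route_id = vapply(routes, function(r) as.character(r$id), ""),
    origin = vapply(routes, function(r) as.character(r$origin), ""),
    vehicle_kind = vapply(routes, function(r) as.character(r$vehicle$kind), ""),
    vehicle_capacity_cm3 = vapply(
      routes, function(r) as.numeric(r$vehicle$capacity_cm3), 0),
    trips_per_year = vapply(
      routes, function(r) as.numeric(r$trips_per_year %||% 12), 0),
    mode = vapply(routes, function(r) as.character(r$mode %||% "collection"), ""),
    loss_prob = vapply(routes, function(r) as.numeric(r$loss_prob %||% 0), 0),
    stringsAsFactors = FALSE
  )
  stops <- lapply(routes, function(r) vapply(r$stops, as.character, ""))
  names(stops) <- route_df$route_id
  net <- structure(
    list(locations = loc_df, devices = dev_df, routes = route_df,
         stops = stops),
    class = "vax_network"
  )
  validate_network(net)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a supply network
#'
#' Checks device kinds, levels, route references and -- critically -- that
#' every non-central location is reachable from the central store along the
#' configured routes (unreachable locations are a topology error).
#'
#' @param net A `vax_network`.
#' @return The validated network, or an error.
#' @export
validate_network <- function(net) {
  locs <- net$locations
  if (anyDuplicated(locs$id)) stop("schema error: duplicate location ids")
  if (!all(locs$level %in% location_levels)) {
    stop("schema error: unknown location level")
  }
  if (sum(locs$level == "central") != 1L) {
    stop("topology error: exactly one central store required")
  }
  if (nrow(net$devices)) {
    if (!all(net$devices$kind %in% names(storage_kinds))) {
      stop("schema error: unknown storage device kind")
    }
    if (any(net$devices$capacity_cm3 <= 0)) {
      stop("validation error: device net capacity must be > 0")
    }
    if (!all(net$devices$location_id %in% locs$id)) {
      stop("topology error: device at unknown location")
    }
  }
  rt <- net$routes
  if (nrow(rt)) {
    if (!all(rt$vehicle_kind %in% transport_kinds)) {
      stop("schema error: unknown transport device kind")
    }
    if (any(rt$vehicle_capacity_cm3 <= 0)) {
      stop("validation error: vehicle capacity must be > 0")
    }
    all_stops <- unlist(net$stops, use.names = FALSE)
    bad <- setdiff(c(rt$origin, all_stops), locs$id)
    if (length(bad)) {
      stop("topology error: route references unknown location(s): ",
           paste(bad, collapse = ", "))
    }
  }
  # reachability from the central store
  reach <- locs$id[locs$level == "central"]
  repeat {
    new <- unlist(net$stops[net$routes$origin %in% reach], use.names = FALSE)
    new <- setdiff(new, reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  orphan <- setdiff(locs$id, reach)
  if (length(orphan)) {
    stop("topology error: location(s) unreachable from central store: ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  }
  net
}

#' Total net storage capacity of a location for one temperature class
#'
#' Sums the net capacities of the location's matching devices. A store with
#' no cold storage (a legal degenerate case) has capacity 0.
#'
#' @param net A `vax_network`.
#' @param location_id Location id.
#' @param temperature_class `"refrigerated"` (2-8 degrees C: cold rooms and
#'   refrigerators) or `"frozen"` (-15 to -25 degrees C: freezers).
#' @return Capacity in cm^3.
#' @export
storage_capacity <- function(net, location_id,
                             temperature_class = c("refrigerated", "frozen")) {
  temperature_class <- match.arg(temperature_class)
  if (!location_id %in% net$locations$id) {
    stop("unknown location: ", location_id)
  }
  d <- net$devices
  sel <- d$location_id == location_id &
    storage_kinds[d$kind] == temperature_class
  sum(d$capacity_cm3[sel])
}

#' Write a network to JSON
#'
#' @param net A `vax_network`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  locs <- lapply(seq_len(nrow(net$locations)), function(i) {
    l <- net$locations[i, ]
    dv <- net$devices[net$devices$location_id == l$id, , drop = FALSE]
    out <- list(id = l$id, level = l$level,
                reorder_point_fraction = l$reorder_point_fraction,
                buffer_fraction = l$buffer_fraction)
    if (!is.na(l$share)) out$share <- l$share
    out$devices <- lapply(seq_len(nrow(dv)), function(j) {
      list(id = dv$device_id[j], kind = dv$kind[j],
           capacity_cm3 = dv$capacity_cm3[j])
    })
    out
  })
  rts <- lapply(seq_len(nrow(net$routes)), function(i) {
    r <- net$routes[i, ]
    list(id = r$route_id, origin = r$origin,
         stops = as.list(net$stops[[r$route_id]]),
         vehicle = list(kind = r$vehicle_kind,
                        capacity_cm3 = r$vehicle_capacity_cm3),
         trips_per_year = r$trips_per_year, mode = r$mode,
         loss_prob = r$loss_prob)
  })
  jsonlite::write_json(list(locations = locs, routes = rts), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.vax_network <- function(x, ...) {
  lv <- table(factor(x$locations$level, levels = location_levels))
  cat("<vax_network> ", nrow(x$locations), " locations (",
      paste(sprintf("%s: %d", names(lv), lv), collapse = ", "), "), ",
      nrow(x$routes), " routes, ", nrow(x$devices),
      " storage devices\n", sep = "")
  invisible(x)
}
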