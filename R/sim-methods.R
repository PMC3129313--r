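#' @export
print.vaxchain_sim <- function(x, ...) {
  av <- x$summary$availability
  cat("<vaxchain_sim> ", length(x$replications), " replication(s), ",
      length(x$clinic_ids), " clinics, measles presentation: ",
      active_presentations(x$catalog)$doses_per_vial[
        active_presentations(x$catalog)$antigen == "M"],
      "-dose vial\n", sep = "")
  cat("vaccine availability (mean over replications):\n")
  print(data.frame(antigen = av$antigen,
                   availability = sprintf("%.0f%%", 100 * av$availability)),
        row.names = FALSE)
  invisible(x)
}

#' Summarize a simulation
#'
#' @param object A `vaxchain_sim`.
#' @param ... Unused.
#' @return The summary list (availability, dose accounts, transport and
#'   storage utilization, conservation ledger), invisibly; printed in the
#'   style of the published tables (whole percent).
#' @export
summary.vaxchain_sim <- function(object, ...) {
  s <- object$summary
  cat("Vaccine availability (percent of arriving patients served):\n")
  av <- s$availability
  print(data.frame(antigen = av$antigen,
                   availability = round(100 * av$availability),
                   sd = round(100 * av$sd, 1)), row.names = FALSE)
  cat("\nDose accounts (mean per replication):\n")
  d <- s$doses
  print(data.frame(antigen = d$antigen, arrivals = round(d$arrivals),
                   administered = round(d$administered),
                   missed = round(d$missed),
                   open_vial_waste = round(d$open_vial_waste)),
        row.names = FALSE)
  cat("\nTransport utilization by origin level (per-route means):\n")
  tr <- s$transport
  print(data.frame(level = tr$origin_level, routes = tr$n_routes,
                   requested_median = sprintf("%.0f%%",
                                              100 * tr$requested_median),
                   requested_range = sprintf("%.0f-%.0f%%",
                                             100 * tr$requested_min,
                                             100 * tr$requested_max),
                   actual_median = sprintf("%.0f%%",
                                           100 * tr$actual_median)),
        row.names = FALSE)
  cat("\nStorage utilization by level (refrigerated, time-mean per store):\n")
  st <- s$storage
  print(data.frame(level = st$level, stores = st$n_locations,
                   median = sprintf("%.0f%%", 100 * st$refrigerated_median),
                   range = sprintf("%.0f-%.0f%%", 100 * st$refrigerated_min,
                                   100 * st$refrigerated_max)),
        row.names = FALSE)
  invisible(s)
}

#' Plot utilization histograms
#'
#' Frequency histograms of per-route demand-requested transport
#' utilization (by origin level) and per-store refrigerated storage
#' utilization (by level), the layout used for the published figures.
#'
#' @param x A `vaxchain_sim`.
#' @param what `"transport"` or `"storage"`.
#' @param width Bin width in percentage points.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the binned data.
#' @export
plot.vaxchain_sim <- function(x, what = c("transport", "storage"),
                              width = 10, ...) {
  what <- match.arg(what)
  if (what == "transport") {
    tl <- do.call(rbind, lapply(x$replications, function(r) r$trip_log))
    lv <- x$route_levels[tl[, "route"]]
    groups <- split(tl[, "requested"], lv)
  } else {
    u <- lapply(x$replications, function(r)
      colMeans(r$storage_refrigerated, na.rm = TRUE))
    u <- Reduce(`+`, u) / length(u)
    groups <- split(u, x$levels)
    groups <- groups[vapply(groups, function(g) any(!is.na(g)), TRUE)]
  }
  old <- graphics::par(mfrow = c(length(groups), 1),
                       mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  out <- lapply(names(groups), function(g) {
    h <- utilization_histogram(groups[[g]], width = width)
    graphics::barplot(h$count,
                      names.arg = paste0(h$bin_low, "%"),
                      main = paste(what, "utilization:", g, "origin"),
                      ylab = "frequency", las = 2, ...)
    h
  })
  invisible(stats::setNames(out, names(groups)))
}
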