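# Performance metrics: availability, transport and storage utilization,
# and their aggregations across replications, routes and stores.

#' Vaccine availability
#'
#' The fraction of vaccination opportunities that were served:
#' patients receiving a vaccine over patients arriving for it. Undefined
#' (returned as `NA`) when nobody arrived.
#'
#' @param received Number of patients receiving the vaccine.
#' @param arrived Number of patients arriving for it (>= `received`).
#' @return A fraction in [0, 1], or `NA` if `arrived` is 0.
#' @export
#' @examples
#' vaccine_availability(583575 - 58482, 583575)  # 0.8998 ~ 90%
vaccine_availability <- function(received, arrived) {
  stopifnot(all(received >= 0), all(arrived >= 0))
  if (any(received > arrived)) {
    stop("consistency error: received exceeds arrived")
  }
  ifelse(arrived == 0, NA_real_, received / arrived)
}

#' Transport capacity utilization
#'
#' Space consumed over available space per shipment, as a pair: the
#' demand-requested utilization (ordered volume over capacity, which
#' exceeds 100% when a downstream order overfills the vehicle) and the
#' actual utilization (loaded volume over capacity, at most 100%; the
#' excess is backlogged to the next trip).
#'
#' @param requested_volume Ordered volume, cm^3.
#' @param actual_volume Volume actually loaded, cm^3 (<= `capacity`).
#' @param capacity Vehicle net capacity, cm^3 (> 0).
#' @return Named vector `c(requested = , actual = )`, as fractions.
#' @export
#' @examples
#' transport_utilization(100 * 26.1, 50 * 26.1, 50 * 26.1)  # 200%, 100%
transport_utilization <- function(requested_volume, actual_volume, capacity) {
  if (capacity <= 0) stop("capacity must be > 0")
  if (actual_volume > capacity + 1e-9) {
    stop("consistency error: actual volume exceeds capacity")
  }
  c(requested = requested_volume / capacity, actual = actual_volume / capacity)
}

#' Storage utilization
#'
#' Volume stored over net capacity of a storage device (or of a location's
#' devices of one temperature class). A store with zero capacity (the
#' degenerate storage-less district store) reports `NA`.
#'
#' @param volume_stored Stored volume, cm^3.
#' @param capacity Net capacity, cm^3.
#' @return A fraction in [0, 1], or `NA` when capacity is 0.
#' @export
storage_utilization <- function(volume_stored, capacity) {
  stopifnot(all(volume_stored >= 0))
  if (any(capacity < 0)) stop("capacity must be >= 0")
  out <- ifelse(capacity == 0, NA_real_, volume_stored / capacity)
  if (any(out > 1 + 1e-9, na.rm = TRUE)) {
    stop("consistency error: stored volume exceeds capacity")
  }
  out
}

#' Median and range summary
#'
#' @param x Numeric vector (fractions).
#' @return Named vector: `median`, `mean`, `min`, `max`.
#' @export
median_range <- function(x) {
  x <- x[!is.na(x)]
  c(median = stats::median(x), mean = mean(x),
    min = if (length(x)) min(x) else NA_real_,
    max = if (length(x)) max(x) else NA_real_)
}

#' Histogram bins for utilization figures
#'
#' Bins utilization values (fractions) at a given width in percentage
#' points with an open-ended top bin, the layout used for the
#' transport/storage frequency histograms.
#'
#' @param x Utilizations as fractions.
#' @param width Bin width in percentage points (default 10).
#' @param top Lower edge of the open-ended top bin, percent (default the
#'   smallest multiple of `width` above `max(x)`, at least 100).
#' @return Data frame: `bin_low`, `bin_high` (percent), `count`.
#' @export
utilization_histogram <- function(x, width = 10, top = NULL) {
  x <- x[!is.na(x)] * 100
  if (is.null(top)) top <- max(100, ceiling(max(x, 0) / width) * width)
  edges <- c(seq(0, top, by = width), Inf)
  ct <- table(cut(x, edges, right = FALSE))
  data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1],
             count = as.integer(ct))
}

#' Aggregate simulation results
#'
#' Produces the standard summary of a [run_simulation()] object: national
#' per-antigen availability and dose accounts (means over replications,
#' with per-replication values retained), per-level transport utilization
#' summaries (replication-mean per route, then median/mean and range
#' across routes), and per-level storage utilization summaries
#' (time-mean per store, then median/range across stores). Both mean and
#' median are reported wherever either could be wanted.
#'
#' @param sim A `vaxchain_sim`.
#' @return A list with data frames `availability`, `doses`, `transport`,
#'   `storage`, and `conservation` (the per-replication dose-ledger
#'   balance).
#' @export
aggregate_results <- function(sim) {
  reps <- sim$replications
  R <- length(reps)
  A <- length(sim$antigens)

  avail_rep <- vapply(reps, function(r) {
    vaccine_availability(colSums(r$administered), colSums(r$arrivals))
  }, numeric(A))
  avail_rep <- matrix(avail_rep, A, R)
  availability <- data.frame(
    antigen = sim$antigens,
    availability = rowMeans(avail_rep),
    sd = apply(avail_rep, 1L, stats::sd),
    stringsAsFactors = FALSE
  )

  pick <- function(f) vapply(reps, f, numeric(A))
  doses <- data.frame(
    antigen = sim$antigens,
    arrivals = rowMeans(matrix(pick(function(r) colSums(r$arrivals)), A, R)),
    administered = rowMeans(matrix(pick(function(r) colSums(r$administered)),
                                   A, R)),
    missed = rowMeans(matrix(pick(function(r)
      colSums(r$arrivals - r$administered)), A, R)),
    open_vial_waste = rowMeans(matrix(pick(function(r)
      colSums(r$open_vial_waste)), A, R)),
    expiry_waste = rowMeans(matrix(pick(function(r) r$ledger$expiry), A, R)),
    breakage = rowMeans(matrix(pick(function(r) r$ledger$breakage), A, R)),
    vials_opened = rowMeans(matrix(pick(function(r)
      colSums(r$vials_opened)), A, R)),
    stringsAsFactors = FALSE
  )

  # transport: per-route mean utilization within a replication, averaged
  # over replications, then summarized across routes by origin level
  nrt <- nrow(sim$routes)
  rt_req <- rt_act <- matrix(NA_real_, nrt, R)
  for (i in seq_len(R)) {
    tl <- reps[[i]]$trip_log
    f <- factor(tl[, "route"], levels = seq_len(nrt))
    rt_req[, i] <- as.numeric(tapply(tl[, "requested"], f, mean))
    rt_act[, i] <- as.numeric(tapply(tl[, "actual"], f, mean))
  }
  route_req <- rowMeans(rt_req)
  route_act <- rowMeans(rt_act)
  transport <- do.call(rbind, lapply(unique(sim$route_levels), function(lv) {
    sel <- sim$route_levels == lv
    mr <- median_range(route_req[sel])
    ma <- median_range(route_act[sel])
    data.frame(origin_level = lv, n_routes = sum(sel),
               requested_median = mr[["median"]], requested_mean = mr[["mean"]],
               requested_min = mr[["min"]], requested_max = mr[["max"]],
               actual_median = ma[["median"]], actual_mean = ma[["mean"]],
               stringsAsFactors = FALSE)
  }))

  # storage: time-mean per store per replication, mean over replications,
  # then median/range across stores by level and temperature class
  store_util <- function(field) {
    m <- Reduce(`+`, lapply(reps, function(r) {
      u <- colMeans(r[[field]], na.rm = TRUE)
      u[is.nan(u)] <- NA_real_
      u
    })) / R
    m
  }
  u_ref <- store_util("storage_refrigerated")
  u_frz <- store_util("storage_frozen")
  storage <- do.call(rbind, lapply(unique(sim$levels), function(lv) {
    sel <- sim$levels == lv
    mr <- median_range(u_ref[sel])
    mf <- median_range(u_frz[sel])
    data.frame(level = lv, n_locations = sum(sel),
               refrigerated_median = mr[["median"]],
               refrigerated_mean = mr[["mean"]],
               refrigerated_min = mr[["min"]], refrigerated_max = mr[["max"]],
               frozen_median = mf[["median"]],
               stringsAsFactors = FALSE)
  }))

  conservation <- do.call(rbind, lapply(seq_len(R), function(i) {
    led <- reps[[i]]$ledger
    supplied <- led$initial + led$shipped - led$returned
    used <- colSums(reps[[i]]$administered) +
      colSums(reps[[i]]$open_vial_waste) + led$expiry + led$breakage +
      reps[[i]]$residual
    data.frame(replication = i, antigen = sim$antigens,
               supplied = supplied, accounted = used,
               stringsAsFactors = FALSE)
  }))

  list(availability = availability, doses = doses, transport = transport,
       storage = storage, conservation = conservation,
       availability_by_replication = avail_rep)
}
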