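# Engine primitives.
#
# Vials move through the chain as FIFO batches: a batch is a group of
# same-antigen, same-presentation vials that arrived together and share an
# expiry date. Internally a batch set is a numeric matrix with columns
# (n, arrival, expiry), rows in arrival (FIFO) order. The exported
# operations accept/return data frames with those columns plus `antigen`;
# the simulation loop uses the matrix cores directly.

empty_batches <- function() {
  matrix(numeric(0), ncol = 3L, dimnames = list(NULL, c("n", "arrival", "expiry")))
}

# Take k vials off the front of a FIFO batch matrix. Returns the remaining
# matrix, the removed batches, and the expiry of the last vial removed
# (needed when that vial stays open as a liquid multi-dose vial).
fifo_take <- function(m, k) {
  if (k <= 0 || nrow(m) == 0L) {
    return(list(rest = m, taken = empty_batches(), last_expiry = NA_real_))
  }
  cs <- cumsum(m[, 1L])
  k <- min(k, cs[length(cs)])
  i <- which(cs >= k)[1L]
  taken <- m[seq_len(i), , drop = FALSE]
  part <- cs[i] - k              # vials of batch i NOT taken
  taken[i, 1L] <- m[i, 1L] - part
  if (part > 0) {
    rest <- m[i:nrow(m), , drop = FALSE]
    rest[1L, 1L] <- part
  } else {
    rest <- m[-seq_len(i), , drop = FALSE]
  }
  list(rest = rest, taken = taken, last_expiry = taken[i, 3L])
}

batches_to_df <- function(lst, antigens) {
  rows <- lapply(seq_along(lst), function(a) {
    m <- lst[[a]]
    if (!NROW(m)) return(NULL)
    data.frame(antigen = antigens[a], n = m[, 1L], arrival = m[, 2L],
               expiry = m[, 3L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(antigen = character(), n = numeric(),
                      arrival = numeric(), expiry = numeric())
  }
  rownames(out) <- NULL
  out
}

df_to_batches <- function(df, antigens) {
  lapply(antigens, function(a) {
    d <- df[df$antigen == a, , drop = FALSE]
    if (!nrow(d)) return(empty_batches())
    d <- d[order(d$arrival), , drop = FALSE]
    cbind(n = d$n, arrival = d$arrival, expiry = d$expiry)
  })
}

#' Update a store's inventory with arrivals and removals
#'
#' The daily inventory balance: stock after the event equals stock before,
#' plus arriving vials (admitted only up to free cold-storage capacity --
#' the excess is rejected, never squeezed in), minus removed vials.
#' Removing vials that are not present is an internal consistency error.
#'
#' @param inventory Data frame of batches: `antigen`, `n`, `arrival`,
#'   `expiry`.
#' @param arrivals Data frame of arriving batches (same columns).
#' @param removals Data frame of batches to remove (must be a subset of
#'   `inventory` per antigen count).
#' @param catalog A `vax_catalog` (needed to compute volumes when
#'   `capacity` is finite).
#' @param capacity Free-volume limit in cm^3 for arrivals (`Inf` = no
#'   clamp). Applied through the balanced allocation scheme of
#'   [allocate_limited_space()].
#' @return A list: `inventory` (updated batch data frame) and `rejected`
#'   (arrivals that did not fit).
#' @export
update_inventory <- function(inventory, arrivals = NULL, removals = NULL,
                             catalog = NULL, capacity = Inf) {
  inv <- inventory
  if (!is.null(removals) && nrow(removals)) {
    for (i in seq_len(nrow(removals))) {
      a <- removals$antigen[i]
      have <- sum(inv$n[inv$antigen == a])
      if (have < removals$n[i]) {
        stop("internal consistency error: removing ", removals$n[i], " ", a,
             " vial(s) but only ", have, " present")
      }
      bt <- df_to_batches(inv, a)[[1L]]
      tk <- fifo_take(bt, removals$n[i])
      inv <- rbind(inv[inv$antigen != a, , drop = FALSE],
                   batches_to_df(list(tk$rest), a))
    }
  }
  rejected <- arrivals[0, ]
  if (!is.null(arrivals) && nrow(arrivals)) {
    if (is.finite(capacity)) {
      if (is.null(catalog)) stop("catalog required when capacity is finite")
      act <- active_presentations(catalog)
      vol_vial <- act$packed_vol_per_dose * act$doses_per_vial
      names(vol_vial) <- act$antigen
      inc <- tapply(arrivals$n, arrivals$antigen, sum)
      alloc <- allocate_limited_space(
        stats::setNames(as.numeric(inc), names(inc)), capacity, catalog)
      acc <- alloc$accepted
      keep <- list(); rej <- list()
      for (a in unique(arrivals$antigen)) {
        d <- arrivals[arrivals$antigen == a, , drop = FALSE]
        d <- d[order(d$arrival), , drop = FALSE]
        k <- if (a %in% names(acc)) acc[[a]] else 0
        cs <- cumsum(d$n)
        take <- pmin(d$n, pmax(0, k - c(0, cs[-length(cs)])))
        kd <- d; kd$n <- take
        rd <- d; rd$n <- d$n - take
        keep[[a]] <- kd[kd$n > 0, , drop = FALSE]
        rej[[a]] <- rd[rd$n > 0, , drop = FALSE]
      }
      arrivals <- do.call(rbind, keep)
      rejected <- do.call(rbind, rej)
      if (is.null(rejected)) rejected <- inventory[0, ]
    }
    inv <- rbind(inv, arrivals)
  }
  inv <- inv[order(inv$antigen, inv$arrival), , drop = FALSE]
  rownames(inv) <- NULL
  list(inventory = inv, rejected = rejected)
}

# Core of the balanced allocation scheme. Accepts vials in regimen rounds:
# round r admits, for each antigen, up to ceiling(r * doses_per_person /
# doses_per_vial) vials, i.e. one child's complete schedule per round
# (fractional vials accumulate across rounds). After the last full round,
# single vials are added in catalog order while space remains. `free` is
# either a single pooled volume (vehicles) or a length-2 vector by
# temperature class (refrigerated, frozen); `cls` maps antigens to
# classes (1 = refrigerated, 2 = frozen, or class names).
alloc_core <- function(inc, vol_vial, w, cls, free) {
  pooled <- length(free) == 1L
  if (!pooled) {
    if (!is.null(names(free))) free <- unname(free[c("refrigerated", "frozen")])
    if (is.character(cls)) cls <- ifelse(cls == "frozen", 2L, 1L)
    i1 <- cls == 1L; i2 <- !i1
  }
  fits <- function(acc) {
    v <- acc * vol_vial
    if (pooled) return(sum(v) <= free + 1e-9)
    sum(v[i1]) <= free[1L] + 1e-9 && sum(v[i2]) <= free[2L] + 1e-9
  }
  acc_at <- function(r) pmin(inc, ceiling(r * w - 1e-9))
  if (fits(inc)) return(inc)
  # largest whole number of regimen rounds that fits (binary search)
  lo <- 0; hi <- max(ceiling(inc / pmax(w, 1e-12))) + 1
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (fits(acc_at(mid))) lo <- mid else hi <- mid
  }
  acc <- acc_at(lo)
  # partial round: single vials in catalog order up to the next round's cap
  nxt <- pmin(inc, acc_at(lo + 1))
  for (a in seq_along(inc)) {
    while (acc[a] < nxt[a]) {
      try_acc <- acc
      try_acc[a] <- acc[a] + 1
      if (!fits(try_acc)) break
      acc <- try_acc
    }
  }
  # an exhausted temperature class must not block antigens of the other
  # class: recurse on whatever still has both demand and room
  rem_free <- if (pooled) {
    free - sum(acc * vol_vial)
  } else {
    c(free[1L] - sum((acc * vol_vial)[i1]), free[2L] - sum((acc * vol_vial)[i2]))
  }
  cls_free <- if (pooled) rep(rem_free, length(inc)) else rem_free[cls]
  sub <- which(acc < inc & vol_vial <= cls_free + 1e-9)
  if (length(sub)) {
    acc[sub] <- acc[sub] + alloc_core(inc[sub] - acc[sub], vol_vial[sub],
                                      w[sub],
                                      if (pooled) cls else cls[sub],
                                      rem_free)
  }
  acc
}

#' Balanced allocation of vials into limited cold space
#'
#' When space (storage or vehicle) cannot hold everything, vials are
#' admitted in rounds of complete vaccine regimens: each round accepts, per
#' antigen, the vials needed to cover one additional child's full schedule
#' (fractionally by doses per vial, accumulated across rounds), so complete
#' regimens are prioritized over bulk single antigens. Within the last,
#' partial round single vials are added in catalog order.
#'
#' @param incoming Named numeric vector: vials per antigen offered.
#' @param free_volume Free space in cm^3. Either a single pooled number
#'   (transport devices) or a named vector
#'   `c(refrigerated = , frozen = )` (storage locations).
#' @param catalog A `vax_catalog`; active presentations define volumes,
#'   doses per vial and doses per person.
#' @return A list with named vectors `accepted` and `rejected`.
#' @export
allocate_limited_space <- function(incoming, free_volume, catalog) {
  stopifnot(all(free_volume >= 0), all(incoming >= 0))
  act <- active_presentations(catalog)
  idx <- match(names(incoming), act$antigen)
  if (anyNA(idx)) stop("unknown antigen in incoming: ",
                       paste(names(incoming)[is.na(idx)], collapse = ", "))
  vol_vial <- act$packed_vol_per_dose[idx] * act$doses_per_vial[idx]
  w <- act$doses_per_person[idx] / act$doses_per_vial[idx]
  cls <- ifelse(act$storage_class[idx] == "freezer", "frozen", "refrigerated")
  if (!is.null(names(free_volume))) {
    free_volume <- free_volume[c("refrigerated", "frozen")]
    free_volume[is.na(free_volume)] <- 0
    names(free_volume) <- c("refrigerated", "frozen")
  }
  acc <- alloc_core(as.numeric(incoming), vol_vial, w, cls,
                    if (is.null(names(free_volume))) as.numeric(free_volume)
                    else free_volume)
  names(acc) <- names(incoming)
  list(accepted = acc, rejected = incoming - acc)
}

#' Compute a reorder-point order
#'
#' The (s, S)-style rule: whenever on-hand stock of an antigen falls to or
#' below `reorder_fraction` of its order-up-to level ("maximum"), order
#' `(max_level - on_hand) * (1 + buffer_fraction)` vials of it, rounded up.
#' Orders are optionally capped so that post-delivery volume fits the
#' store's free space, via the balanced allocation scheme.
#'
#' @param on_hand Named vector: vials on hand per antigen.
#' @param max_level Named vector: order-up-to level per antigen (vials).
#' @param reorder_fraction Reorder point as a fraction of `max_level`
#'   (default 0.25).
#' @param buffer_fraction Over-order buffer (default 0.25).
#' @param catalog,free_volume Optional: when given, the order is capped by
#'   [allocate_limited_space()] against `free_volume`.
#' @return Named vector of vials to order per antigen.
#' @export
#' @examples
#' compute_order(c(M = 20), c(M = 100))  # ceiling(80 * 1.25) = 100
compute_order <- function(on_hand, max_level, reorder_fraction = 0.25,
                          buffer_fraction = 0.25, catalog = NULL,
                          free_volume = NULL) {
  stopifnot(length(on_hand) == length(max_level), all(on_hand >= 0))
  trigger <- on_hand <= reorder_fraction * max_level
  ord <- ifelse(trigger,
                ceiling(pmax(0, max_level - on_hand) * (1 + buffer_fraction)),
                0)
  names(ord) <- names(on_hand)
  if (!is.null(free_volume) && !is.null(catalog) && any(ord > 0)) {
    ord <- allocate_limited_space(ord, free_volume, catalog)$accepted
  }
  ord
}

# Proportional fill: scale a requested vial mix down to a volume budget,
# preserving each antigen's share of the request (floored to whole vials,
# then topped up one vial at a time in catalog order while space remains).
prop_fill <- function(req, vol_vial, cap) {
  tv <- sum(req * vol_vial)
  if (tv <= cap + 1e-9) return(req)
  out <- floor(req * (cap / tv))
  left <- cap - sum(out * vol_vial)
  repeat {
    added <- FALSE
    for (a in seq_along(req)) {
      if (out[a] < req[a] && vol_vial[a] <= left + 1e-9) {
        out[a] <- out[a] + 1
        left <- left - vol_vial[a]
        added <- TRUE
      }
    }
    if (!added) break
  }
  out
}

#' Load a shipment onto a transport device
#'
#' Draws the ordered vials first-in-first-out from the origin's stock, up
#' to the smaller of the order, the stock, and the vehicle's net capacity.
#' When capacity binds, the load keeps each antigen's share of the request
#' (proportional fill), so every antigen ships at the same fill rate.
#' The demand-requested utilization is the ordered volume over capacity and
#' may exceed 100%; the actual utilization never does. Whatever could not
#' be shipped -- for lack of capacity or of stock -- is returned as backlog
#' for the next trip.
#'
#' @param order Named vector: vials requested per antigen.
#' @param origin_stock Batch data frame (`antigen`, `n`, `arrival`,
#'   `expiry`) at the origin.
#' @param vehicle_capacity Net vehicle capacity, cm^3 (> 0).
#' @param catalog A `vax_catalog`.
#' @return A list: `loaded` (batch data frame), `origin_stock` (updated),
#'   `backlog` (named vector), `requested_utilization` and
#'   `actual_utilization` (fractions; 2.0 means a 200% overfilled order).
#' @export
load_shipment <- function(order, origin_stock, vehicle_capacity, catalog) {
  stopifnot(vehicle_capacity > 0)
  act <- active_presentations(catalog)
  vol_vial <- stats::setNames(
    act$packed_vol_per_dose * act$doses_per_vial, act$antigen)
  req_vol <- sum(order * vol_vial[names(order)])
  stock <- vapply(names(order),
                  function(a) sum(origin_stock$n[origin_stock$antigen == a]), 0)
  take <- pmin(order, stock)
  loadable <- stats::setNames(
    prop_fill(as.numeric(take), vol_vial[names(order)], vehicle_capacity),
    names(order))
  loaded <- list(); rest <- origin_stock
  for (a in names(loadable)) {
    if (loadable[[a]] <= 0) next
    bt <- df_to_batches(rest, a)[[1L]]
    tk <- fifo_take(bt, loadable[[a]])
    rest <- rbind(rest[rest$antigen != a, , drop = FALSE],
                  batches_to_df(list(tk$rest), a))
    loaded[[a]] <- batches_to_df(list(tk$taken), a)
  }
  loaded <- if (length(loaded)) do.call(rbind, loaded) else origin_stock[0, ]
  rownames(loaded) <- NULL
  act_vol <- sum(loaded$n * vol_vial[loaded$antigen])
  list(loaded = loaded,
       origin_stock = rest[order(rest$antigen, rest$arrival), , drop = FALSE],
       backlog = order - loadable,
       requested_utilization = req_vol / vehicle_capacity,
       actual_utilization = act_vol / vehicle_capacity)
}

#' Destroy vials at random (breakage / mishandling loss)
#'
#' Each vial independently survives with probability `1 - p`.
#'
#' @param vials Batch data frame (`antigen`, `n`, `arrival`, `expiry`).
#' @param p Per-vial loss probability in [0, 1].
#' @return A list: `surviving` (batch data frame) and `n_lost` (named per
#'   antigen).
#' @export
apply_random_loss <- function(vials, p) {
  stopifnot(p >= 0, p <= 1)
  if (!nrow(vials) || p == 0) {
    return(list(surviving = vials,
                n_lost = stats::setNames(numeric(0), character(0))))
  }
  lost <- stats::rbinom(nrow(vials), vials$n, p)
  out <- vials
  out$n <- vials$n - lost
  nl <- tapply(lost, vials$antigen, sum)
  list(surviving = out[out$n > 0, , drop = FALSE],
       n_lost = stats::setNames(as.numeric(nl), names(nl)))
}

#' Remove expired vials from a store
#'
#' Sealed vials whose shelf-life expiry has passed are discarded as expiry
#' wastage; opened vials past their open-vial lifetime (28 days for liquid
#' formulations) are discarded with their remaining doses counted as
#' open-vial wastage -- the two wastage streams are kept distinct.
#'
#' @param inventory Sealed-vial batch data frame.
#' @param open_vials Data frame of open vials: `antigen`, `doses_left`,
#'   `expiry`.
#' @param now Current day.
#' @return A list: `inventory`, `open_vials` (both purged), `discarded`
#'   (expired sealed batches), `expired_doses` (sealed doses lost, given
#'   `catalog`-free as vials via attribute), `open_waste_doses` (doses lost
#'   from expired open vials).
#' @export
remove_expired <- function(inventory, open_vials = NULL, now) {
  gone <- inventory$expiry <= now
  discarded <- inventory[gone, , drop = FALSE]
  inv <- inventory[!gone, , drop = FALSE]
  open_waste <- 0
  if (!is.null(open_vials) && nrow(open_vials)) {
    og <- open_vials$expiry <= now
    open_waste <- sum(open_vials$doses_left[og])
    open_vials <- open_vials[!og, , drop = FALSE]
  }
  list(inventory = inv, open_vials = open_vials, discarded = discarded,
       open_waste_doses = open_waste)
}
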