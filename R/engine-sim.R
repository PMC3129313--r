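# The discrete-event simulation loop.
#
# Time advances on a daily grid over a 12 x 30-day year. Within a day the
# phase order is: expiry sweep -> clinic sessions -> order placement and
# shipments (trips depart, suffer per-vial shipping loss, and unload the
# same day; vials rejected for space at the destination return to the
# origin). Inventory loss is applied monthly. Every replication keeps a
# dose ledger per antigen so that conservation -- initial downstream stock
# + doses shipped from central - returns to central = administered +
# open-vial waste + expiry waste + breakage + residual -- holds exactly.

# Swap-in/swap-out RNG streams so demand draws and loss draws are
# independent reproducible streams per replication.
rng_streams <- function(rep_seed) {
  e <- new.env(parent = emptyenv())
  set.seed(rep_seed)
  e$demand <- get(".Random.seed", envir = globalenv())
  set.seed((rep_seed + 500009) %% 2147483647)
  e$loss <- get(".Random.seed", envir = globalenv())
  e
}

with_stream <- function(streams, name, expr) {
  assign(".Random.seed", streams[[name]], envir = globalenv())
  on.exit(assign(name, get(".Random.seed", envir = globalenv()),
                 envir = streams))
  expr
}

#' Simulation configuration defaults
#'
#' Baseline operating conditions: 1% shipping and inventory loss, dynamic
#' monthly demand, 100% target population, ten replications.
#'
#' @param ... Overrides of the defaults.
#' @return A named list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    replications = 10L,
    seed = 1L,
    shipping_loss = 0.01,   # per vial per trip departure
    inventory_loss = 0.01,  # annual rate, applied monthly at rate/12
    horizon_days = 360L,    # 12 x 30-day months
    snapshot_every = 7L,    # storage-utilization sampling interval (days)
    # order-up-to depth ("maximum") per level, in months of expected flow;
    # quarterly-resupplied tiers hold deeper stock
    order_months = c(central = 6, regional = 4.5, district = 3, clinic = 2.5)
  )
  utils::modifyList(cfg, list(...))
}

# Order-up-to levels per location x antigen, in vials, derived from the
# expected demand over a re-supply interval (not raw device capacity).
# Expected vials consumed per session include the open-vial waste
# inflation for lyophilized multi-dose vials: E[ceil(N/dpv)] for Poisson
# demand is approximately lambda/dpv + (dpv-1)/(2 dpv) P(N > 0).
expected_vial_rate <- function(lam, dpv, lyophilized) {
  extra <- ifelse(lyophilized & dpv > 1,
                  (dpv - 1) / (2 * dpv) * (1 - exp(-lam)), 0)
  lam / dpv + extra
}

build_sim_setup <- function(network, catalog, demand, config) {
  act <- active_presentations(catalog)
  A <- nrow(act)
  antigens <- act$antigen
  dpv <- act$doses_per_vial
  vol_vial <- act$packed_vol_per_dose * dpv
  lyo <- act$formulation == "lyophilized"
  open_days <- act$open_vial_days
  cls <- ifelse(act$storage_class == "freezer", 2L, 1L)
  shelf <- act$shelf_life_days

  locs <- network$locations
  L <- nrow(locs)
  idx_of <- stats::setNames(seq_len(L), locs$id)
  cap <- matrix(0, L, 2L, dimnames = list(NULL, c("refrigerated", "frozen")))
  for (i in seq_len(nrow(network$devices))) {
    d <- network$devices[i, ]
    j <- idx_of[[d$location_id]]
    k <- if (storage_kinds[[d$kind]] == "frozen") 2L else 1L
    cap[j, k] <- cap[j, k] + d$capacity_cm3
  }
  clinics <- which(locs$level == "clinic")
  clinic_ids <- locs$id[clinics]
  if (!all(clinic_ids %in% names(demand$clinic_shares))) {
    stop("pre-flight error: clinic(s) without demand share")
  }
  lam <- antigen_session_lambda(demand, clinic_ids, antigens)

  # supplier tree from routes: each stop's supplier is the route origin
  rt <- network$routes
  supplier <- rep(NA_integer_, L)
  for (r in seq_len(nrow(rt))) {
    for (s in network$stops[[rt$route_id[r]]]) {
      supplier[idx_of[[s]]] <- idx_of[[rt$origin[r]]]
    }
  }

  # expected vial flow per session at clinics, rolled up the tree
  vial_sess <- matrix(0, L, A)
  vial_sess[clinics, ] <- expected_vial_rate(
    lam, matrix(dpv, length(clinics), A, byrow = TRUE),
    matrix(lyo, length(clinics), A, byrow = TRUE))
  ord <- order(match(locs$level, rev(location_levels)))  # clinics first
  for (j in ord) {
    if (!is.na(supplier[j])) {
      vial_sess[supplier[j], ] <- vial_sess[supplier[j], ] + vial_sess[j, ]
    }
  }
  monthly_vials <- vial_sess * demand$sessions_per_month

  k_months <- config$order_months
  stopifnot(all(location_levels %in% names(k_months)))
  max_level <- ceiling(monthly_vials * k_months[locs$level])

  # trip schedule: day offsets phase deliveries down the tree
  if (!is.null(config$shipping_loss)) rt$loss_prob <- config$shipping_loss
  n_routes <- nrow(rt)
  lvl_of_origin <- locs$level[idx_of[rt$origin]]
  interval <- pmax(1L, floor(360 / rt$trips_per_year))
  first_day <- integer(n_routes)
  ctr <- c(central = 0L, regional = 0L, district = 0L)
  for (r in seq_len(n_routes)) {
    lv <- lvl_of_origin[r]
    first_day[r] <- switch(lv,
      central = 2L + (ctr[["central"]] %% 3L),
      regional = 7L + (ctr[["regional"]] %% 4L),
      district = 13L + (ctr[["district"]] %% 16L))
    ctr[[lv]] <- ctr[[lv]] + 1L
  }
  trips_on <- vector("list", config$horizon_days)
  for (r in seq_len(n_routes)) {
    days <- seq(first_day[r], config$horizon_days, by = interval[r])
    for (d in days) trips_on[[d]] <- c(trips_on[[d]], r)
  }
  sess_days <- sort(unique(as.integer(outer(
    0:11 * 30L, ceiling(30 * (seq_len(demand$sessions_per_month) - 0.5) /
                          demand$sessions_per_month), "+"))))
  sess_days <- sess_days[sess_days <= config$horizon_days]

  list(act = act, A = A, antigens = antigens, dpv = dpv, vol_vial = vol_vial,
       lyo = lyo, open_days = open_days, cls = cls, shelf = shelf,
       w = act$doses_per_person / dpv, i_ref = cls == 1L, i_frz = cls == 2L,
       locs = locs, L = L, idx_of = idx_of, cap = cap, clinics = clinics,
       clinic_ids = clinic_ids, lam = lam, supplier = supplier,
       max_level = max_level, rt = rt,
       stops_idx = lapply(network$stops, function(s) unname(idx_of[s])),
       trips_on = trips_on, sess_days = sess_days,
       central = which(locs$level == "central"))
}

run_replication <- function(su, demand, config, rep_seed) {
  A <- su$A; L <- su$L
  dpv <- su$dpv; vol_vial <- su$vol_vial; cls <- su$cls
  streams <- rng_streams(rep_seed)
  pars <- list(dpv = dpv, lyophilized = su$lyo, open_days = su$open_days)

  inv <- lapply(seq_len(L), function(i) lapply(seq_len(A), function(a)
    empty_batches()))
  stock <- matrix(0, L, A)
  svol <- matrix(0, L, 2L)   # stored volume by temperature class
  nxexp <- matrix(Inf, L, A)
  nC <- length(su$clinics)
  open_d <- matrix(0, nC, A)
  open_e <- matrix(Inf, nC, A)
  clinic_row <- integer(L); clinic_row[su$clinics] <- seq_len(nC)
  backlog <- matrix(0, L, A)  # keyed by destination (one supplier each)

  led <- list(shipped = numeric(A), returned = numeric(A),
              initial = numeric(A), adm = numeric(A), ovw = numeric(A),
              expiry = numeric(A), breakage = numeric(A))
  arrivals_m <- matrix(0, nC, A)
  adm_m <- matrix(0, nC, A)
  ovw_m <- matrix(0, nC, A)
  vop_m <- matrix(0, nC, A)
  n_snap <- floor(config$horizon_days / config$snapshot_every)
  snap_ref <- matrix(NA_real_, n_snap, L)
  snap_frz <- matrix(NA_real_, n_snap, L)
  est_trips <- sum(ceiling(su$rt$trips_per_year)) + nrow(su$rt)
  trip_log <- matrix(NA_real_, est_trips, 4L,
                     dimnames = list(NULL, c("route", "day", "requested",
                                             "actual")))
  n_trip <- 0L

  add_batch <- function(j, a, n, arrival, expiry) {
    if (n <= 0) return(invisible())
    inv[[j]][[a]] <<- rbind(inv[[j]][[a]], c(n, arrival, expiry))
    stock[j, a] <<- stock[j, a] + n
    svol[j, cls[a]] <<- svol[j, cls[a]] + n * vol_vial[a]
    if (expiry < nxexp[j, a]) nxexp[j, a] <<- expiry
  }
  take_fifo <- function(j, a, k) {
    tk <- fifo_take(inv[[j]][[a]], k)
    inv[[j]][[a]] <<- tk$rest
    taken <- sum(tk$taken[, 1L])
    stock[j, a] <<- stock[j, a] - taken
    svol[j, cls[a]] <<- svol[j, cls[a]] - taken * vol_vial[a]
    tk$taken
  }

  # warm start: every location begins at its order-up-to level (capped by
  # its own storage); the doses placed downstream enter the ledger
  for (j in seq_len(L)) {
    want <- su$max_level[j, ]
    if (all(want <= 0)) next
    free <- c(su$cap[j, 1L], su$cap[j, 2L])
    accepted <- alloc_core(want, vol_vial, su$act$doses_per_person / dpv,
                           c("refrigerated", "frozen")[cls],
                           stats::setNames(free, c("refrigerated", "frozen")))
    for (a in seq_len(A)) {
      add_batch(j, a, accepted[a], 0, su$shelf[a])
    }
    if (su$locs$level[j] != "central") {
      led$initial <- led$initial + accepted * dpv
    }
  }

  central <- su$central
  max_central <- su$max_level[central, ]

  do_trip <- function(r, day) {
    stops <- su$stops_idx[[su$rt$route_id[r]]]
    origin <- su$idx_of[[su$rt$origin[r]]]
    cap_v <- su$rt$vehicle_capacity_cm3[r]
    # per-stop orders, capped by each stop's free storage, plus backlog
    req <- matrix(0, length(stops), A)
    for (s in seq_along(stops)) {
      d <- stops[s]
      ordv <- compute_order_core(stock[d, ], su$max_level[d, ],
                                 su$locs$reorder_point_fraction[d],
                                 su$locs$buffer_fraction[d])
      ordv <- pmax(ordv, backlog[d, ])
      if (any(ordv > 0)) {
        # cap so post-delivery stock fits storage, scaling the order mix
        # proportionally within each temperature class
        for (k in 1:2) {
          ik <- if (k == 1L) su$i_ref else su$i_frz
          need <- sum((ordv * vol_vial)[ik])
          if (need <= 0) next
          freek <- su$cap[d, k] - svol[d, k]
          if (need > freek + 1e-9) {
            ordv[ik] <- floor(ordv[ik] * max(0, freek) / need)
          }
        }
      }
      req[s, ] <- ordv
    }
    req_tot <- colSums(req)
    req_vol <- sum(req_tot * vol_vial)
    if (req_vol <= 0) {
      n_trip <<- n_trip + 1L
      trip_log[n_trip, ] <<- c(r, day, 0, 0)
      return(invisible())
    }
    take <- pmin(req_tot, stock[origin, ])
    loaded_tot <- prop_fill(take, vol_vial, cap_v)
    # split the load across stops in proportion to requests (whole vials,
    # remainders to earlier stops in visiting order)
    loaded <- matrix(0, length(stops), A)
    for (a in seq_len(A)) {
      if (loaded_tot[a] <= 0 || req_tot[a] <= 0) next
      sh <- floor(loaded_tot[a] * req[, a] / req_tot[a])
      remn <- loaded_tot[a] - sum(sh)
      if (remn > 0) {
        extra <- which(req[, a] > sh)
        sh[extra[seq_len(min(remn, length(extra)))]] <-
          sh[extra[seq_len(min(remn, length(extra)))]] + 1
      }
      loaded[, a] <- pmin(sh, req[, a])
    }
    loaded_tot <- colSums(loaded)
    act_vol <- 0
    from_central <- su$locs$level[origin] == "central"
    p_loss <- su$rt$loss_prob[r]
    for (s in seq_along(stops)) {
      d <- stops[s]
      for (a in seq_len(A)) {
        k <- loaded[s, a]
        if (k <= 0) next
        taken <- take_fifo(origin, a, k)
        if (from_central) led$shipped[a] <<- led$shipped[a] + k * dpv[a]
        act_vol <- act_vol + k * vol_vial[a]
        for (b in seq_len(nrow(taken))) {
          n <- taken[b, 1L]
          if (p_loss > 0) {
            lost <- with_stream(streams, "loss", stats::rbinom(1L, n, p_loss))
            if (lost > 0) {
              led$breakage[a] <<- led$breakage[a] + lost * dpv[a]
              n <- n - lost
            }
          }
          if (n <= 0) next
          # admission at the destination (free space was checked at order
          # time the same day, so rejection is rare; any rejected vials
          # ride back to the origin)
          vfree <- su$cap[d, cls[a]] - svol[d, cls[a]]
          admit <- min(n, max(0, floor(vfree / vol_vial[a] + 1e-9)))
          if (admit > 0) add_batch(d, a, admit, day, taken[b, 3L])
          back <- n - admit
          if (back > 0) {
            add_batch(origin, a, back, taken[b, 2L], taken[b, 3L])
            if (from_central) {
              led$shipped[a] <<- led$shipped[a] - back * dpv[a]
              led$returned[a] <<- led$returned[a] + back * dpv[a]
            }
          }
        }
      }
      backlog[d, ] <<- pmax(0, req[s, ] - loaded[s, ])
    }
    n_trip <<- n_trip + 1L
    trip_log[n_trip, ] <<- c(r, day, req_vol / cap_v, act_vol / cap_v)
  }

  horizon <- config$horizon_days
  p_inv_loss <- config$inventory_loss / 12
  for (day in seq_len(horizon)) {
    # expiry sweep
    if (any(nxexp <= day)) {
      hits <- which(nxexp <= day, arr.ind = TRUE)
      for (h in seq_len(nrow(hits))) {
        j <- hits[h, 1L]; a <- hits[h, 2L]
        m <- inv[[j]][[a]]
        gone <- m[, 3L] <= day
        n_gone <- sum(m[gone, 1L])
        inv[[j]][[a]] <- m[!gone, , drop = FALSE]
        stock[j, a] <- stock[j, a] - n_gone
        svol[j, cls[a]] <- svol[j, cls[a]] - n_gone * vol_vial[a]
        if (su$locs$level[j] != "central") {
          led$expiry[a] <- led$expiry[a] + n_gone * dpv[a]
        }
        nxexp[j, a] <- if (nrow(inv[[j]][[a]])) min(inv[[j]][[a]][, 3L]) else Inf
      }
    }
    # clinic sessions
    si <- match(day, su$sess_days)
    if (!is.na(si)) {
      Dm <- if (demand$mode == "dynamic") {
        with_stream(streams, "demand",
                    matrix(stats::rpois(nC * A, su$lam), nC, A))
      } else {
        round(su$lam * si) - round(su$lam * (si - 1))
      }
      for (ci in seq_len(nC)) {
        need <- Dm[ci, ]
        j <- su$clinics[ci]
        if (all(need == 0) && all(open_d[ci, ] == 0)) next
        st <- list(batches = inv[[j]], stock = stock[j, ],
                   open_d = open_d[ci, ], open_e = open_e[ci, ])
        res <- mdvp_session(st, need, day, pars)
        opened <- res$outcome$vials_opened
        inv[[j]] <- res$state$batches
        stock[j, ] <- res$state$stock
        svol[j, 1L] <- svol[j, 1L] - sum((opened * vol_vial)[cls == 1L])
        svol[j, 2L] <- svol[j, 2L] - sum((opened * vol_vial)[cls == 2L])
        open_d[ci, ] <- res$state$open_d
        open_e[ci, ] <- res$state$open_e
        arrivals_m[ci, ] <- arrivals_m[ci, ] + need
        adm_m[ci, ] <- adm_m[ci, ] + res$outcome$administered
        ovw_m[ci, ] <- ovw_m[ci, ] + res$outcome$open_vial_waste
        vop_m[ci, ] <- vop_m[ci, ] + opened
      }
    }
    # trips
    tr <- su$trips_on[[day]]
    for (r in tr) do_trip(r, day)
    # monthly: inventory loss, central procurement, storage snapshot
    if (day %% 30L == 0L) {
      with_stream(streams, "loss", {
        for (j in seq_len(L)) {
          for (a in seq_len(A)) {
            if (stock[j, a] <= 0) next
            m <- inv[[j]][[a]]
            lost <- stats::rbinom(nrow(m), m[, 1L], p_inv_loss)
            tl <- sum(lost)
            if (tl > 0) {
              m[, 1L] <- m[, 1L] - lost
              inv[[j]][[a]] <- m[m[, 1L] > 0, , drop = FALSE]
              stock[j, a] <- stock[j, a] - tl
              svol[j, cls[a]] <- svol[j, cls[a]] - tl * vol_vial[a]
              if (su$locs$level[j] != "central") {
                led$breakage[a] <- led$breakage[a] + tl * dpv[a]
              }
            }
          }
        }
      })
      if ((day / 30L) %% 3L == 0L) {  # quarterly procurement, fresh stock
        topup <- pmax(0, max_central - stock[central, ])
        free <- stats::setNames(pmax(0, su$cap[central, ] - svol[central, ]),
                                c("refrigerated", "frozen"))
        acc <- alloc_core(topup, vol_vial, su$act$doses_per_person / dpv,
                          c("refrigerated", "frozen")[cls], free)
        for (a in seq_len(A)) {
          add_batch(central, a, acc[a], day, day + su$shelf[a])
        }
      }
    }
    if (day %% config$snapshot_every == 0L) {
      k <- day %/% config$snapshot_every
      if (k >= 1 && k <= n_snap) {
        snap_ref[k, ] <- ifelse(su$cap[, 1L] > 0, svol[, 1L] / su$cap[, 1L],
                                NA_real_)
        snap_frz[k, ] <- ifelse(su$cap[, 2L] > 0, svol[, 2L] / su$cap[, 2L],
                                NA_real_)
      }
    }
  }

  residual <- colSums(stock[-central, , drop = FALSE] *
                        matrix(dpv, L - 1L, A, byrow = TRUE)) +
    colSums(open_d)
  list(arrivals = arrivals_m, administered = adm_m, open_vial_waste = ovw_m,
       vials_opened = vop_m, ledger = led, residual = residual,
       trip_log = trip_log[seq_len(n_trip), , drop = FALSE],
       storage_refrigerated = snap_ref, storage_frozen = snap_frz)
}

# vectorized core of the reorder rule (no allocation cap)
compute_order_core <- function(on_hand, max_level, reorder_fraction,
                               buffer_fraction) {
  trigger <- on_hand <= reorder_fraction * max_level & max_level > 0
  ifelse(trigger,
         ceiling(pmax(0, max_level - on_hand) * (1 + buffer_fraction)), 0)
}

#' Run the supply-chain simulation
#'
#' Executes the one-year discrete-event simulation -- shipments at route
#' frequencies, reorder-point ordering with backlog, capacity-clamped FIFO
#' storage, random losses, expiry, and clinic sessions under the Multi-Dose
#' Vial Policy -- over the configured number of replications, and averages
#' the results. Identical seeds give bit-identical results.
#'
#' @param network A `vax_network`.
#' @param catalog A `vax_catalog` (apply [substitute_presentation()] first
#'   for vial-size scenarios).
#' @param demand A `vax_demand` whose clinic shares match the network's
#'   clinics.
#' @param config A list from [sim_config()].
#' @return An object of class `vaxchain_sim`: per-replication results
#'   (`replications`), the averaged summary (`summary`, see
#'   [aggregate_results()]), and the inputs.
#' @export
run_simulation <- function(network, catalog, demand, config = sim_config()) {
  config <- utils::modifyList(sim_config(), config)
  su <- build_sim_setup(network, catalog, demand, config)
  if (all(su$cap <= 0)) {
    stop("pre-flight error: no storage capacity anywhere in the network")
  }
  for (a in seq_len(su$A)) {
    k <- su$cls[a]
    reachable <- su$cap[, k] > 0
    if (!any(reachable)) {
      stop("pre-flight error: no storable device for ", su$antigens[a],
           " (", c("refrigerated", "frozen")[k], ")")
    }
  }
  reps <- lapply(seq_len(config$replications), function(r) {
    run_replication(su, demand, config, (config$seed + 7919 * r) %% 2147483647)
  })
  out <- structure(list(
    replications = reps,
    antigens = su$antigens,
    clinic_ids = su$clinic_ids,
    levels = su$locs$level,
    location_ids = su$locs$id,
    routes = su$rt,
    route_levels = su$locs$level[su$idx_of[su$rt$origin]],
    catalog = catalog, demand = demand, config = config
  ), class = "vaxchain_sim")
  out$summary <- aggregate_results(out)
  out
}
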