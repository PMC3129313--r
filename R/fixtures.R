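# Synthetic network fixtures.
#
# The real national equipment inventory and route list behind the
# published experiments are unpublished, so every network here is
# synthetic: it reproduces the published structure (one central store, 7
# regional stores on two cold-truck delivery loops, 42 district stores of
# which 7 procure directly from the central store and one has no cold
# storage, 695 clinics) and its qualitative operating regime, not any real
# facility's capacity. Device and vehicle capacities are calibrated as
# documented multiples of expected flow under the baseline 10-dose
# catalog -- constants chosen so the baseline lands where the published
# scenario operates (district refrigerators in the 60-70% band, many
# clinic vaccine carriers above 100% demand-requested utilization) -- and
# are held fixed across vial-size scenarios, since the equipment does not
# change when the vial does.

#' Fixture parameters for the synthetic network generator
#'
#' @param n_regional,n_district,n_clinics Tier sizes (defaults 7/42/695).
#' @param n_direct_districts Districts that procure directly from the
#'   central store by 4x4 truck instead of through their regional store.
#' @param storage_less_district Include one district store with no cold
#'   storage (its clinics collect from the regional store instead)?
#'   Defaults to `TRUE` for full-size networks.
#' @param annual_births Annual birth cohort; defaults to the published
#'   2010 projection scaled by `n_clinics / 695` for miniatures.
#' @param share_sdlog Log-normal sd of clinic demand weights; long-tailed
#'   shares make session sizes heterogeneous, which is what makes
#'   session-size-dependent open-vial wastage observable.
#' @param sessions_per_month Clinic sessions per month.
#' @param calibration Named list of capacity multipliers (see source).
#' @param seed Generator seed; the same seed reproduces the network
#'   bit-identically.
#' @return A list of class `fixture_params`.
#' @export
fixture_params <- function(n_regional = 7L, n_district = 42L,
                           n_clinics = 695L,
                           n_direct_districts = min(7L, n_district),
                           storage_less_district = n_district >= 10L,
                           annual_births = round(586880 * n_clinics / 695),
                           share_sdlog = 0.6,
                           sessions_per_month = 4L,
                           calibration = list(),
                           seed = 42L) {
  stopifnot(n_regional >= 1, n_district >= 1, n_clinics >= 1,
            n_direct_districts <= n_district)
  cal <- utils::modifyList(list(
    carrier = 1.4,      # x mean clinic monthly volume
    four_by_four = 1.8, # x mean district monthly volume
    cold_truck = 4.5,   # x loop monthly through-volume
    clinic_store = 3.5, # x mean clinic monthly volume (standard fridge)
    district_store = 1.7, # x own district monthly volume
    regional_store = 16,  # x own regional monthly volume
    central_store = 7     # x national monthly volume
  ), calibration)
  structure(list(n_regional = as.integer(n_regional),
                 n_district = as.integer(n_district),
                 n_clinics = as.integer(n_clinics),
                 n_direct_districts = as.integer(n_direct_districts),
                 storage_less_district = isTRUE(storage_less_district),
                 annual_births = annual_births,
                 share_sdlog = share_sdlog,
                 sessions_per_month = as.integer(sessions_per_month),
                 calibration = cal, seed = as.integer(seed)),
            class = "fixture_params")
}

#' Generate a synthetic four-tier supply network
#'
#' Builds the network described in [fixture_params()]: clinics with
#' log-normal demand shares assigned round-robin to districts, districts
#' to regions, two central-to-regional cold-truck delivery loops, direct
#' 4x4 collection for the self-procuring districts, monthly 4x4 collection
#' from regional stores by districts, and monthly vaccine-carrier
#' collection from district stores by clinics. Capacities follow the
#' calibration constants applied to expected baseline flows computed from
#' `catalog`.
#'
#' @param params A `fixture_params`.
#' @param catalog Baseline catalog used to size capacities (active
#'   presentations only).
#' @return A validated `vax_network` whose clinic rows carry demand
#'   `share` weights.
#' @export
generate_network <- function(params = fixture_params(),
                             catalog = load_vaccine_catalog()) {
  set.seed(params$seed)
  act <- active_presentations(catalog)
  frz <- act$storage_class == "freezer"
  vol_child_ref <- sum((act$doses_per_person * act$packed_vol_per_dose)[!frz])
  vol_child_frz <- sum((act$doses_per_person * act$packed_vol_per_dose)[frz])
  cal <- params$calibration

  nR <- params$n_regional; nD <- params$n_district; nC <- params$n_clinics
  shares <- stats::rlnorm(nC, meanlog = -params$share_sdlog^2 / 2,
                          sdlog = params$share_sdlog)
  shares <- shares / sum(shares)
  clinic_ids <- sprintf("IHC%04d", seq_len(nC))
  district_ids <- sprintf("D%03d", seq_len(nD))
  region_ids <- sprintf("R%02d", seq_len(nR))

  district_of <- sample(rep_len(seq_len(nD), nC))
  region_of <- rep_len(seq_len(nR), nD)   # district -> region
  direct <- seq_len(nD) <= params$n_direct_districts
  storeless <- integer(0)
  if (params$storage_less_district) {
    storeless <- which(!direct)[1L]       # one supplied district, no storage
  }

  monthly <- function(ann_share) {
    c(ref = ann_share * params$annual_births * vol_child_ref / 12,
      frz = ann_share * params$annual_births * vol_child_frz / 12)
  }
  clinic_mean_m <- monthly(1 / nC)
  district_share <- vapply(seq_len(nD),
                           function(d) sum(shares[district_of == d]), 0)
  region_through <- vapply(seq_len(nR), function(r)
    sum(district_share[region_of == r & !direct]), 0)

  locations <- list(list(
    id = "CEN", level = "central",
    devices = list(
      list(id = "CEN-CR", kind = "cold_room",
           capacity_cm3 = cal$central_store * sum(monthly(1))),
      list(id = "CEN-FR", kind = "freezer",
           capacity_cm3 = cal$central_store * monthly(1)[["frz"]] * 3)
    )))
  for (r in seq_len(nR)) {
    m <- monthly(region_through[r])
    locations[[length(locations) + 1L]] <- list(
      id = region_ids[r], level = "regional",
      devices = list(
        list(id = paste0(region_ids[r], "-CR"), kind = "cold_room",
             capacity_cm3 = max(1, cal$regional_store * m[["ref"]])),
        list(id = paste0(region_ids[r], "-FR"), kind = "freezer",
             capacity_cm3 = max(1, cal$regional_store * m[["frz"]]))
      ))
  }
  for (d in seq_len(nD)) {
    m <- monthly(district_share[d])
    devs <- if (d %in% storeless) list() else list(
      list(id = paste0(district_ids[d], "-RF"), kind = "refrigerator",
           capacity_cm3 = max(1, cal$district_store * m[["ref"]])),
      list(id = paste0(district_ids[d], "-FR"), kind = "freezer",
           capacity_cm3 = max(1, cal$district_store * m[["frz"]]))
    )
    locations[[length(locations) + 1L]] <- list(
      id = district_ids[d], level = "district", devices = devs)
  }
  for (i in seq_len(nC)) {
    locations[[length(locations) + 1L]] <- list(
      id = clinic_ids[i], level = "clinic", share = shares[i],
      devices = list(
        list(id = paste0(clinic_ids[i], "-RF"), kind = "refrigerator",
             capacity_cm3 = cal$clinic_store * clinic_mean_m[["ref"]]),
        list(id = paste0(clinic_ids[i], "-FR"), kind = "freezer",
             capacity_cm3 = cal$clinic_store * clinic_mean_m[["frz"]])
      ))
  }

  routes <- list()
  # two cold-truck delivery loops over the regional stores
  if (nR > 0) {
    half <- ceiling(nR / 2)
    loops <- list(seq_len(half), if (nR > half) (half + 1):nR else integer(0))
    for (k in seq_along(loops)) {
      if (!length(loops[[k]])) next
      loop_m <- sum(vapply(loops[[k]],
                           function(r) sum(monthly(region_through[r])), 0))
      routes[[length(routes) + 1L]] <- list(
        id = sprintf("LOOP%d", k), origin = "CEN",
        stops = as.list(region_ids[loops[[k]]]),
        vehicle = list(kind = "cold_truck",
                       capacity_cm3 = max(1, cal$cold_truck * loop_m)),
        trips_per_year = 4, mode = "delivery", loss_prob = 0.01)
    }
  }
  # the storage-less district keeps its supply route (its orders are always
  # zero -- nothing can be stored -- but the location stays connected);
  # its clinics collect from the regional store instead
  district_mean_m <- sum(monthly(1)) / nD
  for (d in seq_len(nD)) {
    org <- if (direct[d]) "CEN" else region_ids[region_of[d]]
    routes[[length(routes) + 1L]] <- list(
      id = paste0("SUP-", district_ids[d]), origin = org,
      stops = list(district_ids[d]),
      vehicle = list(kind = "four_by_four",
                     capacity_cm3 = cal$four_by_four * district_mean_m),
      trips_per_year = 12, mode = "collection", loss_prob = 0.01)
  }
  carrier_cap <- cal$carrier * sum(clinic_mean_m)
  for (i in seq_len(nC)) {
    d <- district_of[i]
    org <- if (d %in% storeless) region_ids[region_of[d]] else district_ids[d]
    routes[[length(routes) + 1L]] <- list(
      id = paste0("CAR-", clinic_ids[i]), origin = org,
      stops = list(clinic_ids[i]),
      vehicle = list(kind = "vaccine_carrier", capacity_cm3 = carrier_cap),
      trips_per_year = 12, mode = "collection", loss_prob = 0.01)
  }
  network_from_list(list(locations = locations, routes = routes))
}

#' Demand model matching a generated network
#'
#' @param network A network from [generate_network()] (clinic rows carry
#'   `share` weights).
#' @param params The `fixture_params` used to generate it.
#' @param target_fraction,mode Passed to [demand_model()].
#' @return A `vax_demand`.
#' @export
fixture_demand <- function(network, params = fixture_params(),
                           target_fraction = 1.0,
                           mode = c("dynamic", "static")) {
  cl <- network$locations$level == "clinic"
  demand_model(annual_births = params$annual_births,
               clinic_shares = stats::setNames(network$locations$share[cl],
                                               network$locations$id[cl]),
               target_fraction = target_fraction,
               mode = match.arg(mode),
               sessions_per_month = params$sessions_per_month)
}

#' Miniature fixture parameters
#'
#' A small network (1 region, 2 districts, 10 clinics by default) for unit
#' tests and desk-scale experiments; demand scales with clinic count so
#' per-clinic session sizes match the full fixture.
#'
#' @param n_clinics,n_district,n_regional Tier sizes.
#' @param ... Passed to [fixture_params()].
#' @return A `fixture_params`.
#' @export
mini_params <- function(n_clinics = 10L, n_district = 2L, n_regional = 1L,
                        ...) {
  fixture_params(n_regional = n_regional, n_district = n_district,
                 n_clinics = n_clinics,
                 n_direct_districts = 0L, storage_less_district = FALSE, ...)
}

#' Generate the scenario suite
#'
#' The core experimental grid: measles vial sizes {10, 5, 2, 1} crossed
#' with target population fractions {1.0, 0.8, 0.6} (12 scenarios), under
#' the baseline operating conditions (dynamic monthly demand, 1% shipping
#' and inventory loss). With `sensitivity = TRUE`, adds the sensitivity
#' axes: loss rates 0 and 2%, and static demand, each varied from
#' baseline.
#'
#' @param vial_sizes,target_fractions Grid axes.
#' @param sensitivity Include sensitivity-axis scenarios?
#' @return A list of scenario config lists (`vial_size`,
#'   `target_fraction`, `demand_mode`, `shipping_loss`, `inventory_loss`,
#'   `id`).
#' @export
generate_scenario_suite <- function(vial_sizes = c(10, 5, 2, 1),
                                    target_fractions = c(1.0, 0.8, 0.6),
                                    sensitivity = FALSE) {
  grid <- expand.grid(vial_size = vial_sizes,
                      target_fraction = target_fractions)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    list(id = sprintf("M%02d_tf%03d", grid$vial_size[i],
                      round(100 * grid$target_fraction[i])),
         vial_size = grid$vial_size[i],
         target_fraction = grid$target_fraction[i],
         demand_mode = "dynamic", shipping_loss = 0.01,
         inventory_loss = 0.01)
  })
  if (sensitivity) {
    base <- out[[1L]]
    for (sl in c(0, 0.02)) {
      v <- base; v$shipping_loss <- sl; v$inventory_loss <- sl
      v$id <- sprintf("M10_tf100_loss%03d", round(100 * sl))
      out[[length(out) + 1L]] <- v
    }
    v <- base; v$demand_mode <- "static"; v$id <- "M10_tf100_static"
    out[[length(out) + 1L]] <- v
  }
  out
}
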