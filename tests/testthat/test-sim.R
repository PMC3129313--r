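test_that("identical seeds give bit-identical simulations", {
  md <- mini_network_and_demand()
  cat0 <- load_vaccine_catalog()
  s1 <- run_simulation(md$network, cat0, md$demand,
                       sim_config(replications = 2, seed = 7))
  s2 <- run_simulation(md$network, cat0, md$demand,
                       sim_config(replications = 2, seed = 7))
  expect_identical(s1$replications, s2$replications)
  s3 <- run_simulation(md$network, cat0, md$demand,
                       sim_config(replications = 2, seed = 8))
  expect_false(identical(s1$replications, s3$replications))
})

test_that("with ample capacity, stock and no losses, availability is 100%", {
  cat0 <- load_vaccine_catalog()
  p <- mini_params(n_clinics = 1L, n_district = 1L,
                   calibration = list(carrier = 50, four_by_four = 50,
                                      cold_truck = 50, clinic_store = 50,
                                      district_store = 50,
                                      regional_store = 50,
                                      central_store = 50))
  net <- generate_network(p, cat0)
  dem <- fixture_demand(net, p)
  sim <- run_simulation(net, cat0, dem,
                        sim_config(replications = 2, seed = 2,
                                   shipping_loss = 0, inventory_loss = 0,
                                   order_months = c(central = 16,
                                                    regional = 14,
                                                    district = 14,
                                                    clinic = 14)))
  expect_equal(sim$summary$availability$availability,
               rep(1, length(sim$antigens)))
})

test_that("no storage device or vehicle ever exceeds its net capacity", {
  md <- mini_network_and_demand()
  sim <- run_simulation(md$network, load_vaccine_catalog(), md$demand,
                        sim_config(replications = 2, seed = 4))
  for (r in sim$replications) {
    expect_true(all(r$storage_refrigerated <= 1 + 1e-9, na.rm = TRUE))
    expect_true(all(r$storage_frozen <= 1 + 1e-9, na.rm = TRUE))
    expect_true(all(r$trip_log[, "actual"] <= 1 + 1e-9))
    # demand-requested utilization is never below the actual
    expect_true(all(r$trip_log[, "requested"] >=
                      r$trip_log[, "actual"] - 1e-9))
  }
})

test_that("dose conservation holds exactly in every replication", {
  md <- mini_network_and_demand()
  sim <- run_simulation(md$network, load_vaccine_catalog(), md$demand,
                        sim_config(replications = 3, seed = 6))
  cons <- sim$summary$conservation
  expect_equal(cons$supplied, cons$accounted)
})

test_that("an infeasible configuration fails before simulating", {
  cat0 <- load_vaccine_catalog()
  raw <- list(
    locations = list(
      list(id = "CEN", level = "central",
           devices = list(list(id = "c", kind = "cold_room",
                               capacity_cm3 = 1e7))),
      list(id = "C1", level = "clinic", share = 1,
           devices = list(list(id = "r", kind = "refrigerator",
                               capacity_cm3 = 1e5)))
    ),
    routes = list(list(id = "t", origin = "CEN", stops = list("C1"),
                       vehicle = list(kind = "vaccine_carrier",
                                      capacity_cm3 = 1e5),
                       trips_per_year = 12, mode = "collection",
                       loss_prob = 0))
  )
  net <- network_from_list(raw)
  dem <- demand_model(annual_births = 1000, clinic_shares = c(C1 = 1))
  # OPV needs frozen storage and no freezer exists anywhere
  expect_error(run_simulation(net, cat0, dem,
                              sim_config(replications = 1, seed = 1)),
               "pre-flight error")
})

test_that("static demand removes arrival-count stochasticity", {
  md <- mini_network_and_demand(mode = "static")
  sim <- run_simulation(md$network, load_vaccine_catalog(), md$demand,
                        sim_config(replications = 2, seed = 9))
  r1 <- sim$replications[[1]]; r2 <- sim$replications[[2]]
  expect_identical(r1$arrivals, r2$arrivals)
  ann <- colSums(r1$arrivals)
  act <- active_presentations(load_vaccine_catalog())
  expected <- md$demand$annual_births * act$doses_per_person
  expect_equal(unname(ann), expected, tolerance = 0.005)
})
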