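cat0 <- load_vaccine_catalog()
costs <- load_cost_inputs()
act <- active_presentations(cat0)
m10 <- act[act$antigen == "M", ]

test_that("administration cost follows the published equation", {
  # ten doses from one reconstituted 10-dose vial
  expect_equal(administration_cost(10, 1, costs, m10),
               10 * (0.246 + 0.07) + 0.06)
  expect_equal(administration_cost(0, 0, costs, m10), 0)
  c1 <- active_presentations(substitute_presentation(cat0, "M", 1))
  m1 <- c1[c1$antigen == "M", ]
  expect_equal(administration_cost(1, 1, costs, m1), 0.943 + 0.07 + 0.06)
  # liquid vaccines take no reconstitution syringe; oral ones no syringe
  tt <- act[act$antigen == "TT", ]
  tt$price_per_dose <- 0.1
  expect_equal(administration_cost(10, 1, costs, tt), 10 * (0.1 + 0.07))
  opv <- act[act$antigen == "OPV", ]
  opv$price_per_dose <- 0.1
  expect_equal(administration_cost(10, 1, costs, opv), 10 * 0.1)
})

test_that("the unknown 2-dose price fails loudly everywhere it is touched", {
  c2 <- active_presentations(substitute_presentation(cat0, "M", 2))
  m2 <- c2[c2$antigen == "M", ]
  expect_error(administration_cost(10, 1, costs, m2), "missing-price")
  expect_error(wasted_dose_cost(5, m2$price_per_dose), "missing-price")
})

test_that("wasted-dose cost is price times count", {
  expect_equal(wasted_dose_cost(0, 0.246), 0)
  expect_equal(wasted_dose_cost(100, 0.246), 24.60)
})

test_that("disposal cost weighs vials and syringes at the per-gram rate", {
  # one 10-dose vial + 1 reconstitution + 10 injection syringes
  d <- suppressWarnings(disposal_cost(c("10" = 1), 1, 10, 10, costs))
  expect_equal(d, 0.0069 * (3.522 + 6.625 + 10 * 6.625), tolerance = 1e-9)
  expect_equal(d, 0.527, tolerance = 1e-3)
  expect_equal(suppressWarnings(disposal_cost(c("10" = 0), 0, 0, 0, costs)), 0)
  # per-kg and per-g rates agree within their printed rounding
  per_kg <- costs$disposal_cost_per_kg / 1000 * (3.522 + 6.625 + 66.25)
  expect_equal(d, per_kg, tolerance = 0.01)
  expect_warning(disposal_cost(c("10" = 1), 1, 10, 10, costs), "safety box")
})

test_that("cost per injection reproduces the published figures", {
  expect_equal(cost_per_injection(244759, 583575 - 58482), 0.47)
  expect_equal(cost_per_injection(586214, 583264 - 117167), 1.26)
  expect_equal(cost_per_injection(42, 1), 42)
  expect_true(is.na(cost_per_injection(10, 0)))
})

test_that("single-dose scenarios cost administration + disposal exactly", {
  md <- mini_network_and_demand()
  c1 <- substitute_presentation(cat0, "M", 1)
  sim <- run_simulation(md$network, c1, md$demand,
                        sim_config(replications = 2, seed = 5))
  br <- suppressWarnings(scenario_costs(sim))
  expect_equal(br$wasted_dose_cost, 0)
  expect_equal(br$total, br$administration_cost + br$disposal_cost)
  expect_equal(br$cost_per_injection,
               round(br$total / br$doses_administered, 2))
})
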