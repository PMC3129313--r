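test_that("bundled catalog matches the published vaccine characteristics", {
  cat0 <- load_vaccine_catalog()
  m10 <- cat0[cat0$antigen == "M" & cat0$doses_per_vial == 10, ]
  expect_equal(m10$packed_vol_per_dose, 2.6)
  expect_equal(m10$diluent_vol_per_dose, 0.5)
  expect_true(m10$active)
  # freezer storage is OPV only
  expect_identical(cat0$antigen[cat0$storage_class == "freezer"], "OPV")
  # per-dose packed volume grows as measles vials shrink
  m <- cat0[cat0$antigen == "M", ]
  m <- m[order(-m$doses_per_vial), ]
  expect_identical(m$doses_per_vial, c(10, 5, 2, 1))
  expect_true(all(diff(m$packed_vol_per_dose) > 0))
  # formulation split drives the MDVP rule
  expect_setequal(cat0$antigen[cat0$formulation == "lyophilized"],
                  c("BCG", "YF", "M"))
  # 2-dose measles price is explicitly missing, never imputed
  expect_true(is.na(m$price_per_dose[m$doses_per_vial == 2]))
})

test_that("catalog loading rejects bad inputs with named schema errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("", f)
  expect_error(load_vaccine_catalog(f), "schema error")
  cat0 <- load_vaccine_catalog()
  g <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(cat0[, setdiff(names(cat0), "packed_vol_per_dose")], g,
                   row.names = FALSE)
  expect_error(load_vaccine_catalog(g), "packed_vol_per_dose")
  bad <- cat0
  bad$doses_per_vial[1] <- 0
  h <- withr::local_tempfile(fileext = ".csv")
  write_vaccine_catalog(bad, h)
  expect_error(load_vaccine_catalog(h), "doses_per_vial")
})

test_that("catalog round-trips through CSV identically", {
  cat0 <- load_vaccine_catalog()
  f <- withr::local_tempfile(fileext = ".csv")
  write_vaccine_catalog(cat0, f)
  expect_equal(load_vaccine_catalog(f), cat0)
})

test_that("vial-size substitution activates the target and nothing else", {
  cat0 <- load_vaccine_catalog()
  c1 <- substitute_presentation(cat0, "M", 1)
  a1 <- active_presentations(c1)
  expect_equal(a1$packed_vol_per_dose[a1$antigen == "M"], 26.1)
  expect_equal(a1$price_per_dose[a1$antigen == "M"], 0.943)
  expect_equal(a1[a1$antigen != "M", ],
               active_presentations(cat0)[a1$antigen != "M", ])
  # identity substitution changes nothing
  expect_equal(substitute_presentation(cat0, "M", 10), cat0)
  # idempotent, and invertible by substituting back
  expect_equal(substitute_presentation(c1, "M", 1), c1)
  expect_equal(substitute_presentation(c1, "M", 10), cat0)
  expect_error(substitute_presentation(cat0, "M", 3), "lookup error")
  expect_error(substitute_presentation(cat0, "XYZ", 10), "lookup error")
})

test_that("cost-year adjustment compounds at the discount rate", {
  expect_equal(adjust_cost_year(100, 2011, 2011, 0.03), 100)
  expect_equal(adjust_cost_year(100, 2010, 2011, 0.03), 103)
  # frozen from direct evaluation of 100 * 1.03^6
  expect_equal(adjust_cost_year(100, 2004, 2010, 0.03), 119.405230, tolerance = 1e-6)
  expect_lt(adjust_cost_year(100, 2011, 2004, 0.03), 100)  # deflation
})

test_that("cost inputs carry the published masses and unit costs", {
  costs <- load_cost_inputs()
  expect_equal(unname(costs$vial_mass_g[c("10", "5", "1")]),
               c(3.522, 2.517, 1.713))
  expect_equal(costs$recon_syringe_mass_g, 6.625)
  expect_equal(costs$disposal_cost_per_g, 0.0069)
  # per-g and per-kg disposal rates agree within rounding
  expect_equal(costs$disposal_cost_per_kg / 1000, costs$disposal_cost_per_g,
               tolerance = 0.01)
  expect_true(is.na(costs$safety_box_cost_per_dose))
})
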