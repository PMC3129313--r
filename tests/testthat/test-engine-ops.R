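cat0 <- load_vaccine_catalog()

batch <- function(antigen, n, arrival = 0, expiry = 730) {
  data.frame(antigen = antigen, n = n, arrival = arrival, expiry = expiry,
             stringsAsFactors = FALSE)
}

test_that("inventory balance: previous + arrivals - removals", {
  inv <- batch("M", 10)
  r <- update_inventory(inv, arrivals = batch("M", 5, arrival = 1),
                        removals = batch("M", 3))
  expect_equal(sum(r$inventory$n), 12)
  # no events: unchanged
  expect_equal(update_inventory(inv)$inventory$n, 10)
  # removing absent vials is a bug trap
  expect_error(update_inventory(inv, removals = batch("M", 11)),
               "internal consistency error")
  expect_error(update_inventory(inv, removals = batch("YF", 1)),
               "internal consistency error")
})

test_that("arrivals into a full store are rejected, not squeezed in", {
  inv <- batch("M", 0)[0, ]
  r <- update_inventory(inv, arrivals = batch("M", 5), catalog = cat0,
                        capacity = 0)
  expect_equal(nrow(r$inventory), 0L)
  expect_equal(sum(r$rejected$n), 5)
  # partial space admits FIFO-first arrivals
  vol <- 26  # one 10-dose measles vial
  r2 <- update_inventory(inv, arrivals = rbind(batch("M", 1, arrival = 1),
                                               batch("M", 1, arrival = 2)),
                         catalog = cat0, capacity = vol)
  expect_equal(sum(r2$inventory$n), 1)
  expect_equal(r2$inventory$arrival, 1)
  expect_equal(r2$rejected$arrival, 2)
})

test_that("balanced allocation fills complete regimens first", {
  act <- active_presentations(cat0)
  inc <- stats::setNames(rep(10, nrow(act)), act$antigen)
  big <- allocate_limited_space(inc, 1e9, cat0)
  expect_equal(big$accepted, inc)              # ample space: all accepted
  none <- allocate_limited_space(inc, 0, cat0)
  expect_equal(unname(none$accepted), rep(0, length(inc)))  # zero space
  # space for exactly one regimen-unit: one vial-mix of every antigen,
  # none doubled (two children's worth offered)
  w <- act$doses_per_person / act$doses_per_vial
  one_unit <- ceiling(w)
  vol_needed <- sum(one_unit * act$doses_per_vial * act$packed_vol_per_dose)
  two <- stats::setNames(ceiling(2 * w), act$antigen)
  got <- allocate_limited_space(two, vol_needed, cat0)
  expect_equal(unname(got$accepted), unname(one_unit))
})

test_that("allocation respects per-temperature-class volumes", {
  inc <- c(OPV = 10, M = 10)
  r <- allocate_limited_space(inc, c(refrigerated = 1e9, frozen = 0), cat0)
  expect_equal(unname(r$accepted["OPV"]), 0)   # freezer vaccine, no freezer
  expect_equal(unname(r$accepted["M"]), 10)
})

test_that("reorder rule: 25% trigger, 25% buffer, rounded up", {
  expect_equal(unname(compute_order(c(M = 26), c(M = 100))), 0)  # above s
  expect_equal(unname(compute_order(c(M = 0), c(M = 100))), 125)
  expect_equal(unname(compute_order(c(M = 20), c(M = 100))),
               ceiling((100 - 20) * 1.25))
  # per-antigen triggering: only depleted antigens ordered
  o <- compute_order(c(M = 10, YF = 90), c(M = 100, YF = 100))
  expect_equal(unname(o), c(ceiling(90 * 1.25), 0))
})

test_that("shipment loading: FIFO draw, 200% overfill, backlog", {
  act <- active_presentations(cat0)
  vol <- act$packed_vol_per_dose[act$antigen == "M"] *
    act$doses_per_vial[act$antigen == "M"]
  stock <- rbind(batch("M", 60, arrival = 1), batch("M", 60, arrival = 2))
  s <- load_shipment(c(M = 100), stock, vehicle_capacity = 50 * vol,
                     catalog = cat0)
  expect_equal(unname(s$requested_utilization), 2.0)   # the 200% example
  expect_equal(unname(s$actual_utilization), 1.0)
  expect_equal(sum(s$loaded$n), 50)
  expect_equal(unname(s$backlog["M"]), 50)
  # FIFO: the oldest batch ships first
  expect_equal(s$loaded$arrival, 1)
  expect_equal(s$origin_stock$n[s$origin_stock$arrival == 1], 10)
  # order fits: no backlog, utilization below 100%
  s2 <- load_shipment(c(M = 10), stock, 50 * vol, cat0)
  expect_equal(unname(s2$backlog["M"]), 0)
  expect_equal(unname(s2$requested_utilization), 10 / 50)
  # empty origin: nothing ships, order fully re-queued
  s3 <- load_shipment(c(M = 10), stock[0, ], 50 * vol, cat0)
  expect_equal(nrow(s3$loaded), 0L)
  expect_equal(unname(s3$backlog["M"]), 10)
  expect_equal(unname(s3$requested_utilization), 10 / 50)
})

test_that("random loss is Bernoulli per vial", {
  v <- batch("M", 1000)
  expect_equal(apply_random_loss(v, 0)$surviving$n, 1000)
  expect_equal(nrow(apply_random_loss(v, 1)$surviving), 0L)
  set.seed(11)
  big <- rbind(batch("M", 50000), batch("M", 50000, arrival = 1))
  lost <- apply_random_loss(big, 0.01)$n_lost[["M"]]
  expect_lt(abs(lost - 1000), 3 * sqrt(1000 * 0.99))  # binomial moments
})

test_that("expiry removal separates shelf-life and open-vial wastage", {
  inv <- rbind(batch("M", 2, expiry = 100), batch("M", 3, expiry = 300))
  r <- remove_expired(inv, now = 100)
  expect_equal(sum(r$discarded$n), 2)
  expect_equal(sum(r$inventory$n), 3)
  r2 <- remove_expired(inv, now = 50)
  expect_equal(nrow(r2$discarded), 0L)
  # open liquid vial at opened_time + 29 days: removed, remaining doses
  # counted as open-vial waste
  open <- data.frame(antigen = "TT", doses_left = 7, expiry = 20 + 28)
  r3 <- remove_expired(inv[0, ], open, now = 20 + 29)
  expect_equal(r3$open_waste_doses, 7)
  expect_equal(nrow(r3$open_vials), 0L)
})
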