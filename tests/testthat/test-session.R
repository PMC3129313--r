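cat0 <- load_vaccine_catalog()

test_that("MDVP traces: lyophilized discard, single-dose zero waste", {
  inv <- data.frame(antigen = "M", n = 1, arrival = 0, expiry = 730)
  s <- run_session(c(M = 2), inv, cat0, day = 1)
  m <- s$outcome[s$outcome$antigen == "M", ]
  expect_equal(m$administered, 2)
  expect_equal(m$open_vial_waste, 8)   # 10-dose vial, 2 doses drawn
  expect_equal(m$vials_opened, 1)
  expect_equal(nrow(s$open_vials), 0L) # lyophilized never persists
  # single-dose measles: no vial can be partially used
  c1 <- substitute_presentation(cat0, "M", 1)
  inv1 <- data.frame(antigen = "M", n = 40, arrival = 0, expiry = 730)
  s1 <- run_session(c(M = 37), inv1, c1, day = 1)
  m1 <- s1$outcome[s1$outcome$antigen == "M", ]
  expect_equal(m1$administered, 37)
  expect_equal(m1$open_vial_waste, 0)
  expect_equal(m1$vials_opened, 37)
})

test_that("open liquid vials persist and later sessions finish them", {
  # 10-dose liquid TT: 2 arrivals now, 8 a week later -> no waste at all
  inv <- data.frame(antigen = "TT", n = 1, arrival = 0, expiry = 730)
  s1 <- run_session(c(TT = 2), inv, cat0, day = 1)
  expect_equal(s1$open_vials$doses_left, 8)
  expect_equal(s1$open_vials$expiry, 1 + 28)
  s2 <- run_session(c(TT = 8), s1$inventory, cat0,
                    open_vials = s1$open_vials, day = 8)
  t2 <- s2$outcome[s2$outcome$antigen == "TT", ]
  expect_equal(t2$administered, 8)
  expect_equal(t2$vials_opened, 0)
  expect_equal(s1$outcome$open_vial_waste[s1$outcome$antigen == "TT"] +
                 t2$open_vial_waste, 0)
  # but an open vial past 28 days is discarded before use
  s3 <- run_session(c(TT = 1), inv, cat0,
                    open_vials = data.frame(antigen = "TT", doses_left = 5,
                                            expiry = 29),
                    day = 30)
  t3 <- s3$outcome[s3$outcome$antigen == "TT", ]
  expect_equal(t3$open_vial_waste, 5)
  expect_equal(t3$vials_opened, 1)   # fresh vial opened instead
})

test_that("stock-outs are recorded as missed opportunities", {
  s <- run_session(c(M = 5, YF = 3),
                   data.frame(antigen = "M", n = 0, arrival = 0,
                              expiry = 730)[0, ], cat0, day = 1)
  expect_equal(s$outcome$missed[s$outcome$antigen == "M"], 5)
  expect_equal(s$outcome$missed[s$outcome$antigen == "YF"], 3)
  expect_true(all(s$outcome$administered + s$outcome$missed ==
                    s$outcome$arrivals))
})

test_that("sealed vials are opened first-in-first-out", {
  inv <- data.frame(antigen = "M", n = c(1, 1), arrival = c(5, 2),
                    expiry = c(400, 300))
  # after drawing 2 doses (one vial opened), the surviving sealed vial
  # must be the later arrival
  s2 <- run_session(c(M = 2), inv, cat0, day = 10)
  expect_equal(s2$inventory$arrival, 5)  # older (arrival 2) consumed first
})

test_that("session core matches the brute-force per-dose oracle", {
  # randomized smoke over all four measles presentations (the full
  # 1000-session equivalence sweep lives in the acceptance suite)
  set.seed(20260928)
  for (vs in c(10, 5, 2, 1)) {
    cs <- substitute_presentation(cat0, "M", vs)
    act <- active_presentations(cs)
    mism <- 0L
    for (j in seq_len(30)) {
      st <- random_session_state(act)
      orc <- oracle_session(st$need, st$inventory, st$open, 100, act)
      rs <- state_to_run_session(st, act)
      got <- run_session(stats::setNames(st$need, act$antigen),
                         rs$inventory, cs, rs$open, day = 100)
      for (a in seq_len(nrow(act))) {
        o <- orc[[a]]; g <- got$outcome[a, ]
        if (g$administered != o$administered || g$missed != o$missed ||
            g$vials_opened != o$vials_opened ||
            g$open_vial_waste != o$open_vial_waste) mism <- mism + 1L
      }
    }
    expect_equal(mism, 0L)
  }
})
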