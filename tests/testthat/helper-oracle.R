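# Independent brute-force oracle for the Multi-Dose Vial Policy session
# rules: replays every dose one at a time against an explicit vial list,
# with no shared code with the engine's vectorized session core.
#
# inventory: list per antigen of data.frame(arrival, expiry), one row per
# sealed vial, FIFO order. open: list per antigen of NULL or
# list(doses, expiry).
oracle_session <- function(need, inventory, open, day, act) {
  out <- list()
  for (a in seq_along(need)) {
    dpv <- act$doses_per_vial[a]
    lyo <- act$formulation[a] == "lyophilized"
    vials <- inventory[[a]]
    op <- open[[a]]
    administered <- 0; missed <- 0; opened <- 0; waste <- 0
    if (!is.null(op) && op$expiry <= day) {
      waste <- waste + op$doses
      op <- NULL
    }
    n <- need[a]
    while (n > 0) {
      if (!is.null(op) && op$doses > 0) {
        op$doses <- op$doses - 1
        administered <- administered + 1
      } else if (nrow(vials) > 0) {
        if (!is.null(op)) waste <- waste + op$doses  # drained, zero doses
        v <- vials[1, ]
        vials <- vials[-1, , drop = FALSE]
        opened <- opened + 1
        op <- list(doses = dpv - 1,
                   expiry = min(day + act$open_vial_days[a], v$expiry))
        administered <- administered + 1
      } else {
        if (!is.null(op) && op$doses == 0) op <- NULL
        missed <- missed + 1
      }
      n <- n - 1
    }
    # session end: MDVP disposal
    if (!is.null(op)) {
      if (lyo || op$doses == 0) {
        waste <- waste + op$doses
        op <- NULL
      }
    }
    out[[a]] <- list(administered = administered, missed = missed,
                     vials_opened = opened, open_vial_waste = waste,
                     inventory = vials, open = op)
  }
  out
}

# Random session-state generator shared by the oracle-equivalence tests.
random_session_state <- function(act, max_arrivals = 50, day = 100) {
  A <- nrow(act)
  need <- stats::rpois(A, stats::runif(A, 0, max_arrivals / 3))
  need <- pmin(need, max_arrivals)
  inventory <- lapply(seq_len(A), function(a) {
    k <- sample(0:8, 1)
    if (k == 0) return(data.frame(arrival = numeric(0), expiry = numeric(0)))
    arr <- sort(stats::runif(k, 0, day))
    data.frame(arrival = arr, expiry = arr + 730)
  })
  open <- lapply(seq_len(A), function(a) {
    if (stats::runif(1) < 0.3 && act$doses_per_vial[a] > 1) {
      list(doses = sample(seq_len(act$doses_per_vial[a] - 1), 1),
           expiry = day + sample(c(-3, 2, 10), 1))
    } else NULL
  })
  list(need = need, inventory = inventory, open = open)
}

# convert oracle-style state to run_session() inputs
state_to_run_session <- function(st, act) {
  inv <- do.call(rbind, lapply(seq_len(nrow(act)), function(a) {
    v <- st$inventory[[a]]
    if (!nrow(v)) return(NULL)
    data.frame(antigen = act$antigen[a], n = 1, arrival = v$arrival,
               expiry = v$expiry, stringsAsFactors = FALSE)
  }))
  if (is.null(inv)) {
    inv <- data.frame(antigen = character(), n = numeric(),
                      arrival = numeric(), expiry = numeric())
  }
  keep <- !vapply(st$open, is.null, TRUE)
  open_df <- if (any(keep)) {
    data.frame(antigen = act$antigen[keep],
               doses_left = vapply(st$open[keep], function(o) o$doses, 0),
               expiry = vapply(st$open[keep], function(o) o$expiry, 0),
               stringsAsFactors = FALSE)
  } else NULL
  list(inventory = inv, open = open_df)
}

mini_network_and_demand <- function(target_fraction = 1, mode = "dynamic",
                                    ...) {
  p <- mini_params(...)
  net <- generate_network(p, load_vaccine_catalog())
  list(params = p, network = net,
       demand = fixture_demand(net, p, target_fraction, mode))
}
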