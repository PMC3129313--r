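# The clinic-session core: Multi-Dose Vial Policy accounting.
#
# For each antigen, arriving children draw doses first from an
# already-open vial (if it still holds usable doses), then from sealed
# vials opened first-in-first-out; a child whose antigen is out of stock
# is a missed vaccination opportunity and does not re-queue. At session
# end, open lyophilized vials are discarded (remaining doses become
# open-vial wastage); open liquid vials persist for up to 28 days after
# opening. Single-dose vials can never be partially used, so their
# open-vial wastage is identically zero.
#
# `mdvp_session()` operates on the lean per-clinic state the simulation
# loop keeps (vectorized over antigens); the exported `run_session()`
# wraps it with data-frame inputs and outputs.

# pars: list with vectors over antigens: dpv, lyophilized (logical),
#   open_days (NA for lyophilized).
# state: list(batches = list of FIFO matrices, stock = vials on hand,
#   open_d = doses left in the open vial, open_e = its removal day).
mdvp_session <- function(state, need, day, pars) {
  dpv <- pars$dpv
  open_d <- state$open_d
  open_e <- state$open_e
  ovw <- numeric(length(need))

  # open vials past their lifetime are discarded before use
  stale <- open_d > 0 & open_e <= day
  if (any(stale)) {
    ovw[stale] <- ovw[stale] + open_d[stale]
    open_d[stale] <- 0
  }

  use_open <- pmin(need, open_d)
  open_d <- open_d - use_open
  rem <- need - use_open
  vn <- ceiling(rem / dpv)
  open_v <- pmin(vn, state$stock)
  from_new <- pmin(rem, open_v * dpv)
  administered <- use_open + from_new
  missed <- need - administered
  left <- open_v * dpv - from_new      # doses left in the last vial opened

  last_exp <- rep(NA_real_, length(need))
  for (a in which(open_v > 0)) {
    tk <- fifo_take(state$batches[[a]], open_v[a])
    state$batches[[a]] <- tk$rest
    last_exp[a] <- tk$last_expiry
  }
  state$stock <- state$stock - open_v

  # session end: MDVP disposal rules
  lyo <- pars$lyophilized
  ovw[lyo] <- ovw[lyo] + left[lyo] + open_d[lyo]
  open_d[lyo] <- 0
  liq_new <- !lyo & left > 0
  open_d[liq_new] <- left[liq_new]
  open_e[liq_new] <- pmin(day + pars$open_days[liq_new], last_exp[liq_new])
  open_e[open_d == 0] <- Inf

  state$open_d <- open_d
  state$open_e <- open_e
  list(state = state,
       outcome = list(arrivals = need, administered = administered,
                      missed = missed, vials_opened = open_v,
                      open_vial_waste = ovw))
}

#' Run one clinic immunization session
#'
#' Applies the WHO Multi-Dose Vial Policy to one session's arrivals: doses
#' are drawn from an already-open vial when one holds doses, else the
#' first-in-first-out next sealed vial is opened, else the opportunity is
#' missed. At session end open lyophilized vials are discarded (remaining
#' doses counted as open-vial wastage); open liquid vials persist to later
#' sessions until 28 days after opening.
#'
#' @param arrivals Data frame of arriving children with a `visit` column
#'   (as from [session_arrivals()]), or a named numeric vector of dose
#'   demand per antigen.
#' @param inventory Sealed-vial batch data frame: `antigen`, `n`,
#'   `arrival`, `expiry`.
#' @param catalog A `vax_catalog`; its active presentations define doses
#'   per vial, formulation and open-vial lifetime.
#' @param open_vials Data frame of vials already open at session start:
#'   `antigen`, `doses_left`, `expiry` (at most one per antigen); or
#'   `NULL`.
#' @param day Simulation day of the session.
#' @return A list with:
#'   \describe{
#'     \item{outcome}{data frame per antigen: `arrivals`, `administered`,
#'       `missed`, `vials_opened`, `open_vial_waste` (doses).}
#'     \item{inventory}{updated sealed-vial batches.}
#'     \item{open_vials}{open vials persisting past the session.}
#'   }
#' @export
#' @examples
#' cat <- load_vaccine_catalog()
#' inv <- data.frame(antigen = "M", n = 1, arrival = 0, expiry = 730)
#' s <- run_session(c(M = 2), inv, cat, day = 1)
#' s$outcome[s$outcome$antigen == "M", ]  # 2 administered, 8 doses wasted
run_session <- function(arrivals, inventory, catalog, open_vials = NULL,
                        day = 0) {
  act <- active_presentations(catalog)
  antigens <- act$antigen
  if (is.data.frame(arrivals)) {
    need <- stats::setNames(numeric(length(antigens)), antigens)
    if (nrow(arrivals)) {
      for (v in arrivals$visit) {
        due <- doses_due(v)
        need[due$antigen] <- need[due$antigen] + 1
      }
    }
  } else {
    need <- stats::setNames(numeric(length(antigens)), antigens)
    need[names(arrivals)] <- arrivals
  }
  pars <- list(dpv = act$doses_per_vial,
               lyophilized = act$formulation == "lyophilized",
               open_days = act$open_vial_days)
  batches <- df_to_batches(inventory, antigens)
  open_d <- stats::setNames(numeric(length(antigens)), antigens)
  open_e <- stats::setNames(rep(Inf, length(antigens)), antigens)
  if (!is.null(open_vials) && nrow(open_vials)) {
    open_d[open_vials$antigen] <- open_vials$doses_left
    open_e[open_vials$antigen] <- open_vials$expiry
  }
  state <- list(batches = batches,
                stock = vapply(batches, function(m) sum(m[, 1L]), 0),
                open_d = open_d, open_e = open_e)
  res <- mdvp_session(state, as.numeric(need), day, pars)
  oc <- res$outcome
  keep <- res$state$open_d > 0
  list(
    outcome = data.frame(antigen = antigens, arrivals = oc$arrivals,
                         administered = oc$administered, missed = oc$missed,
                         vials_opened = oc$vials_opened,
                         open_vial_waste = oc$open_vial_waste,
                         stringsAsFactors = FALSE),
    inventory = batches_to_df(res$state$batches, antigens),
    open_vials = data.frame(antigen = antigens[keep],
                            doses_left = res$state$open_d[keep],
                            expiry = res$state$open_e[keep],
                            stringsAsFactors = FALSE)
  )
}
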