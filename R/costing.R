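# Vaccine costing: administration, wasted doses, disposal, and cost per
# injection. Prices, masses and unit costs come from the cost-input table;
# a presentation with an unknown price (the 2-dose measles vial) fails
# loudly rather than being silently imputed.

price_or_stop <- function(presentation) {
  p <- presentation$price_per_dose
  if (is.na(p)) {
    stop("missing-price error: price per dose unknown for ",
         presentation$antigen, " ", presentation$doses_per_vial,
         "-dose presentation; supply one explicitly")
  }
  p
}

#' Cost of administering doses
#'
#' `doses * (price per dose + injection-syringe cost) + vials opened *
#' reconstitution-syringe cost`. Reconstitution syringes apply to
#' lyophilized presentations only (one per opened vial -- reconstitution
#' is a per-vial operation); orally administered vaccines consume no
#' injection syringe.
#'
#' @param doses_administered Doses administered.
#' @param vials_opened Vials opened.
#' @param costs A `vax_costs` from [load_cost_inputs()].
#' @param presentation One catalog row (e.g. from
#'   [active_presentations()]).
#' @return USD.
#' @export
#' @examples
#' cat <- load_vaccine_catalog(); costs <- load_cost_inputs()
#' m10 <- subset(cat, antigen == "M" & doses_per_vial == 10)
#' administration_cost(10, 1, costs, m10)  # 3.22
administration_cost <- function(doses_administered, vials_opened, costs,
                                presentation) {
  stopifnot(doses_administered >= 0, vials_opened >= 0)
  if (doses_administered == 0 && vials_opened == 0) return(0)
  price <- price_or_stop(presentation)
  syr <- if (identical(presentation$route, "oral")) 0 else costs$inj_syringe_cost
  recon <- if (identical(presentation$formulation, "lyophilized")) {
    vials_opened * costs$recon_syringe_cost
  } else 0
  doses_administered * (price + syr) + recon
}

#' Cost of wasted doses
#'
#' Doses discarded from opened-but-unfinished vials, valued at the price
#' per dose. Single-dose presentations have no open-vial waste, so this is
#' identically zero for them.
#'
#' @param n_wasted Wasted doses.
#' @param price_per_dose USD per dose (`NA` errors).
#' @return USD.
#' @export
wasted_dose_cost <- function(n_wasted, price_per_dose) {
  stopifnot(n_wasted >= 0)
  if (n_wasted == 0) return(0)
  if (is.na(price_per_dose)) {
    stop("missing-price error: cannot cost wasted doses without a price")
  }
  n_wasted * price_per_dose
}

#' Cost of contaminated-waste disposal
#'
#' `safety-box cost per dose * doses + disposal cost per gram * total mass`
#' where the mass sums the discarded vials (empty-vial masses by vial
#' size), reconstitution syringes and injection syringes. The safety-box
#' cost per dose is not published for this setting; if unset it defaults
#' to 0 with a warning.
#'
#' @param vials_discarded Named vector: vials by doses-per-vial size, e.g.
#'   `c("10" = 1)`.
#' @param reconstitution_syringes Count.
#' @param injection_syringes Count.
#' @param doses Doses administered (the safety-box driver).
#' @param costs A `vax_costs`.
#' @return USD.
#' @export
#' @examples
#' costs <- load_cost_inputs()
#' # one 10-dose vial + 1 reconstitution + 10 injection syringes:
#' suppressWarnings(disposal_cost(c("10" = 1), 1, 10, 10, costs))  # 0.527
disposal_cost <- function(vials_discarded, reconstitution_syringes,
                          injection_syringes, doses, costs) {
  stopifnot(all(vials_discarded >= 0), reconstitution_syringes >= 0,
            injection_syringes >= 0, doses >= 0)
  sb <- costs$safety_box_cost_per_dose
  if (is.na(sb)) {
    warning("safety box cost per dose unset; using 0")
    sb <- 0
  }
  vial_mass <- 0
  if (length(vials_discarded)) {
    masses <- costs$vial_mass_g[names(vials_discarded)]
    if (anyNA(masses) && any(vials_discarded[is.na(masses)] > 0)) {
      stop("missing-mass error: no empty-vial mass for size(s) ",
           paste(names(vials_discarded)[is.na(masses)], collapse = ", "))
    }
    vial_mass <- sum(vials_discarded * masses, na.rm = TRUE)
  }
  total_g <- vial_mass +
    reconstitution_syringes * costs$recon_syringe_mass_g +
    injection_syringes * costs$inj_syringe_mass_g
  sb * doses + costs$disposal_cost_per_g * total_g
}

#' Cost per injection
#'
#' Total cost over doses administered, reported to the cent.
#'
#' @param total_cost USD.
#' @param doses_administered Count (> 0; 0 gives `NA`).
#' @param digits Rounding for reporting (default 2).
#' @return USD per injection.
#' @export
#' @examples
#' cost_per_injection(244759, 583575 - 58482)  # 0.47
cost_per_injection <- function(total_cost, doses_administered, digits = 2) {
  if (doses_administered == 0) return(NA_real_)
  round(total_cost / doses_administered, digits)
}

#' Full cost breakdown for one antigen in one simulated scenario
#'
#' Assembles the administration, wasted-dose and disposal components from
#' a simulation's dose accounts, plus the total and cost per injection.
#' For a single-dose presentation the wasted-dose component is exactly 0,
#' so total = administration + disposal.
#'
#' @param sim A `vaxchain_sim`.
#' @param antigen Antigen to cost (default `"M"`, the measles experiments).
#' @param costs A `vax_costs`.
#' @return A one-row data frame of class `vax_cost_breakdown`:
#'   `administration_cost`, `wasted_dose_cost`, `disposal_cost`, `total`,
#'   `doses_administered`, `cost_per_injection`.
#' @export
scenario_costs <- function(sim, antigen = "M", costs = load_cost_inputs()) {
  act <- active_presentations(sim$catalog)
  pres <- act[act$antigen == antigen, ]
  d <- sim$summary$doses
  row <- d[d$antigen == antigen, ]
  adm <- row$administered
  vop <- row$vials_opened
  wasted <- row$open_vial_waste
  admin <- administration_cost(adm, vop, costs, pres)
  waste <- wasted_dose_cost(wasted, pres$price_per_dose)
  lyo <- pres$formulation == "lyophilized"
  n_inj <- if (identical(pres$route, "oral")) 0 else adm
  disp <- disposal_cost(
    stats::setNames(vop, as.character(pres$doses_per_vial)),
    if (lyo) vop else 0, n_inj, adm, costs)
  total <- admin + waste + disp
  out <- data.frame(
    antigen = antigen, doses_per_vial = pres$doses_per_vial,
    administration_cost = admin, wasted_dose_cost = waste,
    disposal_cost = disp, total = total, doses_administered = adm,
    cost_per_injection = cost_per_injection(total, adm),
    stringsAsFactors = FALSE
  )
  class(out) <- c("vax_cost_breakdown", "data.frame")
  out
}
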