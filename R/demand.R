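#' Immunization visit schedule
#'
#' The routine childhood contact points and the antigens due at each. TT
#' (tetanus toxoid) contacts are folded into an aggregate demand stream
#' proportional to newborn counts (five contacts per newborn-equivalent),
#' since no separate maternal population is modelled.
#'
#' @format A data frame with columns `visit`, `age_weeks`,
#'   `contacts_per_child` and a list column `antigens` of
#'   `(antigen, dose_index)` pairs.
#' @keywords internal
visit_schedule <- function() {
  data.frame(
    visit = c("birth", "6w", "10w", "14w", "9m", "tt"),
    age_weeks = c(0, 6, 10, 14, 39, NA),
    contacts_per_child = c(1, 1, 1, 1, 1, 5),
    stringsAsFactors = FALSE
  )
}

visit_antigens <- list(
  birth = data.frame(antigen = c("BCG", "OPV"), dose_index = c(1L, 1L)),
  `6w`  = data.frame(antigen = c("DTP-HepB-Hib", "OPV"), dose_index = c(1L, 2L)),
  `10w` = data.frame(antigen = c("DTP-HepB-Hib", "OPV"), dose_index = c(2L, 3L)),
  `14w` = data.frame(antigen = c("DTP-HepB-Hib", "OPV"), dose_index = c(3L, 4L)),
  `9m`  = data.frame(antigen = c("M", "YF"), dose_index = c(1L, 1L)),
  tt    = data.frame(antigen = "TT", dose_index = 1L)
)

#' Project an annual birth cohort forward
#'
#' Compound growth: `round(base * (1 + rate)^years)`.
#'
#' @param base Base-year births.
#' @param rate Annual growth rate (fraction, e.g. 0.0104).
#' @param years Number of years forward.
#' @return Projected births (rounded to a whole count).
#' @export
#' @examples
#' project_annual_births(557381, 0.0104, 5)  # 586976
project_annual_births <- function(base, rate, years) {
  stopifnot(rate >= 0, years >= 0)
  round(base * (1 + rate)^years)
}

#' Construct a demand model
#'
#' Describes how patient arrivals are generated at clinics over a one-year
#' horizon: an annual birth cohort shared across clinics by weight, a
#' target-population fraction (the share of eligible children that actually
#' presents), and either `static` (fixed monthly counts) or `dynamic`
#' (Poisson) session arrivals.
#'
#' @param annual_births Projected births for the simulated year. The
#'   default, 586880, is the published 2010 projection for the modelled
#'   setting (the direct compound projection from the 2005 registry total
#'   gives 586976; the published figure is carried as-is).
#' @param clinic_shares Named numeric vector of per-clinic demand weights;
#'   normalised to sum to 1.
#' @param target_fraction Fraction in (0, 1] of the eligible population
#'   arriving at clinics (the 100/80/60% scenarios).
#' @param mode `"dynamic"` (Poisson session counts) or `"static"`.
#' @param sessions_per_month Immunization sessions per clinic per month.
#' @return A list of class `vax_demand`.
#' @export
demand_model <- function(annual_births = 586880,
                         clinic_shares,
                         target_fraction = 1.0,
                         mode = c("dynamic", "static"),
                         sessions_per_month = 4L) {
  mode <- match.arg(mode)
  stopifnot(target_fraction > 0, target_fraction <= 1,
            sessions_per_month >= 1, all(clinic_shares >= 0),
            sum(clinic_shares) > 0)
  if (is.null(names(clinic_shares))) {
    stop("clinic_shares must be named by clinic id")
  }
  structure(list(
    annual_births = annual_births,
    clinic_shares = clinic_shares / sum(clinic_shares),
    target_fraction = target_fraction,
    mode = mode,
    sessions_per_month = as.integer(sessions_per_month),
    n_sessions = 12L * as.integer(sessions_per_month)
  ), class = "vax_demand")
}

#' Doses due at a visit
#'
#' Resolves the antigen set a child is due, either by visit label or by age
#' (the nearest schedule contact at or before that age, within the 0-24
#' month window).
#'
#' @param visit One of `"birth"`, `"6w"`, `"10w"`, `"14w"`, `"9m"`, `"tt"`;
#'   or `NULL` if `age_weeks` is given.
#' @param age_weeks Age in weeks (0 to 104), used when `visit` is `NULL`.
#' @return A data frame with columns `antigen` and `dose_index`.
#' @export
#' @examples
#' doses_due("birth")  # BCG dose 1, OPV dose 1
#' doses_due("9m")     # measles dose 1, YF dose 1
doses_due <- function(visit = NULL, age_weeks = NULL) {
  if (is.null(visit)) {
    stopifnot(!is.null(age_weeks), age_weeks >= 0, age_weeks <= 104)
    sched <- visit_schedule()
    aged <- sched[!is.na(sched$age_weeks) & sched$age_weeks <= age_weeks, ]
    if (!nrow(aged)) return(visit_antigens[["birth"]][0, ])
    visit <- aged$visit[which.max(aged$age_weeks)]
  }
  out <- visit_antigens[[visit]]
  if (is.null(out)) stop("unknown visit: ", visit)
  out
}

# Expected arrivals per session for one clinic, by visit stream.
session_lambda <- function(demand, clinic_id) {
  share <- unname(demand$clinic_shares[match(clinic_id,
                                             names(demand$clinic_shares))])
  if (length(share) != 1L || is.na(share)) {
    stop("clinic has no share weight: ", clinic_id)
  }
  sched <- visit_schedule()
  ann <- demand$annual_births * demand$target_fraction * share *
    sched$contacts_per_child
  stats::setNames(ann / demand$n_sessions, sched$visit)
}

#' Generate one session's arrivals at a clinic
#'
#' In `dynamic` mode each visit stream draws a Poisson count with its
#' session mean; in `static` mode counts follow a deterministic
#' cumulative-rounding split of the clinic's annual target across sessions
#' (so annual totals are preserved to the nearest whole child). Each
#' arriving child carries its visit label and age so due doses resolve via
#' [doses_due()]. A child who finds a vaccine out of stock does not
#' re-queue: every arrival is a distinct vaccination opportunity.
#'
#' @param demand A `vax_demand`.
#' @param clinic_id Clinic id (must have a share weight).
#' @param session_index Session number within the year (1-based).
#' @return A data frame with one row per arriving child: `visit`,
#'   `age_weeks`.
#' @export
session_arrivals <- function(demand, clinic_id, session_index) {
  lam <- session_lambda(demand, clinic_id)
  counts <- if (demand$mode == "dynamic") {
    stats::rpois(length(lam), lam)
  } else {
    round(lam * session_index) - round(lam * (session_index - 1))
  }
  sched <- visit_schedule()
  visit <- rep(sched$visit, counts)
  data.frame(visit = visit,
             age_weeks = rep(sched$age_weeks, counts),
             stringsAsFactors = FALSE)
}

# Per-antigen session demand matrix (clinics x antigens) used by the
# engine: sums visit streams onto antigens, so a clinic-session draw is a
# single Poisson per antigen (sum of independent Poissons across streams).
antigen_session_lambda <- function(demand, clinic_ids, antigens) {
  sched <- visit_schedule()
  # doses per child per antigen implied by the visit structure
  per_child <- vapply(antigens, function(a) {
    sum(vapply(seq_len(nrow(sched)), function(i) {
      va <- visit_antigens[[sched$visit[i]]]
      sched$contacts_per_child[i] * sum(va$antigen == a)
    }, 0))
  }, 0)
  shares <- demand$clinic_shares[clinic_ids]
  outer(as.numeric(shares), per_child) *
    demand$annual_births * demand$target_fraction / demand$n_sessions
}
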