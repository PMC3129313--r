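#' Load a vaccine presentation catalog
#'
#' Reads a catalog of vaccine presentations -- one row per (antigen, vial
#' size) -- covering the six EPI antigens (BCG, DTP-HepB-Hib, YF, OPV, TT,
#' measles) plus any alternative presentations that are not part of the
#' active schedule. Exactly one row per antigen is marked `active`; the
#' alternative measles vial sizes (5, 2, 1 doses per vial) are carried as
#' inactive rows and become active through [substitute_presentation()].
#'
#' @param path Path to a CSV (or JSON) catalog file. The bundled fixture is
#'   at `system.file("extdata", "vaccine_catalog.csv", package = "vaxchain")`.
#' @return A data frame of class `vax_catalog` with columns
#'   `antigen`, `schedule`, `doses_per_person`, `doses_per_vial`,
#'   `packed_vol_per_dose` (cm^3), `diluent_vol_per_dose` (cm^3), `route`,
#'   `storage_class` (`"refrigerator"` or `"freezer"`), `formulation`
#'   (`"lyophilized"` or `"liquid"`), `open_vial_days` (`NA` means
#'   discard-at-session-end, the Multi-Dose Vial Policy rule for
#'   lyophilized vaccines), `price_per_dose` (USD, `NA` allowed and
#'   flagged), `shelf_life_days`, `active`.
#' @export
#' @examples
#' cat <- load_vaccine_catalog()
#' subset(cat, antigen == "M" & active)
load_vaccine_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vaccine_catalog.csv", package = "vaxchain")
  }
  if (!file.exists(path)) stop("catalog file not found: ", path)
  cat <- tryCatch({
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      as.data.frame(jsonlite::fromJSON(path))
    } else {
      utils::read.csv(path, stringsAsFactors = FALSE)
    }
  }, error = function(e) {
    stop("schema error: unreadable catalog (", conditionMessage(e), ")")
  })
  validate_catalog(cat)
}

catalog_columns <- c(
  "antigen", "schedule", "doses_per_person", "doses_per_vial",
  "packed_vol_per_dose", "diluent_vol_per_dose", "route", "storage_class",
  "formulation", "open_vial_days", "price_per_dose", "shelf_life_days",
  "active"
)

validate_catalog <- function(cat) {
  if (NROW(cat) == 0L) stop("schema error: catalog is empty")
  missing <- setdiff(catalog_columns, names(cat))
  if (length(missing)) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  }
  num_cols <- c("doses_per_person", "doses_per_vial", "packed_vol_per_dose",
                "diluent_vol_per_dose", "open_vial_days", "price_per_dose",
                "shelf_life_days")
  for (cl in num_cols) {
    cat[[cl]] <- suppressWarnings(as.numeric(cat[[cl]]))
  }
  cat$active <- as.logical(cat$active)
  if (any(is.na(cat$doses_per_vial)) || any(cat$doses_per_vial < 1) ||
      any(cat$doses_per_vial != round(cat$doses_per_vial))) {
    stop("validation error: doses_per_vial must be a positive integer")
  }
  if (any(is.na(cat$packed_vol_per_dose)) || any(cat$packed_vol_per_dose <= 0)) {
    stop("validation error: packed_vol_per_dose must be > 0")
  }
  if (any(cat$diluent_vol_per_dose < 0, na.rm = TRUE)) {
    stop("validation error: diluent_vol_per_dose must be >= 0")
  }
  if (!all(cat$storage_class %in% c("refrigerator", "freezer"))) {
    stop("validation error: storage_class must be refrigerator or freezer")
  }
  if (!all(cat$formulation %in% c("lyophilized", "liquid"))) {
    stop("validation error: formulation must be lyophilized or liquid")
  }
  act <- table(cat$antigen[cat$active])
  if (any(act != 1L) || !setequal(names(act), unique(cat$antigen))) {
    stop("validation error: each antigen needs exactly one active presentation")
  }
  class(cat) <- c("vax_catalog", "data.frame")
  cat
}

#' Write a catalog back to CSV
#'
#' Round-trips with [load_vaccine_catalog()]: writing and reloading yields
#' an identical catalog.
#'
#' @param catalog A `vax_catalog`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_vaccine_catalog <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog)[, catalog_columns],
                   path, row.names = FALSE)
  invisible(path)
}

#' Substitute the active presentation of an antigen
#'
#' Performs the vial-size substitution that defines the experiments: the
#' presentation `(antigen_id, target_doses_per_vial)` becomes the active
#' presentation for that antigen, all other antigens are untouched. The
#' operation is idempotent and is undone by substituting the original vial
#' size back.
#'
#' @param catalog A `vax_catalog`.
#' @param antigen_id Antigen short name, e.g. `"M"` for measles.
#' @param target_doses_per_vial Doses per vial of an existing presentation
#'   of that antigen.
#' @return The modified catalog.
#' @export
#' @examples
#' cat1 <- substitute_presentation(load_vaccine_catalog(), "M", 1)
#' subset(cat1, antigen == "M" & active)$packed_vol_per_dose  # 26.1
substitute_presentation <- function(catalog, antigen_id, target_doses_per_vial) {
  rows <- which(catalog$antigen == antigen_id)
  if (!length(rows)) stop("lookup error: unknown antigen: ", antigen_id)
  hit <- rows[catalog$doses_per_vial[rows] == target_doses_per_vial]
  if (!length(hit)) {
    stop("lookup error: no ", antigen_id, " presentation with ",
         target_doses_per_vial, " doses per vial")
  }
  catalog$active[rows] <- FALSE
  catalog$active[hit[1L]] <- TRUE
  catalog
}

#' Active presentations of a catalog
#'
#' @param catalog A `vax_catalog`.
#' @return One row per antigen (the active presentation), ordered as in the
#'   catalog.
#' @export
active_presentations <- function(catalog) {
  out <- catalog[catalog$active, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load cost inputs
#'
#' Reads the cost-input table: vial and syringe masses, syringe and waste
#' disposal unit costs, the safety-box cost per dose (not published for this
#' setting, so `NA` by default -- computations treat it as 0 with a warning
#' unless supplied), and the annual discount rate used to express costs in a
#' common year.
#'
#' @param path CSV path; default is the bundled fixture.
#' @return A named list of class `vax_costs` with elements
#'   `vial_mass_g` (named by doses-per-vial), `recon_syringe_mass_g`,
#'   `inj_syringe_mass_g`, `inj_syringe_cost`, `recon_syringe_cost`,
#'   `disposal_cost_per_g`, `disposal_cost_per_kg`,
#'   `safety_box_cost_per_dose`, `discount_rate`.
#' @export
load_cost_inputs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cost_inputs.csv", package = "vaxchain")
  }
  if (!file.exists(path)) stop("cost input file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("item", "value") %in% names(tab))) {
    stop("schema error: cost inputs need columns item, value")
  }
  val <- function(key) {
    i <- match(key, tab$item)
    if (is.na(i)) stop("schema error: missing cost input: ", key)
    suppressWarnings(as.numeric(tab$value[i]))
  }
  sizes <- sub("^vial_mass_g_", "", grep("^vial_mass_g_", tab$item, value = TRUE))
  vial_mass <- vapply(sizes, function(s) val(paste0("vial_mass_g_", s)), 0)
  names(vial_mass) <- sizes
  out <- list(
    vial_mass_g = vial_mass,
    recon_syringe_mass_g = val("reconstitution_syringe_mass_g"),
    inj_syringe_mass_g = val("injection_syringe_mass_g"),
    inj_syringe_cost = val("injection_syringe_cost"),
    recon_syringe_cost = val("reconstitution_syringe_cost"),
    disposal_cost_per_g = val("waste_disposal_cost_per_g"),
    disposal_cost_per_kg = val("waste_disposal_cost_per_kg"),
    safety_box_cost_per_dose = val("safety_box_cost_per_dose"),
    discount_rate = val("discount_rate")
  )
  mono <- unlist(out[c("recon_syringe_mass_g", "inj_syringe_mass_g",
                       "inj_syringe_cost", "recon_syringe_cost",
                       "disposal_cost_per_g", "disposal_cost_per_kg")])
  if (any(mono < 0, na.rm = TRUE)) {
    stop("validation error: monetary/mass cost inputs must be >= 0")
  }
  class(out) <- "vax_costs"
  out
}

#' Express a cost in another year's dollars
#'
#' Compounds at the annual discount rate: `amount * (1 + rate)^(to - from)`.
#' A negative exponent (deflating to an earlier year) is allowed.
#'
#' @param amount Cost in `from_year` USD.
#' @param from_year,to_year Calendar years.
#' @param rate Annual rate, default 0.03.
#' @return The adjusted amount.
#' @export
#' @examples
#' adjust_cost_year(100, 2004, 2010)  # 119.41
adjust_cost_year <- function(amount, from_year, to_year, rate = 0.03) {
  stopifnot(rate >= 0)
  amount * (1 + rate)^(to_year - from_year)
}
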