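# Country parameter packs: demographics, component marginals among
# hypertensives, growth rates, treatment mix, event/diabetes rates with
# relative-risk gradients, and unit costs. Packs are plain lists of tibbles
# with CSV + JSON serialisation and a collecting validator.

#' Cardiovascular event outcomes carrying an acute cost
#'
#' Cardiovascular death is an event with an acute cost here; attributable
#' all-cause mortality (`"mortality"` in the rate table) is a separate
#' outcome with no downstream cost, so the two are never double counted.
#'
#' @return Character vector of event-type names.
#' @export
cv_event_outcomes <- function() {
  c("ami", "chf", "unstable_angina", "stroke", "cv_death")
}

pack_outcomes <- function() {
  c(cv_event_outcomes(), "mortality", "t2d_prevalence", "t2d_incidence")
}

#' Build an illustrative country parameter pack
#'
#' Constructs a fully in-code parameter pack for a fictional high-burden
#' western-European country (Germany-like age structure, hypertension
#' prevalence and component mix). All values are illustrative,
#' plausible-order-of-magnitude inputs, not sourced national data; they are
#' the package's demonstration conditions and the substrate of its tests.
#' See the methods vignette for how each block was chosen.
#'
#' @param country Label for the pack (default `"demoland"`).
#' @return A validated object of class `burden_pack`.
#' @export
#' @examples
#' pack <- demo_pack()
#' names(pack)
demo_pack <- function(country = "demoland") {
  strata <- default_strata()
  bands <- unique(strata$age_band)
  # hypertension prevalence rising steeply with age (high-burden profile)
  htn_by_band <- c("20-29" = 0.12, "30-39" = 0.25, "40-49" = 0.45,
                   "50-59" = 0.65, "60-69" = 0.78, "70-79" = 0.85,
                   "80+" = 0.88)
  demography <- strata |>
    dplyr::mutate(
      population_base = round(68e6 * .data$share),
      htn_prevalence = unname(htn_by_band[.data$age_band])
    ) |>
    dplyr::select(-"share")
  horizon_share <- c("20-29" = 0.130, "30-39" = 0.145, "40-49" = 0.160,
                     "50-59" = 0.170, "60-69" = 0.160, "70-79" = 0.140,
                     "80+" = 0.095)
  demography$population_horizon <-
    round(69.5e6 * unname(horizon_share[demography$age_band]) / 2)

  # component marginals among hypertensives: linear age gradient from the
  # youngest to the oldest band, identical for both sexes
  grad <- function(young, old) {
    v <- seq(young, old, length.out = length(bands))
    setNames(v, bands)
  }
  comp_grad <- list(
    obesity = grad(0.45, 0.70),
    low_hdl = grad(0.28, 0.32),
    high_tg = grad(0.40, 0.55),
    impaired_glucose = grad(0.25, 0.55)
  )
  marginals <- tidyr::crossing(
    strata[c("age_band", "sex")],
    tibble::tibble(component = mets_other_components())
  ) |>
    dplyr::rowwise() |>
    dplyr::mutate(prevalence = comp_grad[[.data$component]][[.data$age_band]]) |>
    dplyr::ungroup()

  growth <- tibble::tibble(
    component = c("hypertension", mets_other_components()),
    cagr = c(0.010, 0.022, 0.004, 0.010, 0.025)
  )

  treatment <- list(
    proportion_treated = 0.60,
    visits_per_year = 4,
    visit_cost_eur = 30,
    nod_baseline_incidence_per_1000 = 10,
    classes = tibble::tibble(
      class = c("arb", "ace_inhibitor", "ccb", "diuretic", "beta_blocker",
                "combination"),
      share = c(0.18, 0.26, 0.16, 0.14, 0.16, 0.10),
      annual_cost_eur = c(420, 210, 260, 110, 160, 460),
      continuation = c(0.65, 0.58, 0.52, 0.46, 0.48, 0.55),
      rr_nod = c(0.90, 0.95, 1.00, 1.30, 1.25, 1.10)
    )
  )

  # overall rates per 1,000 hypertensives with relative-risk gradients over
  # k = 0..4; gradients chosen so the pack's own risk-group mix yields
  # MetS/non-MetS ratios near 2x (events, mortality) and 6x (T2D prevalence)
  rates <- tibble::tibble(
    outcome = pack_outcomes(),
    overall_rate_per_1000 = c(6, 5, 3, 6, 2, 2.4, 169, 12),
    rr_k0 = 1,
    rr_k1 = c(rep(1.5, 6), 2.2, 2.2),
    rr_k2 = c(rep(2.1, 6), 6.5, 6.5),
    rr_k3 = c(rep(2.9, 6), 12.5, 12.5),
    rr_k4 = c(rep(3.8, 6), 20.0, 20.0)
  )

  unit_costs <- tibble::tibble(
    item = c(cv_event_outcomes(), "t2d_annual"),
    cost_eur = c(6500, 5200, 4200, 8800, 2800, 2400)
  )

  pack <- structure(
    list(country = country, base_year = 2008L, horizon_year = 2020L,
         currency = "EUR", demography = demography, marginals = marginals,
         growth = growth, treatment = treatment, rates = rates,
         unit_costs = unit_costs,
         options = list(t2d_incident_only = FALSE)),
    class = "burden_pack"
  )
  validate_parameter_pack(pack)
}

#' Validate a country parameter pack
#'
#' Schema and cross-field validation of a `burden_pack`: drug-class shares
#' sum to 1, rates and costs non-negative, relative risks anchored at
#' `rr_k0 = 1` and non-decreasing in k (risk rises with the number of
#' components present), diabetes incidence not above prevalence,
#' prevalences strictly inside (0,1), currency euro. All violations are
#' collected and reported together, not just the first.
#'
#' @param pack A `burden_pack` (from [demo_pack()] or
#'   [read_parameter_pack()]).
#' @return The pack, invisibly usable, if valid; otherwise an error listing
#'   every violation.
#' @export
validate_parameter_pack <- function(pack) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))

  if (!is.list(pack)) stop("validate_parameter_pack: not a pack", call. = FALSE)
  if (!identical(pack$currency, "EUR")) {
    note("meta: currency must be 'EUR' (unit mismatch in parameter pack)")
  }
  if (!is.numeric(pack$horizon_year) || !is.numeric(pack$base_year) ||
      pack$horizon_year <= pack$base_year) {
    note("meta: horizon_year must exceed base_year")
  }

  d <- pack$demography
  need_d <- c("age_band", "sex", "population_base", "population_horizon",
              "htn_prevalence")
  if (!all(need_d %in% names(d))) {
    note("demography: missing column(s): ",
         paste(setdiff(need_d, names(d)), collapse = ", "))
  } else {
    if (any(d$population_base < 0) || any(d$population_horizon < 0)) {
      note("demography: negative population count")
    }
    if (any(d$htn_prevalence <= 0 | d$htn_prevalence >= 1)) {
      note("demography: htn_prevalence must lie strictly in (0,1)")
    }
  }

  m <- pack$marginals
  if (!all(c("age_band", "sex", "component", "prevalence") %in% names(m))) {
    note("marginals: missing required column(s)")
  } else {
    if (any(m$prevalence <= 0 | m$prevalence >= 1)) {
      note("marginals: prevalences must lie strictly in (0,1)")
    }
    want <- tidyr::crossing(d[c("age_band", "sex")],
                            tibble::tibble(component = mets_other_components()))
    if (nrow(dplyr::anti_join(want, m,
                              by = c("age_band", "sex", "component")))) {
      note("marginals: not every stratum/component pair is covered")
    }
  }

  g <- pack$growth
  if (!all(c("component", "cagr") %in% names(g))) {
    note("growth: missing required column(s)")
  } else {
    want_g <- c("hypertension", mets_other_components())
    if (!all(want_g %in% g$component)) {
      note("growth: missing CAGR for component(s): ",
           paste(setdiff(want_g, g$component), collapse = ", "))
    }
    if (any(g$cagr <= -1)) note("growth: CAGR must exceed -1")
  }

  tr <- pack$treatment
  if (!is.list(tr) || !all(c("proportion_treated", "visits_per_year",
                             "visit_cost_eur",
                             "nod_baseline_incidence_per_1000",
                             "classes") %in% names(tr))) {
    note("treatment: missing required field(s)")
  } else {
    if (tr$proportion_treated < 0 || tr$proportion_treated > 1) {
      note("treatment.csv: proportion_treated must lie in [0,1]")
    }
    cl <- tr$classes
    need_c <- c("class", "share", "annual_cost_eur", "continuation", "rr_nod")
    if (!all(need_c %in% names(cl))) {
      note("treatment.csv: classes missing column(s): ",
           paste(setdiff(need_c, names(cl)), collapse = ", "))
    } else {
      if (abs(sum(cl$share) - 1) > 1e-9) {
        note("treatment.csv: drug-class shares sum to ",
             format(sum(cl$share)), ", not 1")
      }
      if (any(cl$continuation < 0 | cl$continuation > 1)) {
        note("treatment.csv: continuation rates must lie in [0,1]")
      }
      if (any(cl$annual_cost_eur < 0)) {
        note("treatment.csv: negative annual drug cost")
      }
      if (any(cl$rr_nod < 0)) {
        note("treatment.csv: negative new-onset-diabetes relative risk")
      }
    }
    if (tr$visits_per_year < 0 || tr$visit_cost_eur < 0 ||
        tr$nod_baseline_incidence_per_1000 < 0) {
      note("treatment.csv: visit and baseline-incidence fields must be >= 0")
    }
  }

  r <- pack$rates
  rr_cols <- paste0("rr_k", 0:4)
  need_r <- c("outcome", "overall_rate_per_1000", rr_cols)
  if (!all(need_r %in% names(r))) {
    note("rates.csv: missing column(s): ",
         paste(setdiff(need_r, names(r)), collapse = ", "))
  } else {
    if (!all(pack_outcomes() %in% r$outcome)) {
      note("rates.csv: missing outcome(s): ",
           paste(setdiff(pack_outcomes(), r$outcome), collapse = ", "))
    }
    if (any(r$overall_rate_per_1000 < 0)) note("rates.csv: negative rate")
    if (any(abs(r$rr_k0 - 1) > 1e-12)) {
      note("rates.csv: rr_k0 must equal 1 (reference group)")
    }
    rr <- as.matrix(r[rr_cols])
    if (any(rr < 0)) note("rates.csv: negative relative risk")
    if (any(t(apply(rr, 1L, diff)) < -1e-12)) {
      note("rates.csv: rr_k must be non-decreasing in k ",
           "(risk rises with the number of MetS components present)")
    }
    if (all(c("t2d_incidence", "t2d_prevalence") %in% r$outcome)) {
      inc <- r$overall_rate_per_1000[r$outcome == "t2d_incidence"]
      prev <- r$overall_rate_per_1000[r$outcome == "t2d_prevalence"]
      if (inc > prev) {
        note("rates.csv: t2d_incidence exceeds t2d_prevalence")
      }
    }
  }

  u <- pack$unit_costs
  if (!all(c("item", "cost_eur") %in% names(u))) {
    note("unit_costs.csv: missing required column(s)")
  } else {
    want_u <- c(cv_event_outcomes(), "t2d_annual")
    if (!all(want_u %in% u$item)) {
      note("unit_costs.csv: missing unit cost for: ",
           paste(setdiff(want_u, u$item), collapse = ", "))
    }
    if (any(u$cost_eur < 0)) note("unit_costs.csv: negative unit cost")
  }

  if (length(problems)) {
    stop("invalid parameter pack:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  if (!inherits(pack, "burden_pack")) class(pack) <- "burden_pack"
  pack
}

#' @export
print.burden_pack <- function(x, ...) {
  cat("Burden parameter pack for '", x$country, "' (", x$base_year, " -> ",
      x$horizon_year, ", ", x$currency, ")\n", sep = "")
  cat("  ", nrow(x$demography), " strata, ",
      nrow(x$treatment$classes), " drug classes, ",
      nrow(x$rates), " rated outcomes\n", sep = "")
  invisible(x)
}

#' Write / read a parameter pack as CSV + JSON
#'
#' Serialises a pack to a directory of plain-text files (`demography.csv`,
#' `marginals.csv`, `growth.csv`, `rates.csv`, `treatment.csv`,
#' `unit_costs.csv`, `meta.json`) and reads it back with full validation.
#'
#' @param pack A `burden_pack`.
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_parameter_pack()` the directory invisibly;
#'   `read_parameter_pack()` the validated pack.
#' @export
write_parameter_pack <- function(pack, dir) {
  pack <- validate_parameter_pack(pack)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, file) {
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
  }
  wr(pack$demography, "demography.csv")
  wr(pack$marginals, "marginals.csv")
  wr(pack$growth, "growth.csv")
  wr(pack$rates, "rates.csv")
  wr(pack$treatment$classes, "treatment.csv")
  wr(pack$unit_costs, "unit_costs.csv")
  meta <- list(
    country = pack$country, base_year = pack$base_year,
    horizon_year = pack$horizon_year, currency = pack$currency,
    proportion_treated = pack$treatment$proportion_treated,
    visits_per_year = pack$treatment$visits_per_year,
    visit_cost_eur = pack$treatment$visit_cost_eur,
    nod_baseline_incidence_per_1000 =
      pack$treatment$nod_baseline_incidence_per_1000,
    options = pack$options
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_parameter_pack
#' @export
read_parameter_pack <- function(dir) {
  rd <- function(file) {
    tibble::as_tibble(utils::read.csv(file.path(dir, file),
                                      stringsAsFactors = FALSE))
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  pack <- structure(
    list(country = meta$country, base_year = as.integer(meta$base_year),
         horizon_year = as.integer(meta$horizon_year),
         currency = meta$currency,
         demography = rd("demography.csv"),
         marginals = rd("marginals.csv"),
         growth = rd("growth.csv"),
         treatment = list(
           proportion_treated = meta$proportion_treated,
           visits_per_year = meta$visits_per_year,
           visit_cost_eur = meta$visit_cost_eur,
           nod_baseline_incidence_per_1000 =
             meta$nod_baseline_incidence_per_1000,
           classes = rd("treatment.csv")
         ),
         rates = rd("rates.csv"),
         unit_costs = rd("unit_costs.csv"),
         options = as.list(meta$options)),
    class = "burden_pack"
  )
  validate_parameter_pack(pack)
}
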