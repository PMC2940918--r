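# The burden engine and the end-to-end pipeline: conditional structure ->
# calibration -> risk-group decomposition -> consequences -> costs
# (-> projection -> discounting) -> reports.

#' Default reference-microdata specification
#'
#' A survey-like specification the pipeline uses to build its reference
#' conditional structure when none is supplied: flat NHANES-style component
#' marginals with a positive latent clustering (correlation 0.25 among the
#' four non-BP components, 0.15 between hypertension and each of them).
#'
#' @param n_subjects Number of subjects (default 50000).
#' @param seed RNG seed (default 20080101).
#' @return A [microdata_spec()].
#' @export
default_reference_spec <- function(n_subjects = 50000, seed = 20080101) {
  assoc <- matrix(0.25, 5, 5)
  assoc[1, ] <- assoc[, 1] <- 0.15
  diag(assoc) <- 1
  microdata_spec(
    n_subjects, seed = seed,
    marginals = c(hypertension = 0.30, obesity = 0.38, low_hdl = 0.35,
                  high_tg = 0.33, impaired_glucose = 0.25),
    association = assoc,
    weight_model = "lognormal", weight_sigma = 0.4
  )
}

#' Compute the annual burden snapshot for one country
#'
#' Runs the burden engine for the base or horizon year of a parameter pack:
#' projects hypertension prevalence and component marginals with their
#' CAGRs (horizon only), calibrates the reference conditional structure to
#' the country marginals by IPF, decomposes the hypertensive population
#' into risk groups k = 0..4, attributes cardiovascular events, mortality
#' and type 2 diabetes through calibrated relative-risk gradients, and
#' aggregates the four cost components. Horizon-year costs use base-year
#' prices (no price inflation).
#'
#' @param pack A validated `burden_pack`.
#' @param conditional Reference [conditional_matrix()] covering the pack's
#'   strata.
#' @param year `"base"` or `"horizon"`.
#' @return A list of class `burden_snapshot`: `risk_groups` (per-stratum
#'   decomposition), `persons_k`, `epi` (events/cases and per-1,000 rates by
#'   group and MetS split for every outcome), `nod` (treatment-attributable
#'   new-onset diabetes by class and group), `costs_by_k`, `costs_split`,
#'   `per_patient`, and IPF diagnostics.
#' @export
compute_burden <- function(pack, conditional, year = c("base", "horizon")) {
  year <- match.arg(year)
  pack <- validate_parameter_pack(pack)
  years_ahead <- if (year == "horizon") pack$horizon_year - pack$base_year else 0L
  cagr <- setNames(pack$growth$cagr, pack$growth$component)

  demo <- pack$demography
  pop <- if (year == "horizon") demo$population_horizon else demo$population_base
  htn_prev <- project_marginal(demo$htn_prevalence, cagr[["hypertension"]],
                               years_ahead)
  htn_counts <- tibble::tibble(age_band = demo$age_band, sex = demo$sex,
                               htn_count = pop * htn_prev)

  targets <- pack$marginals |>
    dplyr::mutate(target = project_marginal(
      .data$prevalence, cagr[.data$component], years_ahead)) |>
    dplyr::select("age_band", "sex", "component", "target")

  sids <- stratum_id(htn_counts$age_band, htn_counts$sex)
  missing_s <- setdiff(sids, rownames(conditional))
  if (length(missing_s)) {
    stop("compute_burden: conditional matrix lacks strata: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  calibrated <- calibrate_to_marginals(
    conditional_matrix(unclass(conditional)[sids, , drop = FALSE]), targets)

  rgt <- decompose_population(htn_counts, calibrated)
  persons_k <- colSums(as.matrix(rgt[paste0("k", 0:4)]))
  weights <- persons_k / sum(persons_k)

  rr_cols <- paste0("rr_k", 0:4)
  rate_rows <- split(pack$rates, pack$rates$outcome)
  group_rates <- lapply(rate_rows, function(r) {
    calibrate_group_rates(r$overall_rate_per_1000, weights,
                          as.numeric(r[1, rr_cols]))
  })
  events <- vapply(group_rates, function(rk) expected_events(persons_k, rk),
                   numeric(5))
  events <- t(events)  # outcomes x k

  treated_k <- persons_k * pack$treatment$proportion_treated
  nod <- treatment_attributable_new_onset_t2d(
    treated_k, pack$treatment$classes,
    pack$treatment$nod_baseline_incidence_per_1000)
  nod_k <- vapply(0:4, function(kk) sum(nod$cases[nod$k == kk]), numeric(1))

  t2d_prevalent_k <- events["t2d_prevalence", ]
  t2d_incident_k <- events["t2d_incidence", ] + nod_k
  t2d_cost_cases <- if (isTRUE(pack$options$t2d_incident_only)) {
    t2d_incident_k
  } else {
    t2d_prevalent_k
  }

  event_costs <- setNames(pack$unit_costs$cost_eur, pack$unit_costs$item)
  costs_by_k <- annual_costs(
    persons_k, treated_k,
    events[cv_event_outcomes(), , drop = FALSE], t2d_cost_cases,
    pack$treatment$classes, pack$treatment$visits_per_year,
    pack$treatment$visit_cost_eur, event_costs,
    event_costs[["t2d_annual"]])
  costs_split <- aggregate_mets_split(costs_by_k)

  epi <- dplyr::bind_rows(lapply(rownames(events), function(o) {
    ev <- unname(events[o, ])
    tibble::tibble(
      outcome = o,
      group = c(paste0("k", 0:4), "mets", "non_mets", "all"),
      persons = unname(c(persons_k, sum(persons_k[3:5]), sum(persons_k[1:2]),
                         sum(persons_k))),
      events = c(ev, sum(ev[3:5]), sum(ev[1:2]), sum(ev))
    ) |>
      dplyr::mutate(rate_per_1000 = group_rate(.data$events, .data$persons))
  }))

  structure(list(
    country = pack$country, year = year,
    calendar_year = if (year == "horizon") pack$horizon_year else pack$base_year,
    risk_groups = rgt, persons_k = persons_k,
    epi = epi, nod = nod,
    t2d_prevalent_k = t2d_prevalent_k, t2d_incident_k = t2d_incident_k,
    costs_by_k = costs_by_k, costs_split = costs_split,
    per_patient = tibble::tibble(
      k = 0:4, eur_per_patient = per_patient_cost(costs_by_k$total, persons_k)),
    ipf_iterations = attr(calibrated, "iterations"),
    ipf_discrepancy = attr(calibrated, "discrepancy")
  ), class = "burden_snapshot")
}

#' @export
print.burden_snapshot <- function(x, ...) {
  cat("Burden snapshot: ", x$country, ", ", x$calendar_year, "\n", sep = "")
  tot <- x$costs_split
  cat(sprintf("  hypertensives: %.0f (MetS share %.1f%%)\n",
              sum(x$persons_k),
              100 * sum(x$persons_k[3:5]) / sum(x$persons_k)))
  cat(sprintf("  total annual cost: %.0f EUR m (MetS %.0f, non-MetS %.0f)\n",
              tot$total[tot$slice == "all"], tot$total[tot$slice == "mets"],
              tot$total[tot$slice == "non_mets"]))
  invisible(x)
}

#' Project the burden to the horizon year
#'
#' Convenience wrapper: recomputes the full snapshot at horizon-year
#' demographics and CAGR-projected prevalences, at base-year prices, and
#' reports the percent rise in the MetS cost against the base year.
#'
#' @inheritParams compute_burden
#' @return A list with elements `base`, `horizon` (two `burden_snapshot`s)
#'   and `rise_pct` (named: `mets`, `non_mets`, `all`; unrounded).
#' @export
project_burden <- function(pack, conditional) {
  base <- compute_burden(pack, conditional, "base")
  horizon <- compute_burden(pack, conditional, "horizon")
  slices <- c("mets", "non_mets", "all")
  b <- base$costs_split$total[match(slices, base$costs_split$slice)]
  h <- horizon$costs_split$total[match(slices, horizon$costs_split$slice)]
  list(base = base, horizon = horizon,
       rise_pct = setNames(pct_rise(b, h), slices))
}

#' Run the full reproducible burden pipeline
#'
#' Ties the stages together for one or more countries: simulates the
#' reference microdata (fixed seed), estimates the conditional structure,
#' computes base- and horizon-year snapshots per pack, percent rises and
#' (optionally) discounted horizon costs, and writes CSV tables plus a JSON
#' summary with a provenance block. Fully deterministic given the
#' configuration: running the same config twice yields identical outputs.
#'
#' @param packs A `burden_pack` or list of packs (one per country).
#' @param microdata A [microdata_spec()] for the reference structure
#'   (default [default_reference_spec()]); ignored when `conditional` is
#'   given.
#' @param conditional Optionally a precomputed [conditional_matrix()].
#' @param discount_rate Optional fractional rate applied to horizon costs.
#' @param out_dir Optional directory; when given, writes
#'   `epidemiology.csv`, `costs.csv`, `summary.json`.
#' @return A list of class `pipeline_report` with one element per country
#'   (each as [project_burden()] plus discounted totals) and a `provenance`
#'   block (config hash, seed, package version).
#' @export
run_pipeline <- function(packs, microdata = default_reference_spec(),
                         conditional = NULL, discount_rate = NULL,
                         out_dir = NULL) {
  if (inherits(packs, "burden_pack")) packs <- list(packs)
  packs <- lapply(packs, validate_parameter_pack)
  names(packs) <- vapply(packs, `[[`, character(1), "country")

  if (is.null(conditional)) {
    records <- simulate_microdata(microdata)
    conditional <- estimate_conditional_matrix(records)
  }

  countries <- lapply(packs, function(pack) {
    res <- project_burden(pack, conditional)
    if (!is.null(discount_rate)) {
      yrs <- pack$horizon_year - pack$base_year
      res$discounted_horizon <- setNames(
        discount_cost(res$horizon$costs_split$total, discount_rate, yrs),
        res$horizon$costs_split$slice)
    }
    res
  })

  provenance <- list(
    config_hash = rlang::hash(list(
      packs = packs, microdata = unclass(microdata),
      discount_rate = discount_rate)),
    seed = microdata$seed,
    package_version = as.character(utils::packageVersion("metsburden")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  report <- structure(list(countries = countries, provenance = provenance),
                      class = "pipeline_report")

  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

# CSV + JSON serialisation of a pipeline report; printed numbers are
# rounded here only (euro millions and integer percentages), the stored
# JSON keeps unrounded values alongside.
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  epi <- dplyr::bind_rows(lapply(report$countries, function(cr) {
    dplyr::bind_rows(
      dplyr::mutate(cr$base$epi, country = cr$base$country,
                    year = cr$base$calendar_year),
      dplyr::mutate(cr$horizon$epi, country = cr$horizon$country,
                    year = cr$horizon$calendar_year)
    )
  }))
  utils::write.csv(epi, file.path(out_dir, "epidemiology.csv"),
                   row.names = FALSE)
  costs <- dplyr::bind_rows(lapply(report$countries, function(cr) {
    dplyr::bind_rows(
      dplyr::mutate(cr$base$costs_split, country = cr$base$country,
                    year = cr$base$calendar_year),
      dplyr::mutate(cr$horizon$costs_split, country = cr$horizon$country,
                    year = cr$horizon$calendar_year)
    )
  })) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(c(cost_components(), "total")),
                                ~ round_half_up(.x)))
  utils::write.csv(costs, file.path(out_dir, "costs.csv"), row.names = FALSE)
  summary <- list(
    provenance = report$provenance,
    countries = lapply(report$countries, function(cr) {
      out <- list(
        base_total = setNames(as.list(cr$base$costs_split$total),
                              cr$base$costs_split$slice),
        horizon_total = setNames(as.list(cr$horizon$costs_split$total),
                                 cr$horizon$costs_split$slice),
        rise_pct = as.list(cr$rise_pct)
      )
      if (!is.null(cr$discounted_horizon)) {
        out$discounted_horizon <- as.list(cr$discounted_horizon)
      }
      out
    })
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
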