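# Univariate (one-at-a-time) sensitivity analysis: each scenario perturbs
# exactly one factor of a parameter pack, every other parameter staying
# bit-identical to baseline.

#' Univariate sensitivity scenarios
#'
#' Constructors for the one-at-a-time scenarios: scaling one unit-cost
#' family (`drug` = annual drug-class costs, `cvd` = acute event costs,
#' `t2d` = annual diabetes management cost), scaling the continuation
#' (adherence) rate, costing incident rather than prevalent type 2 diabetes
#' (including treatment-attributable new-onset cases), setting the treated
#' proportion, or discounting horizon-year costs. Each scenario perturbs
#' exactly one factor — univariate by construction.
#'
#' @param target One of `"drug"`, `"cvd"`, `"t2d"`.
#' @param factor Multiplicative factor (e.g. 1.2 for +20%).
#' @param value Treated proportion in \[0,1\].
#' @param rate Fractional annual discount rate.
#' @param name Optional scenario label; a default is derived.
#' @return An object of class `burden_scenario`.
#' @export
#' @examples
#' scenario_scale_unit_cost("t2d", 1.2)
scenario_scale_unit_cost <- function(target = c("drug", "cvd", "t2d"),
                                     factor, name = NULL) {
  target <- match.arg(target)
  stopifnot(is.numeric(factor), factor >= 0)
  new_scenario(name %||% sprintf("%s cost x%.2f", target, factor),
               "scale_unit_cost", target = target, factor = factor)
}

#' @rdname scenario_scale_unit_cost
#' @export
scenario_scale_continuation <- function(factor, name = NULL) {
  stopifnot(is.numeric(factor), factor >= 0)
  new_scenario(name %||% sprintf("continuation x%.2f", factor),
               "scale_continuation", factor = factor)
}

#' @rdname scenario_scale_unit_cost
#' @export
scenario_t2d_incident_only <- function(name = "incident T2D only") {
  new_scenario(name, "t2d_incident_only")
}

#' @rdname scenario_scale_unit_cost
#' @export
scenario_proportion_treated <- function(value, name = NULL) {
  stopifnot(is.numeric(value), value >= 0, value <= 1)
  new_scenario(name %||% sprintf("proportion treated %.0f%%", 100 * value),
               "set_proportion_treated", value = value)
}

#' @rdname scenario_scale_unit_cost
#' @export
scenario_discount <- function(rate, name = NULL) {
  stopifnot(is.numeric(rate), rate > -1)
  new_scenario(name %||% sprintf("discount %.0f%%", 100 * rate),
               "discount", rate = rate)
}

new_scenario <- function(name, type, ...) {
  structure(list(name = name, type = type, args = list(...)),
            class = "burden_scenario")
}

#' @export
print.burden_scenario <- function(x, ...) {
  cat("Scenario '", x$name, "' [", x$type, "]\n", sep = "")
  invisible(x)
}

#' Apply a univariate scenario to a parameter pack
#'
#' Returns a copy of the pack with only the scenario's factor changed; the
#' baseline pack is untouched and all non-targeted parameters are identical
#' to it. A continuation scaling is capped at 1 (a rate).
#'
#' @param pack A `burden_pack`.
#' @param scenario A `burden_scenario`.
#' @return The perturbed, revalidated pack.
#' @export
apply_scenario <- function(pack, scenario) {
  stopifnot(inherits(pack, "burden_pack"), inherits(scenario, "burden_scenario"))
  a <- scenario$args
  pack <- switch(scenario$type,
    scale_unit_cost = {
      if (a$target == "drug") {
        pack$treatment$classes$annual_cost_eur <-
          pack$treatment$classes$annual_cost_eur * a$factor
      } else if (a$target == "cvd") {
        sel <- pack$unit_costs$item %in% cv_event_outcomes()
        pack$unit_costs$cost_eur[sel] <- pack$unit_costs$cost_eur[sel] * a$factor
      } else if (a$target == "t2d") {
        sel <- pack$unit_costs$item == "t2d_annual"
        pack$unit_costs$cost_eur[sel] <- pack$unit_costs$cost_eur[sel] * a$factor
      } else {
        stop("apply_scenario: unknown unit-cost target '", a$target, "'",
             call. = FALSE)
      }
      pack
    },
    scale_continuation = {
      pack$treatment$classes$continuation <-
        pmin(1, pack$treatment$classes$continuation * a$factor)
      pack
    },
    t2d_incident_only = {
      pack$options$t2d_incident_only <- TRUE
      pack
    },
    set_proportion_treated = {
      pack$treatment$proportion_treated <- a$value
      pack
    },
    discount = {
      pack$options$discount_rate <- a$rate
      pack
    },
    stop("apply_scenario: unknown scenario type '", scenario$type, "'",
         call. = FALSE)
  )
  validate_parameter_pack(pack)
}

#' Scale one component of a cost breakdown
#'
#' Each cost component is linear in its unit-cost family, so varying a
#' unit cost by a factor varies exactly that component by the same factor
#' and leaves the others untouched. This applies that identity directly to
#' a [cost_breakdown()] — the route used when the model is fed published
#' component costs rather than a full parameter pack.
#'
#' @param breakdown A [cost_breakdown()].
#' @param target One of `"drug"`, `"physician"`, `"cvd"`, `"t2d"`.
#' @param factor Multiplicative factor.
#' @return The breakdown with the component scaled and the total recomputed.
#' @export
#' @examples
#' b <- cost_breakdown(628, 1952, 5265, 16582)
#' scale_cost_component(b, "t2d", 1.2)$total  # 27743.4
scale_cost_component <- function(breakdown,
                                 target = c("drug", "physician", "cvd", "t2d"),
                                 factor) {
  stopifnot(inherits(breakdown, "cost_breakdown"), is.numeric(factor),
            factor >= 0)
  target <- match.arg(target)
  breakdown[[target]] <- breakdown[[target]] * factor
  breakdown$total <- breakdown$drug + breakdown$physician + breakdown$cvd +
    breakdown$t2d
  breakdown
}

#' Run a univariate sensitivity analysis
#'
#' Evaluates the full burden model under the baseline pack and under each
#' scenario, reporting total annual costs for the hypertensive population
#' with and without MetS (euro millions). Deterministic given the pack and
#' conditional structure; the baseline row comes first and rows are
#' otherwise in scenario order (use [tornado_order()] to re-order by
#' spread).
#'
#' A `scenario_discount()` scenario reports the horizon-year totals
#' discounted back to the base year; all other scenarios report base-year
#' totals.
#'
#' @param pack Baseline `burden_pack`.
#' @param scenarios List of `burden_scenario` objects (may be empty).
#' @param conditional Reference [conditional_matrix()].
#' @return A tibble `scenario`, `slice` (`"mets"` / `"non_mets"`), `total`
#'   (euro millions, unrounded).
#' @export
run_univariate <- function(pack, scenarios = list(), conditional) {
  totals <- function(p, label) {
    yr <- if (!is.null(p$options$discount_rate)) "horizon" else "base"
    rep <- compute_burden(p, conditional, year = yr)
    split <- rep$costs_split
    tot <- split$total[match(c("mets", "non_mets"), split$slice)]
    if (!is.null(p$options$discount_rate)) {
      tot <- discount_cost(tot, p$options$discount_rate,
                           p$horizon_year - p$base_year)
    }
    tibble::tibble(scenario = label, slice = c("mets", "non_mets"),
                   total = tot)
  }
  rows <- list(totals(pack, "baseline"))
  for (sc in scenarios) {
    stopifnot(inherits(sc, "burden_scenario"))
    rows[[length(rows) + 1L]] <- totals(apply_scenario(pack, sc), sc$name)
  }
  dplyr::bind_rows(rows)
}

#' Order sensitivity results for a tornado plot
#'
#' @param results Output of [run_univariate()].
#' @return Character vector of scenario names, baseline first, then by
#'   descending absolute spread of the MetS ("presence") totals around the
#'   baseline.
#' @export
tornado_order <- function(results) {
  base <- results$total[results$scenario == "baseline" &
                          results$slice == "mets"]
  others <- results[results$scenario != "baseline" &
                      results$slice == "mets", , drop = FALSE]
  spread <- abs(others$total - base)
  agg <- tapply(spread, others$scenario, max)
  c("baseline", names(sort(agg, decreasing = TRUE)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
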