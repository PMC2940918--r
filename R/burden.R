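# Risk-group attribution of disease consequences. Sourced inputs give an
# overall rate per 1,000 hypertensives plus a relative-risk gradient over
# the risk groups k = 0..4; the gradient is anchored so the
# population-weighted group rates reproduce the overall rate exactly.

#' Calibrate per-risk-group rates to an overall rate
#'
#' Given an overall rate per 1,000 hypertensives, the population share of
#' each risk group k = 0..4 and a relative-risk gradient `rr_by_k`
#' (rr for k = 0 conventionally 1), returns group rates
#' `b * rr_k` with the baseline `b = overall / sum(w_k * rr_k)`, so the
#' population-weighted mean of the group rates equals the overall rate
#' exactly (the calibration identity).
#'
#' @param overall_rate Overall rate per 1,000 hypertensives (>= 0).
#' @param weights Population shares by k (length 5, summing to 1).
#' @param rr_by_k Relative risks by k (length 5, >= 0, not all zero).
#' @return Numeric vector of length 5: the calibrated per-1,000 group rates.
#' @export
#' @examples
#' calibrate_group_rates(15, c(0.5, 0.5, 0, 0, 0), c(1, 2, 2, 2, 2))[1:2]
calibrate_group_rates <- function(overall_rate, weights, rr_by_k) {
  stopifnot(length(weights) == 5L, length(rr_by_k) == 5L)
  if (overall_rate < 0) {
    stop("calibrate_group_rates: overall rate must be non-negative",
         call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("calibrate_group_rates: weights must sum to 1", call. = FALSE)
  }
  if (any(rr_by_k < 0)) {
    stop("calibrate_group_rates: relative risks must be non-negative",
         call. = FALSE)
  }
  denom <- sum(weights * rr_by_k)
  if (denom <= 0) {
    stop("calibrate_group_rates: population-weighted relative risk is zero",
         call. = FALSE)
  }
  (overall_rate / denom) * rr_by_k
}

#' Expected annual events per risk group
#'
#' Events in group k are `persons_k * rate_k / 1000`. Used for incident
#' cardiovascular events and attributable mortality alike.
#'
#' @param persons Persons per risk group (length 5, >= 0).
#' @param rates Calibrated per-1,000 group rates (length 5, >= 0).
#' @return Numeric vector of expected events per group.
#' @seealso [group_rate()] for reporting rates back from counts.
#' @export
expected_events <- function(persons, rates) {
  stopifnot(length(persons) == length(rates))
  if (any(persons < 0) || any(rates < 0)) {
    stop("expected_events: persons and rates must be non-negative",
         call. = FALSE)
  }
  persons * rates / 1000
}

#' Prevalent type 2 diabetes cases per risk group
#'
#' Same arithmetic as [expected_events()], applied to the prevalence pool
#' (a stock of cases, not an incidence flow): cases in group k are
#' `persons_k * prevalence_rate_k / 1000`.
#'
#' @inheritParams expected_events
#' @param rates Calibrated per-1,000 T2D prevalence rates by group.
#' @return Numeric vector of prevalent cases per group.
#' @export
prevalent_t2d <- function(persons, rates) {
  expected_events(persons, rates)
}

#' Event rate per 1,000 implied by counts
#'
#' `1000 * events / persons`, with `NA` (undefined, not zero) where the
#' group is empty.
#'
#' @param events,persons Numeric vectors of equal length.
#' @return Per-1,000 rates; `NA` where `persons == 0`.
#' @export
group_rate <- function(events, persons) {
  ifelse(persons > 0, 1000 * events / persons, NA_real_)
}

#' New-onset type 2 diabetes attributable to antihypertensive drug class
#'
#' Some drug classes (classically beta-blockers and diuretics) carry an
#' excess risk of treatment-related new-onset diabetes. Attributable cases
#' for a class in group k are
#' `treated_k * share * continuation * baseline_incidence/1000 * (rr - 1)`,
#' floored at zero (protective classes do not subtract cases), then summed
#' over classes. Continuation scales the effect because only persisting
#' patients are exposed.
#'
#' @param treated Treated persons per risk group (length 5).
#' @param classes Tibble with columns `class`, `share` (of treated, summing
#'   to 1), `continuation` (in \[0,1\]) and `rr_nod` (>= 0).
#' @param baseline_incidence_per_1000 Baseline new-onset diabetes incidence
#'   among treated patients, per 1,000 patient-years.
#' @return A tibble `class`, `k`, `cases`; sum over classes within k for the
#'   per-group total.
#' @export
treatment_attributable_new_onset_t2d <- function(treated, classes,
                                                 baseline_incidence_per_1000) {
  need <- c("class", "share", "continuation", "rr_nod")
  if (!all(need %in% names(classes))) {
    stop("treatment_attributable_new_onset_t2d: classes needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(classes$rr_nod < 0)) {
    stop("treatment_attributable_new_onset_t2d: rr_nod must be non-negative",
         call. = FALSE)
  }
  stopifnot(length(treated) == 5L, all(treated >= 0),
            baseline_incidence_per_1000 >= 0)
  tidyr::crossing(classes[need], tibble::tibble(k = 0:4)) |>
    dplyr::mutate(
      cases = treated[.data$k + 1L] * .data$share * .data$continuation *
        baseline_incidence_per_1000 / 1000 * pmax(.data$rr_nod - 1, 0)
    ) |>
    dplyr::select("class", "k", "cases")
}
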