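# Projection of prevalences to a horizon year via compound annual growth
# rates (CAGRs), percent-rise reporting, and discounting of future costs.

#' Project a prevalence forward with a compound annual growth rate
#'
#' `p0 * (1 + g)^years`, capped at 1. Applies to component marginal
#' prevalences among hypertensives and to hypertension prevalence itself,
#' each with its own CAGR; demographic change enters the model separately
#' through the horizon-year population counts.
#'
#' @param p0 Base-year prevalence in \[0,1\].
#' @param g Fractional compound annual growth rate (> -1).
#' @param years Non-negative integer horizon.
#' @return The projected prevalence, capped at 1.
#' @export
#' @examples
#' project_marginal(0.1, 0.05, 12)  # 0.17959
project_marginal <- function(p0, g, years) {
  if (any(g <= -1)) {
    stop("project_marginal: growth rate must exceed -1", call. = FALSE)
  }
  stopifnot(all(p0 >= 0 & p0 <= 1), length(years) == 1L, years >= 0,
            years == as.integer(years))
  pmin(1, p0 * (1 + g)^years)
}

#' Discount a future cost back to the present
#'
#' Single-snapshot convention: the horizon-year annual cost is discounted
#' back over the whole base-to-horizon interval at a compound annual rate,
#' `amount / (1 + rate)^years`.
#'
#' @param amount Cost (any unit; euro millions throughout the package).
#' @param rate Fractional annual discount rate (> -1); the conventional
#'   health-economic value is 0.03.
#' @param years Non-negative integer number of years to discount over.
#' @return The discounted amount, same unit as `amount`.
#' @export
#' @examples
#' discount_cost(42769, 0.03, 12)  # ~29997
discount_cost <- function(amount, rate, years) {
  if (any(rate <= -1)) {
    stop("discount_cost: discount rate must exceed -1", call. = FALSE)
  }
  stopifnot(length(years) == 1L, years >= 0, years == as.integer(years))
  amount / (1 + rate)^years
}

#' Percent rise between a base and a horizon value
#'
#' Computed on unrounded totals; round at reporting time only (the
#' presentation convention is integer percentages, half away from zero).
#'
#' @param base,horizon Numeric; `base` must be positive.
#' @param rounded Round to integer percent? Default `FALSE`.
#' @return `100 * (horizon / base - 1)`.
#' @export
#' @examples
#' pct_rise(24427, 38955, rounded = TRUE)  # 59
pct_rise <- function(base, horizon, rounded = FALSE) {
  if (any(base <= 0)) stop("pct_rise: base must be positive", call. = FALSE)
  r <- 100 * (horizon / base - 1)
  if (rounded) round_half_up(r) else r
}
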