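# Cost aggregation: drug, physician, cardiovascular and type 2 diabetes
# components in euro millions per year, with the total as their exact sum
# before any rounding. Reports round at serialisation only.

#' Construct a cost breakdown
#'
#' The four annual cost components of the model, in euro millions, for one
#' population slice (a country-year, a MetS split, or one risk group). The
#' total is always the exact unrounded sum of the four components.
#'
#' @param drug,physician,cvd,t2d Annual costs in euro millions (equal-length
#'   numeric vectors, one element per slice).
#' @param slice Optional character label(s) for the slice(s).
#' @return A tibble of class `cost_breakdown` with columns `slice`, `drug`,
#'   `physician`, `cvd`, `t2d`, `total`.
#' @export
#' @examples
#' cost_breakdown(628, 1952, 5265, 16582, slice = "with MetS")$total
cost_breakdown <- function(drug, physician, cvd, t2d, slice = NA_character_) {
  n <- length(drug)
  stopifnot(length(physician) == n, length(cvd) == n, length(t2d) == n)
  if (any(c(drug, physician, cvd, t2d) < 0)) {
    stop("cost_breakdown: cost components must be non-negative", call. = FALSE)
  }
  out <- tibble::tibble(
    slice = rep_len(as.character(slice), n),
    drug = as.numeric(drug), physician = as.numeric(physician),
    cvd = as.numeric(cvd), t2d = as.numeric(t2d),
    total = as.numeric(drug) + as.numeric(physician) +
      as.numeric(cvd) + as.numeric(t2d)
  )
  class(out) <- c("cost_breakdown", class(out))
  out
}

cost_components <- function() c("drug", "physician", "cvd", "t2d")

#' Round half away from zero
#'
#' Presentation-style rounding used for printed euro-million and percentage
#' figures (`round()` in R rounds half to even). Internal arithmetic is
#' never rounded; this is applied at reporting time only.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Component shares of a cost breakdown
#'
#' Percentage of the total contributed by each of the four cost components.
#' Shares are computed from unrounded values and sum to 100 before any
#' rounding.
#'
#' @param breakdown A single-slice [cost_breakdown()] (one row).
#' @param rounded Round to integer percentages (half away from zero), the
#'   presentation convention? Default `FALSE`.
#' @return Named numeric vector of percentages (`drug`, `physician`, `cvd`,
#'   `t2d`).
#' @export
#' @examples
#' cost_shares(cost_breakdown(116, 126, 699, 968), rounded = TRUE)
cost_shares <- function(breakdown, rounded = FALSE) {
  stopifnot(inherits(breakdown, "cost_breakdown"), nrow(breakdown) == 1L)
  if (breakdown$total <= 0) {
    stop("cost_shares: total cost must be positive", call. = FALSE)
  }
  shares <- 100 * unlist(breakdown[cost_components()]) / breakdown$total
  names(shares) <- cost_components()
  if (rounded) round_half_up(shares) else shares
}

#' MetS share of the overall hypertension cost
#'
#' @param total_mets,total_non_mets Total annual costs (euro millions) of
#'   the hypertensive population with and without MetS.
#' @param rounded Round to an integer percentage? Default `FALSE`.
#' @return The MetS share of the overall cost, in percent.
#' @export
#' @examples
#' mets_cost_share(24427, 5341, rounded = TRUE)
mets_cost_share <- function(total_mets, total_non_mets, rounded = FALSE) {
  denom <- total_mets + total_non_mets
  if (any(denom <= 0)) {
    stop("mets_cost_share: overall cost must be positive", call. = FALSE)
  }
  share <- 100 * total_mets / denom
  if (rounded) round_half_up(share) else share
}

#' Annual costs per risk group
#'
#' Aggregates the four cost components for each risk group k = 0..4:
#' drug cost is treated persons times the continuation-weighted mean annual
#' class cost (drug and physician costs are distributed evenly across the
#' five risk groups — the same treated share and unit costs apply to every
#' group); physician cost is treated persons times visits per year times
#' the visit price; cardiovascular cost sums events times the event-type
#' acute price; diabetes cost is cases times the annual management price.
#' All outputs are in euro millions.
#'
#' @param persons Persons per risk group (length 5).
#' @param treated Treated persons per risk group (length 5).
#' @param events_by_outcome Numeric matrix (outcomes x 5) of annual event
#'   counts with row names naming the event types; every row name must have
#'   a price in `event_costs`. Death as an attributable-mortality outcome
#'   must NOT be included here (it carries no management cost) — only event
#'   types with an acute price.
#' @param t2d_cases Diabetes cases per risk group (length 5) feeding the
#'   annual management cost.
#' @param classes Tibble `class`, `share`, `annual_cost_eur`, `continuation`.
#' @param visits_per_year,visit_cost_eur Physician follow-up frequency and
#'   unit price for treated patients.
#' @param event_costs Named numeric vector of acute euro prices per event
#'   type.
#' @param t2d_annual_cost_eur Annual euro cost per prevalent diabetes case.
#' @return A [cost_breakdown()] with five rows, slices `"k0"`..`"k4"`.
#' @export
annual_costs <- function(persons, treated, events_by_outcome, t2d_cases,
                         classes, visits_per_year, visit_cost_eur,
                         event_costs, t2d_annual_cost_eur) {
  stopifnot(length(persons) == 5L, length(treated) == 5L,
            length(t2d_cases) == 5L)
  if (any(treated > persons + 1e-9)) {
    stop("annual_costs: treated persons exceed group population",
         call. = FALSE)
  }
  missing_price <- setdiff(rownames(events_by_outcome), names(event_costs))
  if (length(missing_price)) {
    stop("annual_costs: no unit cost for event type(s): ",
         paste(missing_price, collapse = ", "), call. = FALSE)
  }
  drug_per_treated <- sum(classes$share * classes$annual_cost_eur *
                            classes$continuation)
  drug <- treated * drug_per_treated / 1e6
  physician <- treated * visits_per_year * visit_cost_eur / 1e6
  cvd <- as.vector(
    crossprod(events_by_outcome,
              event_costs[rownames(events_by_outcome)])) / 1e6
  t2d <- t2d_cases * t2d_annual_cost_eur / 1e6
  cost_breakdown(drug, physician, cvd, t2d, slice = paste0("k", 0:4))
}

#' Aggregate a per-k cost breakdown to the MetS split
#'
#' @param by_k A five-row [cost_breakdown()] with slices `"k0"`..`"k4"`.
#' @return A three-row [cost_breakdown()] with slices `"mets"` (k >= 2),
#'   `"non_mets"` (k <= 1) and `"all"`; the split is cell-wise additive.
#' @export
aggregate_mets_split <- function(by_k) {
  stopifnot(inherits(by_k, "cost_breakdown"), nrow(by_k) == 5L)
  agg <- function(rows, label) {
    cost_breakdown(sum(by_k$drug[rows]), sum(by_k$physician[rows]),
                   sum(by_k$cvd[rows]), sum(by_k$t2d[rows]), slice = label)
  }
  dplyr::bind_rows(agg(3:5, "mets"), agg(1:2, "non_mets"), agg(1:5, "all"))
}

#' Mean annual cost per hypertensive patient by risk group
#'
#' An intensive quantity: total group cost (euro millions) times 1e6 over
#' group persons, in euros per patient-year. Empty groups report `NA`, not
#' zero.
#'
#' @param total_by_k Total annual cost per group, euro millions (length 5).
#' @param persons Persons per group (length 5).
#' @return Euros per patient-year by number of components present (length 5).
#' @export
per_patient_cost <- function(total_by_k, persons) {
  stopifnot(length(total_by_k) == 5L, length(persons) == 5L)
  ifelse(persons > 0, total_by_k * 1e6 / persons, NA_real_)
}
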