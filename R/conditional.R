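# Conditional component structure: per (age band, sex) stratum, the
# probability distribution over the 16 subsets of the four non-BP MetS
# components among hypertensive subjects, and its calibration to
# country-specific marginal prevalences by iterative proportional fitting
# (IPF). IPF rescales the table to new single-component margins while
# leaving every odds ratio (the interaction structure) unchanged — the
# natural formalisation of "applying" a reference conditional structure to
# another population.

#' Construct a conditional component-structure matrix
#'
#' A `conditional_matrix` holds, for each (age band, sex) stratum, the
#' probability vector over the 16 subsets of the four non-blood-pressure
#' MetS components, conditional on hypertension. Rows are strata (named
#' `"<age_band>:<sex>"`), columns the 16 canonical subset labels
#' ([subset_labels()]); every row must be non-negative and sum to 1.
#'
#' @param prob Numeric matrix (n_strata x 16), rows summing to 1 within
#'   1e-12 after the constructor's exact renormalisation guard; row names
#'   are stratum ids, column names must match [subset_labels()] (assigned
#'   if absent).
#' @return An object of class `conditional_matrix`.
#' @export
#' @examples
#' p <- matrix(rep(1 / 16, 16), nrow = 1,
#'             dimnames = list("20-29:female", subset_labels()))
#' conditional_matrix(p)
conditional_matrix <- function(prob) {
  prob <- as.matrix(prob)
  if (ncol(prob) != 16L) {
    stop("conditional_matrix: 16 subset columns required", call. = FALSE)
  }
  if (is.null(colnames(prob))) colnames(prob) <- subset_labels()
  if (!identical(colnames(prob), subset_labels())) {
    prob <- prob[, subset_labels(), drop = FALSE]
  }
  if (is.null(rownames(prob))) {
    stop("conditional_matrix: rows must be named by stratum", call. = FALSE)
  }
  if (any(prob < 0)) {
    stop("conditional_matrix: negative cell probability", call. = FALSE)
  }
  bad <- abs(rowSums(prob) - 1) > 1e-12
  if (any(bad)) {
    stop("conditional_matrix: rows do not sum to 1: ",
         paste(rownames(prob)[bad], collapse = ", "), call. = FALSE)
  }
  structure(prob, class = c("conditional_matrix", "matrix"))
}

#' @export
print.conditional_matrix <- function(x, ...) {
  cat("Conditional MetS component structure (", nrow(x), " strata x 16 subsets)\n",
      sep = "")
  cat("Implied component marginals among hypertensives:\n")
  print(round(implied_marginals(x), 4))
  invisible(x)
}

#' Component marginals implied by a conditional matrix
#'
#' @param matrix A [conditional_matrix()].
#' @return Numeric matrix (n_strata x 4): per stratum, the implied marginal
#'   prevalence of each non-BP component among hypertensives.
#' @export
implied_marginals <- function(matrix) {
  unclass(matrix) %*% subset_design()
}

#' Estimate the conditional component structure from microdata
#'
#' For every (age band, sex) stratum present in the records, tabulates the
#' survey-weighted relative frequency of the 16 non-BP component subsets
#' among the hypertensive records. This is the reference ("NHANES-style")
#' conditional structure later transferred to other populations by
#' [calibrate_to_marginals()].
#'
#' @param records Microdata as from [simulate_microdata()].
#' @return A [conditional_matrix()] with one row per stratum.
#' @export
estimate_conditional_matrix <- function(records) {
  comps <- mets_other_components()
  strata <- dplyr::distinct(records[c("age_band", "sex")]) |>
    dplyr::arrange(.data$age_band, .data$sex)
  htn <- records[as.logical(records$hypertension), , drop = FALSE]
  empty <- dplyr::anti_join(strata, dplyr::distinct(htn[c("age_band", "sex")]),
                            by = c("age_band", "sex"))
  if (nrow(empty)) {
    stop("estimate_conditional_matrix: no hypertensive records in strata: ",
         paste(stratum_id(empty$age_band, empty$sex), collapse = ", "),
         call. = FALSE)
  }
  prob <- matrix(0, nrow(strata), 16L,
                 dimnames = list(stratum_id(strata$age_band, strata$sex),
                                 subset_labels()))
  for (s in seq_len(nrow(strata))) {
    r <- htn[htn$age_band == strata$age_band[s] & htn$sex == strata$sex[s], ,
             drop = FALSE]
    fl <- as.matrix(r[comps])
    idx <- as.integer(fl %*% c(8L, 4L, 2L, 1L)) + 1L
    mass <- vapply(1:16, function(i) sum(r$weight[idx == i]), numeric(1))
    prob[s, ] <- mass / sum(mass)
  }
  conditional_matrix(prob)
}

# IPF on one 16-cell table: rescale to the four single-component margins
# `targets`, preserving all odds ratios. Zero cells are lifted to `eps`
# beforehand so any margin in (0,1) stays reachable.
ipf_fit_16 <- function(p, targets, tol = 1e-8, max_iter = 10000L,
                       eps = 1e-9) {
  d <- subset_design()
  stopifnot(length(p) == 16L, length(targets) == 4L)
  if (any(targets <= 0 | targets >= 1)) {
    stop("ipf_fit_16: fitting margins must lie strictly in (0,1)",
         call. = FALSE)
  }
  if (max_iter < 1L) {
    stop("ipf_fit_16: max_iter must be at least 1", call. = FALSE)
  }
  p <- pmax(p, eps)
  p <- p / sum(p)
  history <- numeric(0)
  disc <- Inf
  for (it in seq_len(max_iter)) {
    for (cc in 1:4) {
      on <- d[, cc] == 1L
      m <- sum(p[on])
      p[on] <- p[on] * (targets[cc] / m)
      p[!on] <- p[!on] * ((1 - targets[cc]) / (1 - m))
    }
    disc <- max(abs(as.vector(crossprod(p, d)) - targets))
    history <- c(history, disc)
    if (disc < tol) {
      return(list(p = p, iterations = it, discrepancy = disc,
                  history = history))
    }
  }
  stop(sprintf(
    "ipf_fit_16: no convergence after %d iterations (worst marginal discrepancy %.3e)",
    max_iter, disc), call. = FALSE)
}

#' Calibrate a conditional structure to new marginal prevalences
#'
#' Adjusts each stratum's 16-cell subset distribution so that the implied
#' marginal prevalence of every non-BP component matches a country-specific
#' target, by iterative proportional fitting with the four single-component
#' marginals as fitting margins. IPF preserves the reference's interaction
#' (odds-ratio) structure exactly, so the clustering pattern of the
#' reference population carries over while its component levels are replaced
#' by the targets.
#'
#' Cells with zero reference mass are lifted to 1e-9 before fitting so any
#' margin strictly inside (0,1) remains reachable.
#'
#' @param reference A [conditional_matrix()].
#' @param targets Tibble `age_band`, `sex`, `component`, `target` with one
#'   row per stratum and non-BP component, targets strictly in (0,1)
#'   (values outside are epsilon-clipped to `[1e-6, 1 - 1e-6]`).
#' @param tol Convergence tolerance on the worst absolute marginal
#'   discrepancy (default 1e-8).
#' @param max_iter Maximum IPF iterations per stratum (default 10000).
#' @return A [conditional_matrix()] whose implied marginals match the
#'   targets within `tol`, with attributes `iterations` (per stratum) and
#'   `discrepancy` (per stratum, final) for logging.
#' @export
calibrate_to_marginals <- function(reference, targets, tol = 1e-8,
                                   max_iter = 10000L) {
  stopifnot(inherits(reference, "conditional_matrix"))
  need <- c("age_band", "sex", "component", "target")
  if (!all(need %in% names(targets))) {
    stop("calibrate_to_marginals: targets needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  comps <- mets_other_components()
  out <- unclass(reference)
  iters <- discs <- setNames(numeric(nrow(out)), rownames(out))
  for (sid in rownames(out)) {
    parts <- strsplit(sid, ":", fixed = TRUE)[[1]]
    tg <- targets |>
      dplyr::filter(.data$age_band == parts[1], .data$sex == parts[2])
    if (nrow(tg) != 4L || !setequal(tg$component, comps)) {
      stop("calibrate_to_marginals: targets must cover all four components ",
           "for stratum ", sid, call. = FALSE)
    }
    t4 <- setNames(tg$target, tg$component)[comps]
    t4 <- pmin(pmax(t4, 1e-6), 1 - 1e-6)
    fit <- ipf_fit_16(out[sid, ], t4, tol = tol, max_iter = max_iter)
    out[sid, ] <- fit$p
    iters[sid] <- fit$iterations
    discs[sid] <- fit$discrepancy
  }
  res <- conditional_matrix(out)
  attr(res, "iterations") <- iters
  attr(res, "discrepancy") <- discs
  res
}

#' Decompose hypertensive person-counts into the five risk groups
#'
#' Applies a (calibrated) conditional structure to per-stratum hypertensive
#' person-counts: the count in risk group k is the stratum count times the
#' total probability of the subsets with exactly k components present.
#' Persons are conserved exactly — per stratum the five group counts sum to
#' the input count — and the MetS count is the k >= 2 total.
#'
#' @param htn_counts Tibble `age_band`, `sex`, `htn_count` (counts >= 0).
#' @param matrix A [conditional_matrix()] covering every stratum in
#'   `htn_counts`.
#' @return A tibble with columns `age_band`, `sex`, `htn_count`,
#'   `k0`..`k4`, `mets_count`, `non_mets_count`.
#' @export
decompose_population <- function(htn_counts, matrix) {
  stopifnot(inherits(matrix, "conditional_matrix"))
  need <- c("age_band", "sex", "htn_count")
  if (!all(need %in% names(htn_counts))) {
    stop("decompose_population: htn_counts needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(htn_counts$htn_count < 0)) {
    stop("decompose_population: negative hypertensive count", call. = FALSE)
  }
  sids <- stratum_id(htn_counts$age_band, htn_counts$sex)
  missing_s <- setdiff(sids, rownames(matrix))
  if (length(missing_s)) {
    stop("decompose_population: strata missing from conditional matrix: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  k <- subset_k()
  # aggregate subset probabilities to P(k = 0..4) per stratum
  agg <- vapply(0:4, function(kk) {
    rowSums(unclass(matrix)[sids, k == kk, drop = FALSE])
  }, numeric(length(sids)))
  if (length(sids) == 1L) agg <- matrix(agg, nrow = 1L)
  counts <- agg * htn_counts$htn_count
  colnames(counts) <- paste0("k", 0:4)
  dplyr::bind_cols(
    tibble::as_tibble(htn_counts[need]),
    tibble::as_tibble(counts)
  ) |>
    dplyr::mutate(
      mets_count = .data$k2 + .data$k3 + .data$k4,
      non_mets_count = .data$k0 + .data$k1
    )
}
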