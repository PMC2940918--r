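#' Default age bands and stratum shares for the microdata generator
#'
#' Seven age bands from 20 upwards crossed with sex. The default population
#' shares decline with age roughly like a western-European adult age pyramid
#' and split evenly by sex; they are generator defaults, not national data.
#'
#' @return A tibble with columns `age_band`, `sex`, `share` (summing to 1).
#' @export
default_strata <- function() {
  bands <- c("20-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80+")
  band_share <- c(0.16, 0.16, 0.18, 0.16, 0.14, 0.12, 0.08)
  tidyr::crossing(
    age_band = factor(bands, levels = bands),
    sex = c("female", "male")
  ) |>
    dplyr::arrange(.data$age_band, .data$sex) |>
    dplyr::mutate(
      share = rep(band_share, each = 2L) / 2,
      age_band = as.character(.data$age_band)
    )
}

#' Specification of a synthetic survey-microdata generator
#'
#' Describes an NHANES-like weighted microdata set: stratified by age band
#' and sex, with a marginal prevalence for each of the five MetS components
#' per stratum and a latent-Gaussian (Gaussian copula) dependence structure
#' shared across strata. Each subject's five binary component indicators are
#' obtained by thresholding a multivariate normal draw at the Gaussian
#' quantiles of the stratum marginals, so the `association` matrix is the
#' latent (tetrachoric-style) correlation of the indicators.
#'
#' @param n_subjects Number of subjects to draw.
#' @param seed Integer seed; a fixed seed gives a bit-identical record
#'   stream. Default 20080101.
#' @param strata Tibble `age_band`, `sex`, `share` with shares summing to 1;
#'   default [default_strata()].
#' @param marginals Either a named numeric vector of length 5 (one
#'   prevalence in (0,1) per component of [mets_components()], recycled
#'   across strata) or a tibble `age_band`, `sex`, `component`, `prevalence`
#'   covering every stratum/component pair.
#' @param association Symmetric 5 x 5 latent correlation matrix with unit
#'   diagonal, rows/columns in [mets_components()] order; must be positive
#'   semi-definite. Default identity (independent components).
#' @param weight_model `"equal"` (all survey weights 1) or `"lognormal"`
#'   (weights `rlnorm(0, weight_sigma)`).
#' @param weight_sigma Log-scale SD for `weight_model = "lognormal"`.
#' @return An object of class `microdata_spec`.
#' @export
#' @examples
#' spec <- microdata_spec(1000, marginals = c(
#'   hypertension = 0.35, obesity = 0.4, low_hdl = 0.25,
#'   high_tg = 0.35, impaired_glucose = 0.25))
#' head(simulate_microdata(spec))
microdata_spec <- function(n_subjects, seed = 20080101,
                           strata = default_strata(),
                           marginals,
                           association = diag(5),
                           weight_model = c("equal", "lognormal"),
                           weight_sigma = 0.5) {
  weight_model <- match.arg(weight_model)
  stopifnot(is.numeric(n_subjects), length(n_subjects) == 1L, n_subjects >= 1)
  comps <- mets_components()

  if (!all(c("age_band", "sex", "share") %in% names(strata))) {
    stop("microdata_spec: strata needs columns age_band, sex, share",
         call. = FALSE)
  }
  if (abs(sum(strata$share) - 1) > 1e-8) {
    stop("microdata_spec: stratum shares must sum to 1", call. = FALSE)
  }

  if (is.numeric(marginals) && !is.data.frame(marginals)) {
    if (!all(comps %in% names(marginals))) {
      stop("microdata_spec: marginal vector must name all five components",
           call. = FALSE)
    }
    marginals <- tidyr::crossing(
      strata[c("age_band", "sex")],
      tibble::tibble(component = comps)
    ) |>
      dplyr::mutate(prevalence = unname(marginals[.data$component]))
  }
  need <- c("age_band", "sex", "component", "prevalence")
  if (!all(need %in% names(marginals))) {
    stop("microdata_spec: marginals needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  covered <- nrow(dplyr::inner_join(
    tidyr::crossing(strata[c("age_band", "sex")],
                    tibble::tibble(component = comps)),
    marginals, by = c("age_band", "sex", "component")
  ))
  if (covered != nrow(strata) * 5L) {
    stop("microdata_spec: marginals must cover every stratum/component pair",
         call. = FALSE)
  }
  if (any(marginals$prevalence <= 0 | marginals$prevalence >= 1)) {
    stop("microdata_spec: marginal prevalences must lie strictly in (0,1)",
         call. = FALSE)
  }

  association <- as.matrix(association)
  if (!isTRUE(all.equal(dim(association), c(5L, 5L))) ||
      max(abs(association - t(association))) > 1e-10 ||
      max(abs(diag(association) - 1)) > 1e-10) {
    stop("microdata_spec: association must be a symmetric 5x5 matrix with ",
         "unit diagonal", call. = FALSE)
  }
  if (min(eigen(association, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8) {
    stop("microdata_spec: association matrix is not positive semi-definite",
         call. = FALSE)
  }
  dimnames(association) <- list(comps, comps)

  structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         strata = tibble::as_tibble(strata),
         marginals = tibble::as_tibble(marginals),
         association = association,
         weight_model = weight_model, weight_sigma = weight_sigma),
    class = "microdata_spec"
  )
}

# Integer ages drawn uniformly within a band; the open-ended band covers
# 80-89.
sample_ages <- function(age_band, n) {
  if (age_band == "80+") return(sample(80:89, n, replace = TRUE))
  lims <- as.integer(strsplit(age_band, "-", fixed = TRUE)[[1]])
  sample(lims[1]:lims[2], n, replace = TRUE)
}

#' Generate synthetic survey microdata
#'
#' Draws weighted subject records according to a [microdata_spec()]: stratum
#' membership is multinomial in the stratum shares, and within each stratum
#' the five component indicators are a thresholded multivariate-normal draw
#' with the spec's latent correlation matrix, thresholds placed at the
#' Gaussian quantiles of the stratum marginals. Reproducible: a fixed spec
#' (including seed) yields a bit-identical record stream, and the caller's
#' RNG state is left untouched.
#'
#' @param spec A [microdata_spec()].
#' @return A tibble with columns `subject_id`, `age_band`, `age`, `sex`,
#'   `weight` and the five 0/1 component indicator columns in
#'   [mets_components()] order.
#' @export
simulate_microdata <- function(spec) {
  stopifnot(inherits(spec, "microdata_spec"))
  comps <- mets_components()
  withr::with_seed(spec$seed, {
    n_strata <- nrow(spec$strata)
    counts <- as.vector(rmultinom(1L, spec$n_subjects, spec$strata$share))
    pieces <- vector("list", n_strata)
    for (s in seq_len(n_strata)) {
      n_s <- counts[s]
      if (n_s == 0L) next
      band <- spec$strata$age_band[s]
      sx <- spec$strata$sex[s]
      p <- spec$marginals |>
        dplyr::filter(.data$age_band == band, .data$sex == sx)
      p <- setNames(p$prevalence, p$component)[comps]
      z <- MASS::mvrnorm(n_s, mu = rep(0, 5), Sigma = spec$association)
      if (n_s == 1L) z <- matrix(z, nrow = 1L)
      flags <- sweep(z, 2L, qnorm(1 - p), `>`) * 1L
      colnames(flags) <- comps
      w <- switch(spec$weight_model,
        equal = rep(1, n_s),
        lognormal = rlnorm(n_s, 0, spec$weight_sigma)
      )
      pieces[[s]] <- tibble::tibble(
        age_band = band, age = sample_ages(band, n_s), sex = sx, weight = w
      ) |>
        dplyr::bind_cols(tibble::as_tibble(flags))
    }
    out <- dplyr::bind_rows(pieces)
    out$subject_id <- seq_len(nrow(out))
    dplyr::relocate(out, "subject_id")
  })
}

#' Weighted joint distribution of the five components in one stratum
#'
#' Tabulates the survey-weighted joint distribution of the 32 combinations
#' of the five MetS component indicators among the records of one
#' (age band, sex) stratum. Cells are labelled by the five concatenated
#' indicator bits in [mets_components()] order (hypertension most
#' significant) and sum to 1; survey weights are used, so the result is
#' invariant to rescaling all weights.
#'
#' @param records Microdata as returned by [simulate_microdata()] (or any
#'   data frame with `age_band`, `sex`, `weight` and the five 0/1 component
#'   columns).
#' @param age_band,sex The stratum to tabulate.
#' @return A named numeric vector of length 32 summing to 1, in canonical
#'   cell order.
#' @export
empirical_joint <- function(records, age_band, sex) {
  comps <- mets_components()
  need <- c("age_band", "sex", "weight", comps)
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("empirical_joint: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sel <- records$age_band == age_band & records$sex == sex
  if (!any(sel)) {
    stop("empirical_joint: no records in stratum ", stratum_id(age_band, sex),
         call. = FALSE)
  }
  r <- records[sel, , drop = FALSE]
  fl <- as.matrix(r[comps])
  idx <- as.integer(fl %*% c(16L, 8L, 4L, 2L, 1L)) + 1L
  mass <- vapply(seq_len(32L), function(i) sum(r$weight[idx == i]), numeric(1))
  mass <- mass / sum(mass)
  names(mass) <- cell_labels_32()
  mass
}
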