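#' Modified ATP III diagnostic thresholds
#'
#' Threshold set for the modified ATP III definition of metabolic syndrome
#' used throughout the package. The blood-pressure cut-off is the modified
#' one (140/90 mm Hg, the treatment threshold in European and US
#' guidelines) rather than the original 135/85; pass
#' `sbp_mmHg = 135, dbp_mmHg = 85` for the unmodified profile.
#'
#' Inequality directions are part of the definition and are applied exactly
#' by [classify_components()]: waist strictly greater-than, HDL strictly
#' less-than, triglycerides / glucose / blood pressure inclusive
#' greater-or-equal.
#'
#' @param waist_cm_male,waist_cm_female Abdominal obesity waist cut-offs (cm).
#' @param sbp_mmHg,dbp_mmHg Systolic / diastolic blood pressure cut-offs
#'   (mm Hg); hypertension is SBP >= `sbp_mmHg` OR DBP >= `dbp_mmHg`.
#' @param hdl_mgdl_male,hdl_mgdl_female Low-HDL cut-offs (mg/dL).
#' @param tg_mgdl Triglyceride cut-off (mg/dL).
#' @param fpg_mgdl Fasting plasma glucose cut-off (mg/dL); known diabetes
#'   satisfies the glucose criterion regardless of the measured value.
#' @return An object of class `atp3_thresholds`.
#' @export
#' @examples
#' atp3_thresholds()
#' atp3_thresholds(sbp_mmHg = 135, dbp_mmHg = 85)  # unmodified ATP III BP
atp3_thresholds <- function(waist_cm_male = 102, waist_cm_female = 88,
                            sbp_mmHg = 140, dbp_mmHg = 90,
                            hdl_mgdl_male = 40, hdl_mgdl_female = 50,
                            tg_mgdl = 150, fpg_mgdl = 110) {
  th <- list(
    waist_cm_male = waist_cm_male, waist_cm_female = waist_cm_female,
    sbp_mmHg = sbp_mmHg, dbp_mmHg = dbp_mmHg,
    hdl_mgdl_male = hdl_mgdl_male, hdl_mgdl_female = hdl_mgdl_female,
    tg_mgdl = tg_mgdl, fpg_mgdl = fpg_mgdl
  )
  bad <- vapply(th, function(x) !is.numeric(x) || length(x) != 1L ||
                  !is.finite(x) || x <= 0, logical(1))
  if (any(bad)) {
    stop("atp3_thresholds: all thresholds must be single positive numbers; ",
         "offending: ", paste(names(th)[bad], collapse = ", "), call. = FALSE)
  }
  structure(th, class = "atp3_thresholds")
}

#' @export
print.atp3_thresholds <- function(x, ...) {
  cat("Modified ATP III thresholds:\n")
  cat(sprintf("  waist     > %g cm (M) / > %g cm (F)\n",
              x$waist_cm_male, x$waist_cm_female))
  cat(sprintf("  BP        >= %g/%g mm Hg\n", x$sbp_mmHg, x$dbp_mmHg))
  cat(sprintf("  HDL       < %g mg/dL (M) / < %g mg/dL (F)\n",
              x$hdl_mgdl_male, x$hdl_mgdl_female))
  cat(sprintf("  TG        >= %g mg/dL\n", x$tg_mgdl))
  cat(sprintf("  FPG       >= %g mg/dL or known diabetes\n", x$fpg_mgdl))
  invisible(x)
}

#' Classify subjects against the modified ATP III component criteria
#'
#' Turns raw clinical measurements into the five MetS component indicators.
#' The rules, with their exact inequality directions, are:
#' abdominal obesity if waist strictly exceeds the sex-specific cut-off;
#' hypertension if SBP >= 140 OR DBP >= 90 mm Hg (or, optionally, the
#' subject is on antihypertensive treatment — see Details); low HDL if HDL is
#' strictly below the sex-specific cut-off; high triglycerides if
#' TG >= 150 mg/dL; impaired fasting glucose if FPG >= 110 mg/dL or the
#' subject has known diabetes.
#'
#' @details
#' Treated-but-controlled hypertensives (BP below threshold on medication)
#' are counted as hypertensive when an `on_antihypertensives` column is
#' present and `TRUE` — the population of interest is defined by the
#' condition, not by momentary control. Omit the column (or set it `FALSE`)
#' to classify on measured pressure alone.
#'
#' @param data A data frame with one row per subject and columns `sex`
#'   (`"male"`/`"female"`), `waist_cm`, `sbp_mmHg`, `dbp_mmHg`, `hdl_mgdl`,
#'   `tg_mgdl`, `fpg_mgdl`, `known_diabetes` (logical), and optionally
#'   `on_antihypertensives` (logical).
#' @param thresholds An [atp3_thresholds()] object.
#' @return A tibble with five logical columns `obesity`, `hypertension`,
#'   `low_hdl`, `high_tg`, `impaired_glucose`, one row per subject.
#' @export
#' @examples
#' subj <- data.frame(
#'   sex = c("male", "female"), waist_cm = c(103, 80),
#'   sbp_mmHg = c(139, 150), dbp_mmHg = c(90, 80),
#'   hdl_mgdl = c(39, 50), tg_mgdl = c(150, 120),
#'   fpg_mgdl = c(110, 95), known_diabetes = c(FALSE, FALSE)
#' )
#' classify_components(subj)
classify_components <- function(data, thresholds = atp3_thresholds()) {
  stopifnot(inherits(thresholds, "atp3_thresholds"))
  required <- c("sex", "waist_cm", "sbp_mmHg", "dbp_mmHg", "hdl_mgdl",
                "tg_mgdl", "fpg_mgdl", "known_diabetes")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("classify_components: missing measurement column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- setdiff(required, c("sex", "known_diabetes"))
  for (col in numeric_cols) {
    x <- data[[col]]
    if (anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
      stop("classify_components: column '", col,
           "' contains missing, non-finite or negative values",
           call. = FALSE)
    }
  }
  sex <- as.character(data$sex)
  if (anyNA(sex) || !all(sex %in% c("male", "female"))) {
    stop("classify_components: 'sex' must be \"male\" or \"female\"",
         call. = FALSE)
  }
  kd <- data$known_diabetes
  if (anyNA(kd)) {
    stop("classify_components: column 'known_diabetes' contains missing values",
         call. = FALSE)
  }
  on_tx <- if ("on_antihypertensives" %in% names(data)) {
    isTRUE_vec <- data$on_antihypertensives
    if (anyNA(isTRUE_vec)) {
      stop("classify_components: column 'on_antihypertensives' contains ",
           "missing values", call. = FALSE)
    }
    as.logical(isTRUE_vec)
  } else {
    rep(FALSE, nrow(data))
  }

  male <- sex == "male"
  waist_cut <- ifelse(male, thresholds$waist_cm_male, thresholds$waist_cm_female)
  hdl_cut <- ifelse(male, thresholds$hdl_mgdl_male, thresholds$hdl_mgdl_female)

  tibble::tibble(
    obesity = data$waist_cm > waist_cut,
    hypertension = data$sbp_mmHg >= thresholds$sbp_mmHg |
      data$dbp_mmHg >= thresholds$dbp_mmHg | on_tx,
    low_hdl = data$hdl_mgdl < hdl_cut,
    high_tg = data$tg_mgdl >= thresholds$tg_mgdl,
    impaired_glucose = data$fpg_mgdl >= thresholds$fpg_mgdl | as.logical(kd)
  )
}

#' Assign the risk category of a hypertensive subject
#'
#' The model stratifies the hypertensive population into five risk groups by
#' the number `k_other` of additional (non-blood-pressure) MetS components
#' present, 0 to 4, and into the two-way MetS split: a hypertensive subject
#' has MetS iff at least two other components are present (i.e. at least
#' three of five in total — the ATP III "three of five" rule). Together these
#' form the model's seven risk categories.
#'
#' Non-hypertensive subjects are outside the model and are refused with an
#' error rather than silently dropped; filter upstream.
#'
#' @param flags A data frame of component indicators as returned by
#'   [classify_components()] (logical or 0/1 columns `obesity`,
#'   `hypertension`, `low_hdl`, `high_tg`, `impaired_glucose`).
#' @return A tibble with integer column `k_other` (0..4) and logical `mets`.
#' @export
#' @examples
#' flags <- data.frame(obesity = FALSE, hypertension = TRUE,
#'                     low_hdl = TRUE, high_tg = TRUE,
#'                     impaired_glucose = FALSE)
#' assign_risk_category(flags)  # k_other 2, mets TRUE
assign_risk_category <- function(flags) {
  needed <- mets_components()
  missing_cols <- setdiff(needed, names(flags))
  if (length(missing_cols)) {
    stop("assign_risk_category: missing flag column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  htn <- as.logical(flags$hypertension)
  if (anyNA(htn) || !all(htn)) {
    stop("assign_risk_category: all subjects must be hypertensive; ",
         "the model covers the hypertensive population only", call. = FALSE)
  }
  other <- as.matrix(flags[mets_other_components()])
  storage.mode(other) <- "integer"
  k <- as.integer(rowSums(other))
  tibble::tibble(k_other = k, mets = k >= 2L)
}
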