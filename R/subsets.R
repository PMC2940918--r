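# Canonical enumeration of the 2^4 = 16 subsets of the four non-blood-pressure
# MetS components and the 2^5 = 32 cells of the full component space.
#
# Canonical order is binary counting with obesity as the most significant bit:
# obesity -> low_hdl -> high_tg -> impaired_glucose, so cell "1010" means
# obesity and high triglycerides present, low HDL and impaired glucose absent.
# For the 32-cell space hypertension is prepended as the highest bit.

#' Names of the MetS components
#'
#' `mets_components()` returns the five modified ATP III components in the
#' package's canonical order; `mets_other_components()` returns the four
#' non-blood-pressure components used to define the risk groups k = 0..4.
#'
#' @return Character vector of component names.
#' @export
#' @examples
#' mets_components()
mets_components <- function() {
  c("hypertension", "obesity", "low_hdl", "high_tg", "impaired_glucose")
}

#' @rdname mets_components
#' @export
mets_other_components <- function() {
  c("obesity", "low_hdl", "high_tg", "impaired_glucose")
}

#' Design matrix of the 16 non-BP component subsets
#'
#' Enumerates the 16 subsets of \{obesity, low HDL, high triglycerides,
#' impaired fasting glucose\} in canonical binary order (obesity most
#' significant). Row names are the four concatenated indicator bits.
#'
#' @return A 16 x 4 integer 0/1 matrix with one column per component and an
#'   attribute-free canonical row order; `rowSums()` gives the component
#'   count k of each subset.
#' @export
#' @examples
#' subset_design()["1010", ]
#' table(rowSums(subset_design()))  # choose(4, 0:4)
subset_design <- function() {
  comps <- mets_other_components()
  idx <- 0:15
  m <- cbind(
    obesity          = bitwAnd(bitwShiftR(idx, 3L), 1L),
    low_hdl          = bitwAnd(bitwShiftR(idx, 2L), 1L),
    high_tg          = bitwAnd(bitwShiftR(idx, 1L), 1L),
    impaired_glucose = bitwAnd(idx, 1L)
  )
  rownames(m) <- apply(m, 1L, paste, collapse = "")
  colnames(m) <- comps
  m
}

#' @rdname subset_design
#' @export
subset_labels <- function() rownames(subset_design())

#' @rdname subset_design
#' @export
subset_k <- function() {
  k <- rowSums(subset_design())
  names(k) <- subset_labels()
  k
}

# Labels for the 32 cells of the full five-component space, hypertension as
# the most significant bit.
cell_labels_32 <- function() {
  as.vector(vapply(0:1, function(h) paste0(h, subset_labels()), character(16)))
}

# One stratum id per (age band, sex) pair, used as matrix row names.
stratum_id <- function(age_band, sex) paste(age_band, sex, sep = ":")
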