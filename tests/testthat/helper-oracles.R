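# Independent numeric oracles used across the suite.

# P(Z1 > a, Z2 > b) for standard bivariate normal with correlation rho,
# by 1-D numerical integration over z1 (no closed form needed):
# integral over z1 > a of phi(z1) * P(Z2 > b | Z1 = z1).
orthant_prob <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(pnorm(a, lower.tail = FALSE) *
                                  pnorm(b, lower.tail = FALSE))
  f <- function(z) {
    dnorm(z) * pnorm((b - rho * z) / sqrt(1 - rho^2), lower.tail = FALSE)
  }
  stats::integrate(f, lower = a, upper = Inf, rel.tol = 1e-10)$value
}

# 2x2 cell probabilities (p00, p01, p10, p11) of two latent-Gaussian binary
# indicators with marginals p1, p2 and latent correlation rho.
biv_cells <- function(p1, p2, rho) {
  a <- qnorm(1 - p1)
  b <- qnorm(1 - p2)
  p11 <- orthant_prob(a, b, rho)
  c(p00 = 1 - p1 - p2 + p11, p01 = p2 - p11, p10 = p1 - p11, p11 = p11)
}

# Closed-form 2x2 table with margins (m1, m2) and odds ratio orr:
# p11 solves the quadratic orr*(m1-p11)*(m2-p11) = p11*(1-m1-m2+p11).
or22_cells <- function(m1, m2, orr) {
  if (abs(orr - 1) < 1e-12) {
    p11 <- m1 * m2
  } else {
    A <- orr - 1
    B <- -(orr * (m1 + m2) + (1 - m1 - m2))
    C <- orr * m1 * m2
    roots <- (-B + c(-1, 1) * sqrt(B^2 - 4 * A * C)) / (2 * A)
    p11 <- roots[roots > max(0, m1 + m2 - 1) & roots < min(m1, m2)]
    stopifnot(length(p11) == 1L)
  }
  c(p00 = 1 - m1 - m2 + p11, p01 = m2 - p11, p10 = m1 - p11, p11 = p11)
}

# Kronecker expansion of two 2x2 tables (components A, B) x (C, D) into the
# canonical 16-cell order of subset_design() given the component pairing:
# cells_ab over (obesity, low_hdl), cells_cd over (high_tg, glucose).
expand_16 <- function(cells_ab, cells_cd) {
  d <- subset_design()
  p <- numeric(16)
  for (i in 1:16) {
    ab <- paste0("p", d[i, "obesity"], d[i, "low_hdl"])
    cd <- paste0("p", d[i, "high_tg"], d[i, "impaired_glucose"])
    p[i] <- cells_ab[[ab]] * cells_cd[[cd]]
  }
  names(p) <- subset_labels()
  p
}

# Empirical odds ratio of two 0/1 columns.
emp_or <- function(x, y) {
  n11 <- sum(x == 1 & y == 1); n00 <- sum(x == 0 & y == 0)
  n10 <- sum(x == 1 & y == 0); n01 <- sum(x == 0 & y == 1)
  (n11 * n00) / (n10 * n01)
}

# A one-band microdata spec with controllable association, handy for
# conditional-structure tests (two strata: one per sex).
one_band_spec <- function(n, seed, marginals, association,
                          weight_model = "equal") {
  strata <- tibble::tibble(
    age_band = "20-29", sex = c("female", "male"), share = c(0.5, 0.5))
  microdata_spec(n, seed = seed, strata = strata, marginals = marginals,
                 association = association, weight_model = weight_model)
}
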