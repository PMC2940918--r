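# Conditional component structure: estimation, IPF calibration and the
# risk-group decomposition.

uniform_matrix <- function(strata = "20-29:female") {
  conditional_matrix(matrix(1 / 16, length(strata), 16,
                            dimnames = list(strata, subset_labels())))
}

test_that("estimation tallies weighted subset frequencies among hypertensives", {
  # degenerate: every hypertensive has zero other components
  rec <- tibble::tibble(
    age_band = "20-29", sex = "female", weight = 1,
    hypertension = c(1L, 1L, 0L), obesity = c(0L, 0L, 1L),
    low_hdl = 0L, high_tg = 0L, impaired_glucose = 0L
  )
  cm <- estimate_conditional_matrix(rec)
  expect_equal(unname(unclass(cm)["20-29:female", "0000"]), 1)

  # 20-record fixture with weights, tallied by hand
  rec20 <- tibble::tibble(
    age_band = "40-49", sex = "male",
    weight = rep(c(1, 2, 3, 4), 5),
    hypertension = rep(c(1L, 1L, 1L, 0L), 5),
    obesity = rep(c(1L, 0L), 10),
    low_hdl = rep(c(1L, 1L, 0L, 0L), 5),
    high_tg = 0L,
    impaired_glucose = rep(c(0L, 1L), 10)
  )
  cm20 <- estimate_conditional_matrix(rec20)
  # hypertensive weight = 5 x (1 + 2 + 3) = 30; patterns repeat in blocks:
  # (o=1,l=1,g=0) w1, (o=0,l=1,g=1) w2, (o=1,l=0,g=0) w3 -> each x5
  p <- unclass(cm20)["40-49:male", ]
  expect_equal(unname(p["1100"]), 5 / 30)
  expect_equal(unname(p["0101"]), 10 / 30)
  expect_equal(unname(p["1000"]), 15 / 30)
  expect_equal(sum(p), 1)
})

test_that("estimation equals the 32-cell joint restricted to hypertensives", {
  spec <- one_band_spec(20000, seed = 21,
                        marginals = setNames(c(0.4, 0.35, 0.3, 0.35, 0.25),
                                             mets_components()),
                        association = 0.25 + 0.75 * diag(5),
                        weight_model = "lognormal")
  rec <- simulate_microdata(spec)
  cm <- estimate_conditional_matrix(rec)
  j <- empirical_joint(rec, "20-29", "female")
  htn_cells <- j[17:32]  # hypertension bit set, same subset order
  expect_equal(unname(unclass(cm)["20-29:female", ]),
               unname(htn_cells / sum(htn_cells)))
})

test_that("strata without hypertensive records are refused by name", {
  rec <- tibble::tibble(
    age_band = c("20-29", "30-39"), sex = "male", weight = 1,
    hypertension = c(1L, 0L), obesity = 0L, low_hdl = 0L, high_tg = 0L,
    impaired_glucose = 0L
  )
  expect_error(estimate_conditional_matrix(rec), "30-39:male")
})

test_that("IPF leaves a matrix already at its targets unchanged", {
  spec <- one_band_spec(20000, seed = 22,
                        marginals = setNames(c(0.4, 0.4, 0.3, 0.35, 0.3),
                                             mets_components()),
                        association = 0.3 + 0.7 * diag(5))
  cm <- estimate_conditional_matrix(simulate_microdata(spec))
  marg <- implied_marginals(cm)
  targets <- tidyr::crossing(
    tibble::tibble(age_band = "20-29", sex = c("female", "male")),
    tibble::tibble(component = mets_other_components())
  )
  targets$target <- mapply(function(s, cc) {
    marg[stratum_id("20-29", s), cc]
  }, targets$sex, targets$component)
  out <- calibrate_to_marginals(cm, targets)
  expect_equal(unclass(out), unclass(cm), tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("an independence reference calibrates to the product distribution", {
  ref <- uniform_matrix()  # uniform = independent with marginals 1/2
  t4 <- c(obesity = 0.3, low_hdl = 0.6, high_tg = 0.2,
          impaired_glucose = 0.45)
  targets <- tibble::tibble(age_band = "20-29", sex = "female",
                            component = names(t4), target = unname(t4))
  out <- calibrate_to_marginals(ref, targets)
  d <- subset_design()
  expected <- apply(d, 1L, function(row) {
    prod(ifelse(row == 1, t4, 1 - t4))
  })
  expect_equal(unname(unclass(out)[1, ]), unname(expected), tolerance = 1e-7)
})

test_that("IPF matches the closed-form 2x2 odds-ratio-preserving solution", {
  # reference: (obesity, low_hdl) 2x2 with OR 4 and margins 0.4/0.4,
  # independent (high_tg, glucose) at 0.3 each
  ref16 <- expand_16(or22_cells(0.4, 0.4, 4), or22_cells(0.3, 0.3, 1))
  ref <- conditional_matrix(matrix(ref16, 1,
                                   dimnames = list("20-29:female",
                                                   subset_labels())))
  targets <- tibble::tibble(
    age_band = "20-29", sex = "female",
    component = mets_other_components(), target = c(0.5, 0.5, 0.3, 0.3))
  out <- calibrate_to_marginals(ref, targets)
  # closed form: margins 0.5/0.5 with OR 4 -> cells (1/3, 1/6, 1/6, 1/3)
  truth <- expand_16(or22_cells(0.5, 0.5, 4), or22_cells(0.3, 0.3, 1))
  expect_equal(unname(or22_cells(0.5, 0.5, 4)),
               unname(c(1 / 3, 1 / 6, 1 / 6, 1 / 3)), tolerance = 1e-12)
  expect_lt(max(abs(unclass(out)[1, ] - truth)), 1e-6)
})

test_that("IPF monotonically reduces the worst marginal discrepancy", {
  ref16 <- expand_16(or22_cells(0.5, 0.3, 6), or22_cells(0.4, 0.2, 3))
  fit <- metsburden:::ipf_fit_16(ref16, c(0.25, 0.6, 0.15, 0.55))
  expect_true(all(diff(fit$history) <= 1e-15))
  expect_lt(fit$discrepancy, 1e-8)
  expect_error(
    metsburden:::ipf_fit_16(ref16, c(0.25, 0.6, 0.15, 0.55), max_iter = 1,
                            tol = 1e-14),
    "no convergence")
})

test_that("raising one component's target raises the MetS share", {
  spec <- one_band_spec(30000, seed = 23,
                        marginals = setNames(c(0.4, 0.4, 0.3, 0.35, 0.3),
                                             mets_components()),
                        association = 0.2 + 0.8 * diag(5))
  cm <- estimate_conditional_matrix(simulate_microdata(spec))
  cm <- conditional_matrix(unclass(cm)["20-29:female", , drop = FALSE])
  base_targets <- tibble::tibble(
    age_band = "20-29", sex = "female",
    component = mets_other_components(), target = c(0.4, 0.3, 0.35, 0.3))
  hi_targets <- dplyr::mutate(base_targets, target = ifelse(
    component == "obesity", 0.6, target))
  k <- subset_k()
  mets_share <- function(tg) {
    p <- unclass(calibrate_to_marginals(cm, tg))["20-29:female", ]
    sum(p[k >= 2])
  }
  expect_gt(mets_share(hi_targets), mets_share(base_targets))
})

test_that("decomposition conserves persons and counts subsets by size", {
  # uniform matrix on 1,600 people -> binomial(4, 1/2) subset counts
  rgt <- decompose_population(
    tibble::tibble(age_band = "20-29", sex = "female", htn_count = 1600),
    uniform_matrix())
  expect_equal(unname(unlist(rgt[paste0("k", 0:4)])),
               c(100, 400, 600, 400, 100))
  expect_equal(rgt$mets_count, 1100)
  expect_equal(rgt$non_mets_count, 500)

  # all mass on the empty subset -> everyone in k = 0
  m0 <- matrix(0, 1, 16, dimnames = list("20-29:female", subset_labels()))
  m0[1, "0000"] <- 1
  rgt0 <- decompose_population(
    tibble::tibble(age_band = "20-29", sex = "female", htn_count = 1000),
    conditional_matrix(m0))
  expect_equal(rgt0$k0, 1000)
  expect_equal(rgt0$mets_count, 0)

  # conservation on random matrices
  set.seed(31)
  for (i in 1:10) {
    p <- matrix(rexp(32), 2, 16)
    p <- p / rowSums(p)
    dimnames(p) <- list(c("20-29:female", "20-29:male"), subset_labels())
    counts <- tibble::tibble(age_band = "20-29", sex = c("female", "male"),
                             htn_count = c(12345.6, 999))
    rgt_i <- decompose_population(counts, conditional_matrix(p))
    expect_equal(rowSums(as.matrix(rgt_i[paste0("k", 0:4)])),
                 counts$htn_count, tolerance = 1e-9)
  }

  expect_error(decompose_population(
    tibble::tibble(age_band = "50-59", sex = "male", htn_count = 10),
    uniform_matrix()), "50-59:male")
  expect_error(decompose_population(
    tibble::tibble(age_band = "20-29", sex = "female", htn_count = -1),
    uniform_matrix()), "negative")
})
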