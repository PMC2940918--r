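# Synthetic survey microdata: marginal recovery, dependence structure and
# the weighted joint tabulation.

flat_marginals <- function(p = 0.3) {
  setNames(rep(p, 5), mets_components())
}

test_that("a fixed seed yields a bit-identical record stream", {
  spec <- microdata_spec(2000, seed = 42, marginals = flat_marginals(),
                         weight_model = "lognormal")
  expect_identical(simulate_microdata(spec), simulate_microdata(spec))
  # and the caller's RNG state is untouched
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(simulate_microdata(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("weighted prevalences recover the spec marginals within 3 SE", {
  n <- 100000
  spec <- one_band_spec(n, seed = 11, marginals = flat_marginals(0.3),
                        association = diag(5))
  rec <- simulate_microdata(spec)
  se <- sqrt(0.3 * 0.7 / n)
  for (comp in mets_components()) {
    expect_lt(abs(mean(rec[[comp]]) - 0.3), 3 * se)
  }
  expect_true(all(rec$age >= 20))
  expect_true(all(rec$weight > 0))
})

test_that("identity association gives pairwise odds ratios near 1", {
  rec <- simulate_microdata(one_band_spec(
    100000, seed = 12, marginals = flat_marginals(0.35),
    association = diag(5)))
  comps <- mets_components()
  for (i in 1:4) {
    for (j in (i + 1):5) {
      # 4-SE band on the log odds ratio
      x <- rec[[comps[i]]]; y <- rec[[comps[j]]]
      se_log <- sqrt(sum(1 / table(x, y)))
      expect_lt(abs(log(emp_or(x, y))), 4 * se_log)
    }
  }
})

test_that("latent correlation reproduces the bivariate-normal orthant mass", {
  assoc <- diag(5)
  assoc[2, 3] <- assoc[3, 2] <- 0.5  # obesity x low_hdl
  m <- flat_marginals(0.3)
  m[c("obesity", "low_hdl")] <- 0.4
  n <- 100000
  rec <- simulate_microdata(one_band_spec(n, seed = 13, marginals = m,
                                          association = assoc))
  p_both <- mean(rec$obesity == 1 & rec$low_hdl == 1)
  truth <- orthant_prob(qnorm(0.6), qnorm(0.6), 0.5)
  expect_lt(abs(p_both - truth), 3 * sqrt(truth * (1 - truth) / n))
})

test_that("invalid generator specifications are refused before sampling", {
  bad <- diag(5); bad[1, 2] <- bad[2, 1] <- 0.99
  bad[1, 3] <- bad[3, 1] <- 0.99
  bad[2, 3] <- bad[3, 2] <- -0.99  # non-PSD triangle
  expect_error(microdata_spec(100, marginals = flat_marginals(),
                              association = bad), "positive semi-definite")
  expect_error(microdata_spec(100, marginals = flat_marginals(1.2)),
               "strictly in \\(0,1\\)")
  expect_error(
    microdata_spec(100, marginals = flat_marginals(),
                   association = matrix(0.2, 5, 5)),
    "unit diagonal")
})

test_that("empirical_joint tabulates weighted mass on the 32 cells", {
  rec <- tibble::tibble(
    age_band = "20-29", sex = "female", weight = c(1, 1, 1, 1),
    hypertension = 1L, obesity = 0L, low_hdl = 1L, high_tg = 0L,
    impaired_glucose = 1L
  )
  j <- empirical_joint(rec, "20-29", "female")
  expect_equal(sum(j), 1)
  expect_equal(unname(j["10101"]), 1)  # all mass on the single pattern

  # 10-record hand fixture: weighted fractions tallied by hand
  rec10 <- tibble::tibble(
    age_band = "30-39", sex = "male",
    weight = c(2, 2, 1, 1, 1, 1, 3, 3, 4, 2),
    hypertension = c(1, 1, 1, 0, 0, 1, 1, 0, 1, 1),
    obesity =      c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0),
    low_hdl =      c(0, 0, 1, 0, 0, 1, 0, 0, 1, 1),
    high_tg =      c(1, 1, 0, 0, 0, 1, 1, 0, 0, 1),
    impaired_glucose = c(0, 0, 0, 0, 1, 1, 0, 0, 1, 0)
  )
  j10 <- empirical_joint(rec10, "30-39", "male")
  # total weight 20; e.g. pattern 1-1-0-1-0 holds records 1 and 7 (w 2+3)
  expect_equal(unname(j10["11010"]), 5 / 20)
  expect_equal(unname(j10["11100"]), 1 / 20)  # record 3
  expect_equal(unname(j10["11101"]), 4 / 20)  # record 9
  expect_equal(unname(j10["00000"]), 3 / 20)  # record 8
  expect_equal(sum(j10), 1)

  # scale invariance: doubling every weight changes nothing
  rec10b <- dplyr::mutate(rec10, weight = weight * 2)
  expect_equal(empirical_joint(rec10b, "30-39", "male"), j10)

  expect_error(empirical_joint(rec10, "70-79", "male"), "70-79:male")
})

test_that("empirical_joint marginalises back to the generator prevalences", {
  n <- 50000
  spec <- one_band_spec(n, seed = 14, marginals = flat_marginals(0.3),
                        association = diag(5), weight_model = "lognormal")
  rec <- simulate_microdata(spec)
  j <- empirical_joint(rec, "20-29", "male")
  bits <- do.call(rbind, strsplit(names(j), ""))
  storage.mode(bits) <- "integer"
  marg <- as.vector(crossprod(j, bits))
  w <- rec[rec$sex == "male", ]
  for (i in seq_along(mets_components())) {
    expect_equal(marg[i],
                 sum(w$weight * w[[mets_components()[i]]]) / sum(w$weight))
  }
})
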