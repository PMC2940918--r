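# One-at-a-time sensitivity: locality of perturbations, linearity in unit
# costs, and the incident-only diabetes scenario.

demo_cm <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- estimate_conditional_matrix(
        simulate_microdata(default_reference_spec(20000, seed = 61)))
    }
    val
  }
})

test_that("each scenario changes exactly its own factor", {
  pack <- demo_pack()
  p1 <- apply_scenario(pack, scenario_scale_unit_cost("t2d", 1.2))
  expect_equal(p1$unit_costs$cost_eur[p1$unit_costs$item == "t2d_annual"],
               1.2 * pack$unit_costs$cost_eur[pack$unit_costs$item == "t2d_annual"])
  p1$unit_costs <- pack$unit_costs
  expect_identical(p1, pack)  # everything else bit-identical

  p2 <- apply_scenario(pack, scenario_scale_unit_cost("cvd", 0.8))
  sel <- pack$unit_costs$item %in% cv_event_outcomes()
  expect_equal(p2$unit_costs$cost_eur[sel], 0.8 * pack$unit_costs$cost_eur[sel])
  expect_equal(p2$unit_costs$cost_eur[!sel], pack$unit_costs$cost_eur[!sel])

  p3 <- apply_scenario(pack, scenario_scale_continuation(1.2))
  expect_equal(p3$treatment$classes$continuation,
               pmin(1, 1.2 * pack$treatment$classes$continuation))
  p3$treatment$classes$continuation <- pack$treatment$classes$continuation
  expect_identical(p3, pack)

  p4 <- apply_scenario(pack, scenario_proportion_treated(0.58))
  expect_equal(p4$treatment$proportion_treated, 0.58)

  p5 <- apply_scenario(pack, scenario_t2d_incident_only())
  expect_true(p5$options$t2d_incident_only)
  p5$options$t2d_incident_only <- FALSE
  expect_identical(p5, pack)
  # the baseline pack object is untouched throughout
  expect_identical(pack, demo_pack())
})

test_that("unit-cost scaling moves exactly one component, linearly", {
  pack <- demo_pack()
  base <- compute_burden(pack, demo_cm(), "base")$costs_split
  up <- compute_burden(apply_scenario(pack, scenario_scale_unit_cost("t2d", 1.2)),
                       demo_cm(), "base")$costs_split
  for (slice in c("mets", "non_mets", "all")) {
    b <- base[base$slice == slice, ]; u <- up[up$slice == slice, ]
    expect_equal(u$t2d, 1.2 * b$t2d, tolerance = 1e-12)
    expect_equal(u$drug, b$drug, tolerance = 1e-12)
    expect_equal(u$physician, b$physician, tolerance = 1e-12)
    expect_equal(u$cvd, b$cvd, tolerance = 1e-12)
    expect_equal(u$total, b$total + 0.2 * b$t2d, tolerance = 1e-9)
  }
})

test_that("breakdown-level scaling implements the same linearity identity", {
  b <- cost_breakdown(628, 1952, 5265, 16582)
  up <- scale_cost_component(b, "t2d", 1.2)
  dn <- scale_cost_component(b, "t2d", 0.8)
  expect_equal(up$total, b$total + 0.2 * b$t2d)
  expect_equal(dn$total, b$total - 0.2 * b$t2d)
  expect_equal((up$total + dn$total) / 2, b$total)  # symmetric unrounded
})

test_that("incident-only diabetes lowers the T2D component when incidence is below prevalence", {
  pack <- demo_pack()
  base <- compute_burden(pack, demo_cm(), "base")$costs_split
  inc <- compute_burden(apply_scenario(pack, scenario_t2d_incident_only()),
                        demo_cm(), "base")$costs_split
  expect_lt(inc$t2d[inc$slice == "all"], base$t2d[base$slice == "all"])
  expect_equal(inc$drug, base$drug)  # other components untouched
  expect_equal(inc$cvd, base$cvd)
})

test_that("run_univariate reports baseline plus one row pair per scenario", {
  pack <- demo_pack()
  empty <- run_univariate(pack, list(), demo_cm())
  base_snap <- compute_burden(pack, demo_cm(), "base")$costs_split
  expect_equal(nrow(empty), 2L)
  expect_equal(empty$total[empty$slice == "mets"],
               base_snap$total[base_snap$slice == "mets"])

  res <- run_univariate(pack, list(
    scenario_scale_unit_cost("t2d", 1.2),
    scenario_scale_unit_cost("drug", 0.8),
    scenario_scale_continuation(0.8),
    scenario_proportion_treated(0.58),
    scenario_t2d_incident_only()
  ), demo_cm())
  expect_equal(nrow(res), 12L)
  expect_equal(res$scenario[1:2], c("baseline", "baseline"))
  # determinism
  res2 <- run_univariate(pack, list(scenario_scale_unit_cost("t2d", 1.2)),
                         demo_cm())
  expect_identical(res2, run_univariate(
    pack, list(scenario_scale_unit_cost("t2d", 1.2)), demo_cm()))
  # tornado ordering puts the largest spread first after baseline
  ord <- tornado_order(res)
  expect_equal(ord[1], "baseline")
  base_mets <- res$total[res$scenario == "baseline" & res$slice == "mets"]
  spreads <- abs(res$total[res$slice == "mets"] - base_mets)
  expect_equal(ord[2],
               res$scenario[res$slice == "mets"][which.max(spreads)])
})

test_that("a discounting scenario reports discounted horizon totals", {
  pack <- demo_pack()
  res <- run_univariate(pack, list(scenario_discount(0.03)), demo_cm())
  horizon <- compute_burden(pack, demo_cm(), "horizon")$costs_split
  expect_equal(res$total[res$scenario != "baseline" & res$slice == "mets"],
               discount_cost(horizon$total[horizon$slice == "mets"], 0.03, 12))
})
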