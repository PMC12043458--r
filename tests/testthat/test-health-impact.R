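test_that("intake chain matches hand arithmetic", {
  expect_equal(additional_intake(1.0, 300, 0.31), 0.093)
  expect_equal(additional_intake(0, 300, 0.31), 0)
  expect_equal(additional_intake(2.5, 1000, 1.0), 2.5)
  expect_error(additional_intake(1, 300, 1.2), "recovery")

  expect_equal(intake_with_ofs(4.90, 0.06), 4.96)
  expect_equal(intake_with_ofs(6.00, 0.12), 6.12)
  expect_equal(intake_with_ofs(5, 0), 5)
  expect_equal(intake_with_ofs(0.05, -1), 0)   # floored at zero

  expect_equal(pct_rni(6.90, 6.90), 100)
  expect_equal(pct_rni(4.96, 6.90), 71.88, tolerance = 1e-4)
  expect_equal(pct_rni(0, 6.90), 0)
  expect_error(pct_rni(1, 0), "rni")
})

test_that("DALY burden formula and discounting follow the closed form", {
  expect_equal(dalys_lost(1e6, 0, 30), 0)
  expect_equal(dalys_lost(1e6, 0, 30,
                          data.frame(incidence = 0.01, duration = 1,
                                     disability_weight = 0.1)),
               1000)
  # discounted years of life lost: (1 - exp(-0.9)) / 0.03
  expect_equal(dalys_lost(1, 1, 30, discount_rate = 0.03),
               (1 - exp(-0.9)) / 0.03)
  expect_equal((1 - exp(-0.9)) / 0.03, 19.781, tolerance = 1e-4)
  expect_error(dalys_lost(1e6, -0.1, 30), ">= 0")
})

test_that("gap closure is a capped linear deficit fraction", {
  expect_equal(gap_closure(4.90, 0.06, 6.90), 0.03)
  expect_equal(gap_closure(4.90, 0, 6.90), 0)
  expect_equal(gap_closure(4.90, 2.00, 6.90), 1)    # full closure
  expect_equal(gap_closure(4.90, 5.00, 6.90), 1)    # capped
  expect_equal(gap_closure(7.50, 0.5, 6.90), 0)     # already above RNI
  expect_error(gap_closure(4.9, 0.1, 0), "rni")
})

test_that("DALYs saved are linear in coverage and bounded by the burden", {
  expect_equal(dalys_saved(128500, 0.6, 0.03) / dalys_saved(128500, 0.2, 0.03),
               3)
  expect_equal(dalys_saved(1000, 0, 0.5), 0)
  expect_lte(dalys_saved(1000, 1, 1), 1000)
  expect_error(dalys_saved(1000, 1.2, 0.5), "\\[0, 1\\]")

  expect_equal(pct_burden_reduction(500, 1000), 50)
  expect_equal(pct_burden_reduction(1000, 1000), 100)
  expect_equal(pct_burden_reduction(0, 1000), 0)
  expect_error(pct_burden_reduction(1, 0), "> 0")
})

test_that("economic benefit is the PCNI valuation minus fertilizer cost", {
  expect_equal(economic_benefit(0, 10000, 0, 0), 0)
  expect_equal(economic_benefit(1000, 10000, 900, 1e6), 1e7 - 9e8)
  expect_error(economic_benefit(-1, 1), ">= 0")
})

test_that("the full assessment composes the operations and keeps its invariants", {
  params <- load_health_params()
  res <- run_health_assessment(params)

  # zero-delta fixed point: identical contents reproduce the status quo
  flat <- params
  flat$contents$content <- 30
  res0 <- run_health_assessment(flat)
  expect_true(all(res0$groups$dalys_saved == 0))
  expect_true(all(res0$groups$intake_with_ofs == res0$groups$baseline_intake))
  expect_true(all(res0$burden$pct_burden_reduction == 0))

  # linearity in coverage below the cap
  g <- res$groups
  pess <- g[g$scenario == "pessimistic", ]
  opt <- g[g$scenario == "optimistic", ]
  expect_equal(opt$dalys_saved, 3 * pess$dalys_saved)

  # conservation: saved never exceeds burden, reduction never exceeds 100
  expect_true(all(g$dalys_saved <= g$baseline_burden + 1e-9))
  expect_true(all(res$burden$pct_burden_reduction >= 0 &
                    res$burden$pct_burden_reduction <= 100))

  # monotonicity in the content increase on randomized parameter sweeps
  set.seed(21)
  for (i in 1:20) {
    p2 <- params
    bump <- runif(1, 0.1, 5)
    p2$contents$content <- p2$contents$content +
      ifelse(p2$contents$treatment == "OF15", bump, 0)
    res2 <- run_health_assessment(p2)
    base15 <- res$groups[res$groups$treatment == "OF15", ]
    bump15 <- res2$groups[res2$groups$treatment == "OF15", ]
    expect_true(all(bump15$dalys_saved >= base15$dalys_saved - 1e-9))
  }

  # broom-style accessors
  expect_identical(tidy(res), res$groups)
  expect_identical(glance(res), res$economics)

  # errors name the problem
  noref <- params
  noref$contents <- dplyr::filter(params$contents, treatment != "OPT")
  expect_error(run_health_assessment(noref), "reference treatment")
})

test_that("parameter files load with schema checks", {
  params <- load_health_params()
  expect_equal(params$reference_treatment, "OPT")
  expect_equal(unname(params$recovery["Zn"]), 0.310)
  expect_equal(unname(params$recovery["Fe"]), 0.217)
  expect_equal(sort(params$scenarios$coverage), c(0.20, 0.60))
  expect_equal(nrow(params$groups), 7)
  expect_error(load_health_params("/nonexistent.yaml"), "not found")

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("reference_treatment: OPT",
               "recovery: {Zn: 0.31}",
               "contents: {Zn: {OPT: 24, OF15: 26}}",
               "groups:",
               "  - {nutrient: Zn, group: A, wheat_intake: 100}",
               "scenarios: [{name: s, coverage: 0.2}]",
               "economics: {pcni: 1, fertilizer_cost_per_ha: 1, area_ha: 1}"),
             f)
  expect_error(load_health_params(f), "baseline_intake")
})
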