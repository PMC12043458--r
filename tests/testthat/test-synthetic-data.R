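test_that("generator produces the full design, deterministically", {
  cfg <- generator_config()
  plots <- generate_trial(cfg, seed = 1)
  expect_equal(nrow(plots), 5 * 5 * 3)
  expect_equal(sort(unique(as.character(plots$treatment))),
               sort(ofs_treatments()))
  expect_equal(dplyr::n_distinct(plots$site), 5)
  expect_silent(validate_plot_table(plots))

  expect_identical(generate_trial(cfg, seed = 7), generate_trial(cfg, seed = 7))
  expect_false(identical(generate_trial(cfg, seed = 7),
                         generate_trial(cfg, seed = 8)))

  # per-site streams: adding a site to a config leaves earlier sites
  # untouched (the variance split is frozen at construction)
  cfg6 <- cfg
  cfg6$n_sites <- 6L
  cfg6$site_yield_means <- c(cfg$site_yield_means, Extra = 9.0)
  p5 <- generate_trial(cfg, seed = 3)
  p6 <- generate_trial(cfg6, seed = 3)
  expect_equal(dplyr::filter(p6, site != "Extra"), p5)
})

test_that("default configuration carries the study conditions", {
  cfg <- generator_config()
  expect_equal(unname(cfg$grain_means["grain_fe"]), 37.13)
  expect_equal(unname(cfg$grain_means["grain_zn"]), 24.61)
  expect_equal(unname(cfg$grain_cvs["grain_zn"]), 10.16)
  expect_equal(range(cfg$site_yield_means), c(7.07, 9.85))
  expect_equal(mean(cfg$site_yield_means), 9.06, tolerance = 1e-9)
  # organic substitution vs control calibration
  expect_equal(unname(cfg$treatment_content_effects$grain_fe["OF15"]),
               1.2469)
  expect_equal(unname(cfg$treatment_content_effects$grain_zn["OF15"]),
               1.1919)
  expect_equal(unname(cfg$treatment_yield_effects["OF15"]), 1.1975)
})

test_that("degenerate noise collapses replicates; concentrations stay positive", {
  cfg <- generator_config(
    yield_cv = 0,
    grain_cvs = c(grain_fe = 0, grain_mn = 0, grain_cu = 0, grain_zn = 0,
                  phytic_acid = 0),
    treatment_yield_effects = c(CK = 1, FP = 1, OPT = 1, OF15 = 1, OF30 = 1),
    treatment_content_effects = lapply(
      generator_config()$treatment_content_effects,
      function(x) setNames(rep(1, 5), names(x)))
  )
  plots <- generate_trial(cfg, seed = 1)
  per_site <- split(plots$yield, plots$site)
  for (v in per_site) expect_equal(diff(range(v)), 0)
  expect_equal(diff(range(plots$grain_fe)), 0)

  # extreme CVs can never push a concentration negative
  wild <- generator_config(grain_cvs = c(grain_fe = 80, grain_mn = 80,
                                         grain_cu = 80, grain_zn = 80,
                                         phytic_acid = 80))
  for (s in 1:5) {
    p <- generate_trial(wild, seed = s)
    expect_true(all(p$grain_fe > 0 & p$grain_zn > 0 & p$phytic_acid > 0))
    pt <- generate_trial(
      generator_config(grain_cvs = wild$grain_cvs,
                       noise_model = "truncnorm"), seed = s)
    expect_true(all(pt$grain_fe > 0 & pt$yield > 0))
  }
})

test_that("parameters are recovered at large replicate counts", {
  cfg <- generator_config(n_reps = 200)
  plots <- generate_trial(cfg, seed = 11)
  est <- recover_parameters(plots)
  n <- nrow(plots)

  for (a in c("grain_fe", "grain_mn", "grain_cu", "grain_zn")) {
    target_mean <- cfg$grain_means[[a]]
    target_cv <- cfg$grain_cvs[[a]]
    row <- est$analytes[est$analytes$analyte == a, ]
    se <- row$sd / sqrt(n)
    expect_lt(abs(row$mean - target_mean), 3 * se)
    expect_lt(abs(row$cv_percent - target_cv) / target_cv, 0.15)
  }
  yrow <- est$analytes[est$analytes$analyte == "yield", ]
  expect_lt(abs(yrow$mean - 9.06), 3 * yrow$sd / sqrt(n))
  expect_lt(abs(yrow$cv_percent - 15.08) / 15.08, 0.15)

  # treatment effects (ratio to control) recovered
  fe15 <- est$treatment_effects |>
    dplyr::filter(analyte == "grain_fe", treatment == "OF15")
  expect_equal(fe15$effect, 1.2469, tolerance = 0.05)

  # unit effects recovered as ~1
  flat <- generator_config(
    n_reps = 200,
    treatment_yield_effects = c(CK = 1, FP = 1, OPT = 1, OF15 = 1, OF30 = 1),
    treatment_content_effects = lapply(
      generator_config()$treatment_content_effects,
      function(x) setNames(rep(1, 5), names(x))))
  est2 <- recover_parameters(generate_trial(flat, seed = 5))
  expect_true(all(abs(est2$treatment_effects$effect - 1) < 0.06))

  expect_error(recover_parameters(make_plots()[0, ]), "empty")
})

test_that("the dilution correlation is recovered", {
  cfg <- generator_config(
    n_sites = 1, site_yield_means = c(Only = 9.06), n_reps = 2000,
    treatment_yield_effects = c(CK = 1, FP = 1, OPT = 1, OF15 = 1, OF30 = 1),
    treatment_content_effects = lapply(
      generator_config()$treatment_content_effects,
      function(x) setNames(rep(1, 5), names(x))),
    yield_content_correlation = -0.5
  )
  est <- recover_parameters(generate_trial(cfg, seed = 2))
  r_fe <- est$yield_correlations$r[est$yield_correlations$analyte == "grain_fe"]
  expect_lt(abs(r_fe - (-0.5)), 0.1)
})
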