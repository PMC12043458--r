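test_that("describe matches hand calculations and is location-scale equivariant", {
  d <- describe(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)
  expect_equal(d$cv_percent, 50)
  expect_equal(d$median, 2)

  expect_equal(describe(rep(5, 4))$sd, 0)
  expect_equal(describe(rep(5, 4))$cv_percent, 0)
  expect_error(describe(1), "at least 2")

  set.seed(9)
  x <- rlnorm(50, 2, 0.3)
  shift <- describe(x + 3)
  scaled <- describe(2.5 * x)
  base <- describe(x)
  expect_equal(shift$mean, base$mean + 3)
  expect_equal(shift$median, base$median + 3)
  expect_equal(shift$sd, base$sd)
  expect_equal(scaled$mean, 2.5 * base$mean)
  expect_equal(scaled$sd, 2.5 * base$sd)
  expect_equal(scaled$cv_percent, base$cv_percent)
})

test_that("one-way ANOVA matches hand computation, aov(), and edge contracts", {
  d <- data.frame(y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                  g = rep(c("a", "b", "c"), each = 3))
  res <- one_way_anova(d, y, g)
  expect_equal(res$f_statistic, 3)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
  expect_equal(res$ss_between + res$ss_within, res$ss_total)

  # identical groups
  same <- data.frame(y = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  r0 <- one_way_anova(same, y, g)
  expect_equal(r0$f_statistic, 0)
  expect_equal(r0$p_value, 1)

  # zero within-variance, unequal means
  degen <- data.frame(y = rep(c(1, 2), each = 3), g = rep(c("a", "b"), each = 3))
  rd <- one_way_anova(degen, y, g)
  expect_equal(rd$f_statistic, Inf)
  expect_equal(rd$p_value, 0)

  expect_error(one_way_anova(data.frame(y = 1:4, g = c("a", "a", "a", "b")),
                             y, g), "at least 2 observations")

  # oracle: base aov on random instances
  set.seed(31)
  for (i in 1:10) {
    n <- sample(3:8, 4, replace = TRUE)
    dd <- data.frame(
      y = rnorm(sum(n), mean = rep(rnorm(4, sd = 2), times = n)),
      g = rep(letters[1:4], times = n))
    mine <- one_way_anova(dd, y, g)
    ref <- summary(aov(y ~ g, data = dd))[[1]]
    expect_equal(mine$f_statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(mine$ms_within, ref$`Mean Sq`[2], tolerance = 1e-10)
  }

  td <- tidy(res)
  expect_equal(td$df, c(2, 6))
  expect_equal(glance(res)$statistic, 3)
})

test_that("LSD letters encode the pairwise decision matrix faithfully", {
  # all groups identical -> single letter a
  same <- data.frame(y = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  expect_equal(fisher_lsd(same, y, g)$summary$letters, c("a", "a", "a"))

  # well-separated groups -> a, b, c by descending mean
  far <- data.frame(y = c(100, 101, 102, 50, 51, 52, 1, 2, 3) + 0.0,
                    g = rep(c("hi", "mid", "lo"), each = 3))
  s <- fisher_lsd(far, y, g)$summary
  expect_equal(s$group, c("hi", "mid", "lo"))
  expect_equal(s$letters, c("a", "b", "c"))

  # protected variant suppresses letters when the ANOVA is not significant
  set.seed(5)
  nul <- data.frame(y = rnorm(25), g = rep(letters[1:5], each = 5))
  prot <- fisher_lsd(nul, y, g, protected = TRUE)
  if (prot$anova$p_value >= 0.05) {
    expect_true(all(prot$summary$letters == "a"))
  }

  # oracle equivalence on random instances: two groups share a letter iff
  # the direct LSD test does not separate them
  set.seed(77)
  for (i in 1:40) {
    k <- sample(3:6, 1)
    n <- sample(3:6, k, replace = TRUE)
    dd <- data.frame(
      y = rnorm(sum(n), mean = rep(rnorm(k, sd = 1.2), times = n)),
      g = rep(paste0("g", seq_len(k)), times = n))
    res <- fisher_lsd(dd, y, g, alpha = 0.05)
    mat <- oracle_lsd_matrix(dd$y, dd$g, 0.05)
    s <- res$summary
    for (a in seq_len(k - 1)) {
      for (b in seq((a + 1), k)) {
        expect_equal(!shares_letter(s$letters[a], s$letters[b]),
                     unname(mat[s$group[a], s$group[b]]))
      }
    }
  }
})

test_that("pearson matches cor.test and its boundary contracts", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, -2 * x + 5)$r, -1)
  expect_equal(pearson(x, x)$p_value, 0)

  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(20); b <- 0.4 * a + rnorm(20)
    mine <- pearson(a, b)
    ref <- cor.test(a, b)
    expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(pearson(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson(1:5, 1:4), "equal length")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("treatment summaries pool sites and attach letters per variable", {
  plots <- generate_trial(generator_config(), seed = 1)
  ts <- treatment_summaries(plots, variables = c("yield", "grain_zn"))
  expect_equal(nrow(ts), 10)
  expect_equal(as.vector(table(ts$variable)), c(5L, 5L))
  expect_true(all(ts$n == 15))
  expect_true(all(nchar(ts$letters) >= 1))

  # single-treatment input: summaries still produced, letters not applicable
  one <- dplyr::filter(plots, treatment == "CK")
  ts1 <- treatment_summaries(one, variables = "yield")
  expect_equal(nrow(ts1), 1)
  expect_true(is.na(ts1$letters))
})
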