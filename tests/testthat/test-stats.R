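printed_hs4 <- function() exceedance_table_from_counts(413, 3, 419, 0)

test_that("exceedance counts match a brute-force threshold scan", {
  set.seed(21)
  n <- 1000
  stresses <- runif(n, 100, 260)
  res <- data.frame(arm = rep(c("Generic", "Personalised"), each = n / 2),
                    patient = rep(sprintf("P%02d", 1:20), 50),
                    stress = stresses, solved = rep(c(TRUE, FALSE),
                                                    c(900, 100)))
  tab <- exceedance_table(res, fatigue_limit())
  keep <- res[res$solved, ]
  for (arm in c("Generic", "Personalised")) {
    expect_equal(tab$cells[[arm]][["N1"]],
                 sum(keep$stress[keep$arm == arm] >= 180))
    expect_equal(tab$cells[[arm]][["N2"]],
                 sum(keep$stress[keep$arm == arm] < 180))
  }
})

test_that("a stress exactly at the limit counts as exceedance", {
  res <- data.frame(arm = "Generic", patient = "P1",
                    stress = c(180, 179.999), solved = TRUE)
  tab <- exceedance_table(res)
  expect_equal(unname(tab$cells$Generic), c(1, 1))
  expect_error(exceedance_table(res[res$stress > 999, ]), "empty-table")
})

test_that("printed exceedance percentages are reproduced to 1 d.p.", {
  expect_equal(
    exceedance_percentages(
      exceedance_table_from_counts(96, 295, 73, 337))$pct_above,
    c(75.4, 82.2))
  expect_equal(
    exceedance_percentages(
      exceedance_table_from_counts(364, 46, 341, 51))$pct_above[1], 11.2)
  expect_equal(exceedance_percentages(printed_hs4())$pct_above, c(0.7, 0))
})

test_that("the penalised HS4 odds ratio reproduces the printed interval", {
  or <- odds_ratio(printed_hs4(), "haldane_penalised")
  expect_equal(round(or$OR, 2), 0.14)
  expect_equal(round(or$ci_low, 2), 0.01)
  expect_equal(round(or$ci_high, 2), 2.73)
  expect_equal(round(or$p, 2), 0.20)
  # auto-selects the penalised route on the zero cell
  expect_equal(odds_ratio(printed_hs4(), "auto")$method,
               "haldane_penalised")
})

test_that("crude odds ratios follow the cross-product rule", {
  tab <- exceedance_table_from_counts(96, 295, 73, 337)
  expect_equal(round(odds_ratio(tab, "crude")$OR, 2), 1.50)
  expect_equal(odds_ratio(tab, "crude")$OR, (337 * 96) / (73 * 295))
  # symmetric table: OR exactly 1
  sym <- exceedance_table_from_counts(40, 10, 80, 20)
  expect_equal(odds_ratio(sym, "crude")$OR, 1)
  # swapping arms inverts the OR
  sw <- exceedance_table_from_counts(73, 337, 96, 295)
  expect_equal(odds_ratio(sw, "crude")$OR,
               1 / odds_ratio(tab, "crude")$OR, tolerance = 1e-12)
  expect_error(odds_ratio(exceedance_table_from_counts(0, 0, 10, 5)),
               "undefined-OR")
})

test_that("cluster-bootstrap intervals are seed-deterministic", {
  set.seed(31)
  res <- data.frame(arm = rep(c("Generic", "Personalised"), each = 150),
                    patient = rep(sprintf("P%02d", 1:10), 30),
                    stress = c(rnorm(150, 175, 15), rnorm(150, 165, 15)),
                    solved = TRUE)
  tab <- exceedance_table(res)
  b1 <- odds_ratio(tab, "cluster_bootstrap", B = 300, seed = 7)
  b2 <- odds_ratio(tab, "cluster_bootstrap", B = 300, seed = 7)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, b1$OR)
  expect_gte(b1$ci_high, b1$OR)
  expect_error(odds_ratio(tab, "cluster_bootstrap", B = 10),
               "requires a seed")
  expect_error(odds_ratio(printed_hs4(), "cluster_bootstrap", seed = 1),
               "per-patient")
})

test_that("paired deltas use each patient as their own control", {
  g <- data.frame(patient = rep(sprintf("P%d", 1:6), each = 5),
                  step = rep(1:5, 6), value = 100, solved = TRUE)
  p <- g
  expect_equal(paired_delta(g, p, B = 200, seed = 1)$mean, 0)
  p2 <- g; p2$value <- g$value - 5
  d <- paired_delta(g, p2, B = 200, seed = 1)
  expect_equal(d$mean, 5)
  expect_equal(d$n, 30)
  # unsolved rows drop out of the pairing
  p3 <- p2; p3$solved[1:5] <- FALSE
  expect_equal(paired_delta(g, p3, B = 200, seed = 1)$n, 25)
  expect_error(paired_delta(g, data.frame(patient = "X", step = 1,
                                          value = 1, solved = FALSE)),
               "pairing error")
})

test_that("the cluster bootstrap approximates the t-interval for iid data", {
  set.seed(13)
  n <- 60
  g <- data.frame(patient = sprintf("P%02d", 1:n), step = 1,
                  value = rnorm(n, 10, 2), solved = TRUE)
  p <- data.frame(patient = g$patient, step = 1,
                  value = rnorm(n, 8, 2), solved = TRUE)
  d <- paired_delta(g, p, B = 4000, seed = 5)
  delta <- g$value - p$value
  tt <- t.test(delta)
  expect_equal(d$ci_low, tt$conf.int[1], tolerance = 0.15)
  expect_equal(d$ci_high, tt$conf.int[2], tolerance = 0.15)
})

test_that("delta-to-maximum ratios match the printed percentages", {
  expect_equal(delta_fraction(17.1, 545), 3.1)
  expect_equal(delta_fraction(11.1, 165), 6.7)
  expect_equal(delta_fraction(0, 100), 0)
  expect_error(delta_fraction(5, 0), "input error")
})

test_that("screw-configuration ANOVA applies the Bonferroni threshold", {
  df0 <- data.frame(step = 1, config = rep(c("SC1", "SC2", "SC3"), each = 3),
                    value = rep(c(1, 2, 3), 3))
  a0 <- screw_config_anova(df0, n_tests = 15)
  expect_equal(a0$F, 0)
  expect_false(a0$significant)
  set.seed(2)
  df1 <- data.frame(step = 1, config = rep(c("SC1", "SC2", "SC3"), each = 50),
                    value = c(rnorm(50, 0), rnorm(50, 5), rnorm(50, 10)))
  a1 <- screw_config_anova(df1, n_tests = 15)
  expect_true(a1$significant)
  expect_lt(a1$p, 0.05 / 15)
  # threshold arithmetic: p = 0.004 clears 0.05 but not 0.05/15
  thr <- attr(a1, "alpha_corrected")
  expect_equal(thr, 0.05 / 15)
  expect_true(0.004 < 0.05 && 0.004 > thr)
  expect_error(screw_config_anova(data.frame(step = 1, config = "SC1",
                                             value = 1:4)), "2 configs")
})

test_that("the sample-size formula matches its closed form", {
  ps <- power_sample_size(mean = 1, sd = 1, relative_difference = 1)
  expect_equal(ps$n_per_arm, 16)   # ceil(2 * (1.9600 + 0.8416)^2)
  expect_equal(ps$n_total_paired, 16)
  # halving the standardised difference quadruples n (monotonicity in sd)
  ps2 <- power_sample_size(mean = 1, sd = 2, relative_difference = 1)
  expect_gt(ps2$n_per_arm, ps$n_per_arm)
  # study stiffness inputs: reported alongside, not asserted against, the
  # published nomogram figure
  ps3 <- power_sample_size(1950, 577, 0.2)
  expect_true(is.finite(ps3$n_per_arm) && ps3$n_per_arm > 0)
  expect_equal(ps3$d, 0.2 * 1950 / 577)
  expect_error(power_sample_size(1950, 577, 0), "infinite-n")
})
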