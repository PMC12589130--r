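# Gap arithmetic, the OLS bias-correction identities, and the association
# analyses (group ANOVA, medication contrasts, dosage correlation).

test_that("raw gap arithmetic and missing handling", {
  tab <- data.frame(subject_id = c("a", "b", "c", "d"),
                    bmi_measured = c(25, 25, 25, NA))
  pred <- setNames(c(25, 26, 20, 22), tab$subject_id)
  expect_message(gp <- compute_gap(pred, tab), "dropping 1")
  expect_equal(gp$gap_raw, c(0, 1, -5))
  expect_equal(gp$bmi_predicted - gp$bmi_measured, gp$gap_raw)
})

test_that("bias correction: hand 4-point OLS and the exact identities", {
  gp <- structure(data.frame(subject_id = letters[1:4],
                             bmi_measured = c(20, 24, 28, 32),
                             bmi_predicted = c(22, 25, 27, 30)),
                  class = c("bmigap_result", "data.frame"))
  gp$gap_raw <- gp$bmi_predicted - gp$bmi_measured    # 2, 1, -1, -2
  gp$gap_corrected <- NA_real_
  corr <- fit_bias_correction(gp)
  expect_equal(corr$slope, -0.35)                     # hand OLS
  ref <- resid(lm(gap_raw ~ bmi_measured, data = gp)) # independent oracle
  gp <- apply_bias_correction(gp, corr)
  expect_equal(gp$gap_corrected, unname(ref), tolerance = 1e-10)
  expect_lt(abs(mean(gp$gap_corrected)), 1e-8)
  expect_lt(abs(cor(gp$gap_corrected, gp$bmi_measured)), 1e-8)
  # gaps exactly affine in BMI vanish after correction
  gp2 <- gp
  gp2$gap_raw <- 3 - 0.2 * gp2$bmi_measured
  gp2 <- apply_bias_correction(gp2, fit_bias_correction(gp2))
  expect_equal(gp2$gap_corrected, rep(0, 4), tolerance = 1e-10)
  gp3 <- gp; gp3$bmi_measured <- rep(25, 4)
  expect_error(fit_bias_correction(gp3), "zero BMI variance")
})

test_that("correction fitted on discovery transfers out-of-sample on the phantom", {
  gp <- accept_gaps()
  corr <- attr(gp, "correction")
  disc <- gp[gp$subject_id %in% corr$fit_ids, ]
  expect_lt(abs(mean(disc$gap_corrected)), 1e-8)
  expect_lt(abs(cor(disc$gap_corrected, disc$bmi_measured)), 1e-8)
  # raw gaps show the BMI-dependent tilt the correction removes
  expect_lt(cor(disc$gap_raw, disc$bmi_measured), -0.1)
})

test_that("group tests: degenerate F, hand t-test, Welch default", {
  g <- c(1, 2, 3, 1, 2, 3)
  lab <- rep(c("A", "B"), each = 3)
  res <- group_tests(g, lab)
  expect_equal(res$anova$F, 0)
  expect_equal(res$anova$p, 1)
  res2 <- group_tests(c(1, 2, 3, 4, 5, 6), lab, reference = "A")
  expect_equal(res2$pairwise$t, -3.674, tolerance = 1e-3)
  # closed form: two-sided p at t = -sqrt(27/2), d.f. 4 (Welch = Student here)
  expect_equal(res2$pairwise$p, 2 * pt(-sqrt(27 / 2), 4), tolerance = 1e-10)
  # a singleton group is excluded with a warning, the rest still tested
  expect_warning(res3 <- group_tests(c(1, 2, 3, 4, 5, 6, 9),
                                     c(rep("A", 3), rep("B", 3), "C")),
                 "n < 2")
  expect_setequal(names(res3$group_means), c("A", "B"))
})

test_that("medication contrasts echo stratum percentages and run the t-test", {
  set.seed(6)
  n <- 170
  tab <- data.frame(subject_id = sprintf("c%03d", 1:n), group = "CHR",
                    weightgain_med = c(rep("yes", 81),
                                       rep("neutral_or_none", 28),
                                       rep("unknown", n - 81 - 28)),
                    antipsychotic_naive = rbinom(n, 1, 0.5),
                    antidepressant_naive = rbinom(n, 1, 0.5))
  gaps <- setNames(rnorm(n), tab$subject_id)
  out <- medication_contrasts(gaps, tab, groups = "CHR")
  expect_equal(out$CHR$counts$yes$n, 81)
  expect_equal(out$CHR$counts$yes$pct, 47.65)         # 81 / 170
  expect_equal(out$CHR$counts$neutral_or_none$pct, round(100 * 28 / 170, 2))
  expect_true(is.finite(out$CHR$t_weightgain$t))
  # all one stratum: contrast skipped with a log entry
  tab2 <- tab; tab2$weightgain_med <- "yes"
  expect_message(out2 <- medication_contrasts(gaps, tab2, groups = "CHR"),
                 "skipped")
  expect_null(out2$CHR$t_weightgain)
})

test_that("dosage correlation: exact cases and null behaviour", {
  tab <- data.frame(subject_id = c("a", "b", "c"), group = "SCZ",
                    cpz_equiv = c(2, 4, 6))
  gaps <- setNames(c(1, 2, 3), tab$subject_id)
  out <- dosage_correlation(gaps, tab)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(out$n, 3)
  hits <- vapply(1:20, function(s) {
    g2 <- setNames(with_seed(s, rnorm(146)), sprintf("s%03d", 1:146))
    t2 <- data.frame(subject_id = names(g2), group = "SCZ",
                     cpz_equiv = with_seed(1000 + s, rlnorm(146, log(300), 0.6)))
    abs(dosage_correlation(g2, t2)$r) < 0.2
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  expect_error(dosage_correlation(gaps[1:2], tab[1:2, ]), ">= 3")
  tabc <- tab; tabc$cpz_equiv <- 5
  expect_warning(outc <- dosage_correlation(gaps, tabc), "constant")
  expect_true(is.na(outc$r))
})
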