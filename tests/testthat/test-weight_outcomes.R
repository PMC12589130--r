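# Weight-change arithmetic, stratified correlations with per-panel FDR, the
# weight-gain classifier, and the paired model comparison.

test_that("weight-change arithmetic and gain flags", {
  tab <- data.frame(subject_id = c("a", "b", "c", "d"),
                    weight_t0 = c(78, 70, 70, 80),
                    weight_t1 = c(80, NA, 70, 81),
                    weight_t2 = c(NA, 75, 70, 90))
  wct <- compute_weight_change(tab)
  expect_equal(wct$dw1[1], 2)
  expect_equal(wct$pct2[2], 100 * 5 / 70)            # 7.142...%
  expect_true(wct$gain3_t2[2] && wct$gain5_t2[2] && wct$gain7_t2[2])
  expect_false(any(wct$gain3_t2[3], wct$gain5_t2[3], wct$gain7_t2[3]))
  expect_true(is.na(wct$gain3_t1[2]))                # missing stays missing
  # flags always consistent with percents
  expect_equal(wct$gain5_t2, wct$pct2 >= 5)
  bad <- tab; bad$weight_t0[1] <- 0
  expect_message(wct2 <- compute_weight_change(bad), "non-positive")
  expect_equal(nrow(wct2), 3)
})

test_that("stratified correlations: exact coupling, n guard, per-panel FDR", {
  set.seed(21)
  n <- 120
  tab <- data.frame(subject_id = sprintf("w%03d", 1:n), group = "ROD",
                    age = runif(n, 16, 39), sex = sample(c("F", "M"), n, TRUE),
                    weight_t0 = rep(70, n))
  gap <- rnorm(n)
  tab$weight_t1 <- tab$weight_t0 + gap                # dW1 == gap exactly
  tab$weight_t2 <- NA_real_
  wct <- compute_weight_change(tab)
  gaps <- setNames(gap, tab$subject_id)
  rep_ <- stratified_correlations(gaps, wct, tab, groups = "ROD",
                                  horizons = 1, thresholds = NA)
  all_cell <- rep_[rep_$age_stratum == "all", ]
  expect_equal(all_cell$r, 1, tolerance = 1e-10)
  expect_true(all(rep_$p_fdr >= rep_$p - 1e-15, na.rm = TRUE))
  expect_true(all(is.na(rep_$r[rep_$n < 3])))
  # sex split keeps cells aligned
  rs <- stratified_correlations(gaps, wct, tab, groups = "ROD", horizons = 1,
                                thresholds = NA, by_sex = TRUE)
  expect_true(all(c("F", "M") %in% rs$sex))
})

test_that("null coupling leaves few FDR-significant cells on average", {
  sig <- vapply(1:8, function(s) {
    spec <- phantom_spec(grid_shape = c(8L, 8L, 8L), support_size = 12L,
                         n_per_group = c(HC = 150L, CHR = 80L, ROD = 80L),
                         dw_coupling = 0, seed = 400 + s)
    co <- generate_cohort(spec)
    wct <- compute_weight_change(co$table)
    gaps <- setNames(co$truth$gap_true, co$table$subject_id)
    rep_ <- stratified_correlations(gaps, wct, co$table)
    mean(rep_$p_fdr <= 0.05, na.rm = TRUE)
  }, 1.0)
  expect_lte(mean(sig), 0.05)
})

wg_table <- function(n = 160, coupling = TRUE, seed = 31) {
  with_seed(seed, {
    tab <- data.frame(subject_id = sprintf("g%03d", 1:n),
                      group = sample(c("CHR", "ROD"), n, TRUE),
                      age = runif(n, 16, 40),
                      sex = sample(c("F", "M"), n, TRUE),
                      weight_t0 = rep(70, n),
                      exercise = rbinom(n, 1, 0.5),
                      somatic_history = rbinom(n, 1, 0.3),
                      tobacco = rbinom(n, 1, 0.3))
    gap <- rnorm(n)
    lift <- if (coupling) gap else rnorm(n)
    tab$weight_t2 <- 70 + ifelse(lift + rnorm(n, 0, 0.8) > 0.3, 6, 0)
    tab$weight_t1 <- NA_real_
    list(tab = tab, gaps = setNames(gap, tab$subject_id))
  })
}

test_that("weight-gain classifier runs, ablates, and reports consistent metrics", {
  w <- wg_table()
  wct <- compute_weight_change(w$tab)
  cls <- weight_gain_classifier(w$gaps, wct, w$tab, threshold = 7, horizon = 2,
                                outer_k = 5, outer_p = 1, inner_k = 3,
                                inner_p = 1, C_grid = 1, seed = 5)
  expect_length(cls$fold_bac, 5L)
  expect_equal(cls$bac, balanced_accuracy(cls$sensitivity, cls$specificity))
  expect_true("bmigap" %in% cls$features)
  abl <- weight_gain_classifier(w$gaps, wct, w$tab, threshold = 7, horizon = 2,
                                with_bmigap = FALSE, outer_k = 5, outer_p = 1,
                                inner_k = 3, inner_p = 1, C_grid = 1, seed = 5)
  expect_false("bmigap" %in% abl$features)
  expect_gt(cls$bac, abl$bac)                        # planted rule uses the gap
  # single-class labels rejected
  tab1 <- w$tab; tab1$weight_t2 <- 70
  expect_error(weight_gain_classifier(w$gaps, compute_weight_change(tab1),
                                      tab1), "single-class")
})

test_that("paired model comparison: identity, d.f., and degenerate guards", {
  x <- c(60, 62, 58, 61, 65)
  out <- compare_models(x, x)
  expect_equal(out$t, 0); expect_equal(out$p, 1)
  set.seed(9)
  a <- rnorm(25, 60, 3); b <- a - rnorm(25, 2, 1)
  out2 <- compare_models(a, b)
  expect_equal(out2$df, 24L)                          # 25 folds
  expect_equal(out2$t, unname(t.test(a, b, paired = TRUE)$statistic))
  expect_warning(out3 <- compare_models(c(1, 2, 3), c(0, 1, 2)), "constant")
  expect_true(out3$degenerate && is.na(out3$t))
  expect_error(compare_models(1:3, 1:4), "length")
})
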