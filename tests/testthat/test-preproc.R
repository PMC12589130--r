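# Preprocessing chain oracles: smoothing kernel, per-feature age
# residualization, site offsets, PCA energy rule, min-max scaling, and the
# CV fold bookkeeping.

test_that("smoothing: identity at 0 mm, constants invariant, delta peak matches the kernel", {
  set.seed(3)
  a <- array(rnorm(10^3), dim = c(10, 10, 10))
  expect_identical(smooth_gmv(a, 0), a)
  konst <- array(2.5, dim = c(8, 8, 8))
  expect_equal(smooth_gmv(konst, 9, voxel_size_mm = 3), konst,
               tolerance = 1e-12)                     # replicate boundary
  # delta spike: peak = product of the three 1-D kernel centre weights,
  # computed here from the closed-form discrete Gaussian (independent oracle)
  d <- array(0, dim = c(11, 11, 11)); d[6, 6, 6] <- 1
  fwhm <- 6; vox <- 3
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / vox
  r <- max(1, ceiling(4 * sigma))
  k0 <- exp(0) / sum(exp(-(seq(-r, r))^2 / (2 * sigma^2)))
  sm <- smooth_gmv(d, fwhm, voxel_size_mm = vox)
  expect_equal(sm[6, 6, 6], k0^3, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)         # mass preserved
  expect_error(smooth_gmv(a, -1), "fwhm")
})

test_that("age residualization matches per-feature OLS and extrapolates", {
  age_tr <- c(20, 30, 40, 50)
  X_tr <- cbind(f1 = 2 + 0.5 * age_tr,                # exactly linear
                f2 = c(1, 5, 2, 4))                   # arbitrary
  st <- fit_residualize(X_tr, age_tr)
  R <- apply_residualize(st, X_tr, age_tr)
  expect_equal(unname(R[, 1]), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(drop(cor(R[, 2], age_tr))), 0, tolerance = 1e-10)
  # hand oracle via lm(), apply ages outside the training range (no clamping)
  ref <- lm(X_tr[, 2] ~ age_tr)
  age_ap <- c(10, 70)
  X_ap <- cbind(c(0, 0), c(3, 3))
  A <- apply_residualize(st, X_ap, age_ap)
  expect_equal(unname(A[, 2]),
               3 - unname(predict(ref, data.frame(age_tr = age_ap))),
               tolerance = 1e-10)
  expect_warning(fit_residualize(X_tr, rep(33, 4)), "zero age variance")
})

test_that("site offset correction equalizes planted offsets and falls back for unseen sites", {
  set.seed(4)
  base <- matrix(rnorm(40), 20, 2)
  sites <- rep(c("A", "B"), each = 10)
  X <- base + ifelse(sites == "A", 0.7, -0.7)
  st <- fit_site_offset(X, sites)
  Xc <- apply_site_offset(st, X, sites)
  expect_lt(max(abs(colMeans(Xc[sites == "A", ]) -
                    colMeans(Xc[sites == "B", ]))), 1e-10)
  # single site: no-op
  st1 <- fit_site_offset(base, rep("A", 20))
  expect_lt(max(abs(apply_site_offset(st1, base, rep("A", 20)) - base)), 1e-12)
  # unseen apply site: row unchanged
  row <- matrix(rnorm(2), 1, 2)
  expect_identical(apply_site_offset(st, row, "Z"), row)
})

test_that("PCA retains the energy-rule component count and matches a hand eigendecomposition", {
  one_axis <- cbind(c(-1, 0, 1) * 5, c(0, 0, 0) + 1e-8 * c(1, -2, 1))
  expect_equal(fit_pca(one_axis, 0.25)$k, 1L)
  set.seed(5)
  Xr <- matrix(rnorm(40), 10, 4)
  full <- fit_pca(Xr, 1.0)
  expect_equal(full$k, qr(scale(Xr, scale = FALSE))$rank)
  # 3-point toy against eigen() on the covariance (independent oracle)
  X3 <- rbind(c(1, 0), c(0, 1), c(-1, -1))
  st <- fit_pca(X3, 0.75)
  ev <- eigen(cov(X3))
  expect_equal(st$k, 1L)                              # 75% energy on PC1
  S <- apply_pca(st, X3)
  Sref <- scale(X3, scale = FALSE) %*% ev$vectors[, 1]
  expect_equal(abs(drop(cor(S[, 1], Sref))), 1, tolerance = 1e-10)
  expect_equal(sd(S[, 1]), sqrt(ev$values[1]), tolerance = 1e-10)
  expect_error(fit_pca(X3, 1.5), "energy")
})

test_that("min-max scaling uses train ranges, clips, and zeroes constant columns", {
  S_tr <- cbind(a = c(2, 4), b = c(7, 7))
  st <- fit_scale(S_tr)
  expect_equal(unname(apply_scale(st, S_tr)[, 1]), c(0, 1))
  expect_equal(unname(apply_scale(st, S_tr)[, 2]), c(0, 0))   # constant -> 0
  ap <- apply_scale(st, cbind(c(5, 3, 1), c(9, 7, 5)))
  expect_equal(unname(ap[, 1]), c(1, 0.5, 0))                 # clip + midpoint
})

test_that("build_cv produces the stated fold structure deterministically", {
  ids <- sprintf("S%02d", 1:10)
  cv <- build_cv(ids, K = 5, P = 5, seed = 3)
  expect_length(cv, 25L)
  expect_true(all(vapply(cv, function(f) length(f$train_ids), 1L) == 8L))
  expect_true(all(vapply(cv, function(f) length(f$test_ids), 1L) == 2L))
  for (p in 1:5) {
    tests <- unlist(lapply(cv[vapply(cv, `[[`, 1L, "repeat_i") == p],
                           `[[`, "test_ids"))
    expect_setequal(tests, ids)                       # partition per repeat
  }
  expect_identical(build_cv(ids, 5, 5, seed = 3), cv) # determinism
  loo <- build_cv(ids, K = 10, P = 1, seed = 1)
  expect_true(all(vapply(loo, function(f) length(f$test_ids), 1L) == 1L))
  expect_error(build_cv(ids[1:3], K = 5), "n = 3")
  # stratification keeps both labels in every training fold
  lab <- rep(c("x", "y"), each = 5)
  cvs <- build_cv(ids, K = 5, P = 2, seed = 2, stratify_on = lab)
  for (f in cvs)
    expect_setequal(unique(lab[match(f$train_ids, ids)]), c("x", "y"))
})
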