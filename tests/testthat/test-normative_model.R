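# Nested-CV training: bookkeeping, out-of-fold discipline, leakage checks,
# ensemble prediction invariances, and the permutation-test formula.

tiny_train <- function() memo("tiny_train", {
  co <- tiny_cohort()
  hc <- co$table[co$table$group == "HC", ]
  sel <- stratified_select(hc, make_bmi_bins(18.5, 35, 0.5), 30, seed = 2)
  tab <- apply_selection(co$table, sel)
  disc <- tab$subject_id[tab$split %in% "discovery"]
  ens <- train_normative(co$features, tab, co$mask, ids = disc, task = "bmi",
                         grid = small_grid("bmi"), outer_k = 5, outer_p = 1,
                         inner_k = 3, inner_p = 1, seed = 3)
  list(co = co, tab = tab, disc = disc, ens = ens)
})

test_that("ensemble bookkeeping: one model per outer partition, full oof coverage", {
  tt <- tiny_train()
  expect_length(tt$ens$models, 5L)                    # P1 * K1
  expect_setequal(names(tt$ens$oof), tt$disc)
  expect_true(all(is.finite(tt$ens$oof)))
  # single-candidate grid is selected everywhere
  expect_true(all(tt$ens$selection_log$C == small_grid("bmi")$C))
})

test_that("no leakage: mutating a held-out subject leaves its fold's fitted state unchanged", {
  tt <- tiny_train()
  victim <- tt$ens$models[[1]]$test_ids[1]
  feats <- tt$co$features
  feats[victim, ] <- feats[victim, ] + 5              # gross corruption
  ens2 <- train_normative(feats, tt$tab, tt$co$mask, ids = tt$disc,
                          task = "bmi", grid = small_grid("bmi"),
                          outer_k = 5, outer_p = 1, inner_k = 3, inner_p = 1,
                          seed = 3)
  for (m in seq_along(tt$ens$models)) {
    a <- tt$ens$models[[m]]; b <- ens2$models[[m]]
    if (victim %in% a$train_ids) next
    expect_identical(a$state$pca$basis, b$state$pca$basis)
    expect_identical(a$state$residualize$coefs, b$state$residualize$coefs)
    expect_identical(a$fit$w, b$fit$w)
    expect_identical(a$fit$b, b$fit$b)
    # other held-out subjects' predictions unchanged
    others <- setdiff(a$test_ids, victim)
    rows <- match(others, a$test_ids)
    expect_identical(predict(a$fit, a$S_test[rows, , drop = FALSE]),
                     predict(b$fit, b$S_test[rows, , drop = FALSE]))
  }
})

test_that("predict_ensemble: pool subjects are out-of-fold, externals are model means", {
  tt <- tiny_train()
  pr <- predict_ensemble(tt$ens, tt$co$features, tt$tab, tt$co$mask)
  expect_equal(pr$prediction[match(tt$disc, pr$subject_id)],
               unname(tt$ens$oof[tt$disc]))
  expect_true(all(pr$source[pr$subject_id %in% tt$disc] == "out_of_fold"))
  ext <- setdiff(pr$subject_id, tt$disc)
  expect_true(all(pr$source[pr$subject_id %in% ext] == "ensemble_mean"))
  # mean invariance: permuting model order leaves external predictions alone
  ens_perm <- tt$ens
  ens_perm$models <- rev(ens_perm$models)
  pr2 <- predict_ensemble(ens_perm, tt$co$features, tt$tab, tt$co$mask)
  expect_equal(pr$prediction, pr2$prediction, tolerance = 1e-12)
  expect_error(predict_ensemble(tt$ens, tt$co$features[, 1:10], tt$tab,
                                tt$co$mask), "n_features")
})

test_that("training is deterministic under a fixed seed", {
  tt <- tiny_train()
  ens2 <- train_normative(tt$co$features, tt$tab, tt$co$mask, ids = tt$disc,
                          task = "bmi", grid = small_grid("bmi"),
                          outer_k = 5, outer_p = 1, inner_k = 3, inner_p = 1,
                          seed = 3)
  expect_identical(tt$ens$oof, ens2$oof)
})

test_that("disease classifier trains, predicts, and orients decision scores", {
  # strong planted atrophy so the small-sample classification is well-posed
  co <- memo("dx_cohort", generate_cohort(tiny_spec(seed = 13, beta_dx = 0.5,
                                                    n_per_group = c(HC = 60L,
                                                                    SCZ = 30L))))
  tab <- co$table
  ids <- tab$subject_id[tab$group %in% c("HC", "SCZ")]
  ens <- train_normative(co$features, tab, co$mask, ids = ids, task = "dx",
                         grid = small_grid("dx"), outer_k = 3, outer_p = 1,
                         inner_k = 2, inner_p = 1, seed = 4, pos_label = "SCZ")
  sc <- ens$oof
  scz <- tab$subject_id[tab$group == "SCZ"]
  hc <- intersect(ids, tab$subject_id[tab$group == "HC"])
  expect_gt(mean(sc[scz]), mean(sc[hc]))              # disease scores higher
  lab <- ifelse(sc >= 0, "SCZ", "HC")
  truth <- tab$group[match(ids, tab$subject_id)]
  expect_gt(bac_from_labels(truth, lab[ids], "SCZ")$bac, 60)
})

test_that("permutation test obeys the add-one formula and its floor", {
  # the default world has a strong planted signal, so the observed MAE beats
  # every permuted draw and p sits at the add-one floor
  ens <- accept_ensemble()
  co <- accept_cohort()
  pt <- permutation_test(ens, co$table, n_perm = 19, seed = 5)
  expect_gte(pt$p, 1 / 20)
  expect_lte(pt$p, 1)
  expect_equal(pt$p, 1 / 20)
  expect_lt(pt$observed, min(pt$null))
})
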