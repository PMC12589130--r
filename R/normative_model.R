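# Repeated nested cross-validation around the preprocessing chain and the
# linear nu-SVR (BMI) / linear SVC (diagnosis) models. All fitted parameters
# — residualization lines, site offsets, PCA bases, scaling ranges, model
# weights, hyperparameters — come from training rows only; discovery-sample
# predictions are strictly out-of-fold.

#' Default hyperparameter grid
#'
#' Preprocessing candidates (FWHM, PCA energy) crossed with model
#' hyperparameters: `nu` for regression, cost `C` for both (powers of four
#' spanning 2^-5 .. 2^5).
#'
#' @param task `"bmi"` (regression) or `"dx"` (classification).
#' @return data.frame of candidate configurations.
#' @export
default_grid <- function(task = c("bmi", "dx")) {
  task <- match.arg(task)
  C <- 4^seq(-2.5, 2.5, by = 1)   # 2^-5, 2^-3, ..., 2^5
  if (task == "bmi")
    expand.grid(fwhm = c(0, 3, 6, 9), energy = c(0.25, 0.5, 0.75),
                nu = c(0.25, 0.5, 0.75), C = C)
  else
    expand.grid(fwhm = c(0, 3, 6, 9), energy = c(0.25, 0.5, 0.75), C = C)
}

#' Reduced grid for desk-scale runs
#' @rdname default_grid
#' @export
small_grid <- function(task = c("bmi", "dx")) {
  task <- match.arg(task)
  if (task == "bmi") expand.grid(fwhm = 6, energy = 0.75, nu = 0.5, C = 8)
  else expand.grid(fwhm = 6, energy = 0.75, C = 8)
}

fit_candidate <- function(S_train, tab_train, task, cfg, seed, pos_label) {
  if (task == "bmi")
    nusvr_fit(S_train, tab_train$bmi_measured, C = cfg$C, nu = cfg$nu,
              seed = seed)
  else
    svc_fit(S_train, tab_train$group, C = cfg$C, pos_label = pos_label,
            seed = seed)
}

eval_candidate <- function(fit, S_test, tab_test, task, pos_label) {
  pred <- predict(fit, S_test)
  if (task == "bmi") {
    mean(abs(pred - tab_test$bmi_measured))          # MAE, lower better
  } else {
    lab <- ifelse(pred >= 0, fit$pos_label, fit$neg_label)
    -bac_from_labels(tab_test$group, lab, fit$pos_label)$bac  # -BAC
  }
}

#' Train a normative BMI predictor or disease classifier under repeated
#' nested cross-validation
#'
#' Outer loop: `outer_p` repeats x `outer_k` folds. Per outer training
#' partition, an inner `inner_p` x `inner_k` CV selects the configuration
#' (FWHM, PCA energy, nu, C) minimizing inner-test MAE (regression) or
#' maximizing balanced accuracy (classification); the winner is refitted on
#' the full outer training partition. Held-out outer folds provide strictly
#' out-of-fold predictions for every training-pool subject.
#'
#' @param features `[n x p]` masked GMV matrix, rownames = subject_id
#'   (unsmoothed; smoothing is applied per candidate FWHM internally).
#' @param table cohort data.frame covering at least the rows of `features`.
#' @param mask `voxel_mask` matching the feature columns.
#' @param ids subject ids forming the training pool (e.g. the discovery
#'   sample, or HC + SCZ rows for the classifier).
#' @param task `"bmi"` or `"dx"`.
#' @param grid candidate data.frame (see [default_grid()]).
#' @param outer_k,outer_p,inner_k,inner_p CV geometry (defaults 5/5/5/5).
#' @param seed master seed; folds and solver streams derive from it.
#' @param pos_label positive class for `task = "dx"`.
#' @return object of class `trained_ensemble`: per-outer-partition models
#'   (preprocessing state, linear weights, chosen configuration, cached
#'   component scores for fast permutation refits), out-of-fold predictions,
#'   and a selection log.
#' @export
train_normative <- function(features, table, mask, ids,
                            task = c("bmi", "dx"),
                            grid = default_grid(task),
                            outer_k = 5L, outer_p = 5L,
                            inner_k = 5L, inner_p = 5L,
                            seed = 1L, pos_label = "SCZ") {
  task <- match.arg(task)
  stopifnot(!is.null(rownames(features)))
  if (!all(ids %in% rownames(features))) stopf("ids missing from features")
  if (!all(ids %in% table$subject_id)) stopf("ids missing from table")
  tab <- table[match(rownames(features), table$subject_id), , drop = FALSE]
  if (task == "bmi" && anyNA(tab$bmi_measured[match(ids, tab$subject_id)]))
    stopf("missing BMI in training pool")

  fwhms <- sort(unique(grid$fwhm))
  smoothed <- lapply(fwhms, function(f) smooth_feature_matrix(features, mask, f))
  names(smoothed) <- as.character(fwhms)

  strat <- if (task == "dx") tab$group[match(ids, tab$subject_id)] else NULL
  outer <- build_cv(ids, K = outer_k, P = outer_p,
                    seed = derive_seed(seed, "outer"), stratify_on = strat)

  models <- vector("list", length(outer))
  log_rows <- vector("list", length(outer))
  oof_sum <- setNames(numeric(length(ids)), ids)
  oof_n <- setNames(integer(length(ids)), ids)

  for (m in seq_along(outer)) {
    tr_ids <- outer[[m]]$train_ids
    te_ids <- outer[[m]]$test_ids
    tr_rows <- match(tr_ids, rownames(features))
    te_rows <- match(te_ids, rownames(features))
    strat_in <- if (task == "dx") tab$group[tr_rows] else NULL
    inner <- build_cv(tr_ids, K = inner_k, P = inner_p,
                      seed = derive_seed(seed, 1000L + m),
                      stratify_on = strat_in)
    scores <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      cfg <- grid[g, ]
      Xs <- smoothed[[as.character(cfg$fwhm)]]
      fold_scores <- numeric(length(inner))
      ok <- logical(length(inner))
      for (f in seq_along(inner)) {
        itr <- match(inner[[f]]$train_ids, rownames(features))
        ite <- match(inner[[f]]$test_ids, rownames(features))
        if (task == "dx" && length(unique(tab$group[itr])) < 2L) next
        st <- fit_preproc(Xs[itr, , drop = FALSE], tab$age[itr],
                          tab$site[itr], cfg$energy, cfg$fwhm)
        S_tr <- apply_preproc(st, Xs[itr, , drop = FALSE],
                              tab$age[itr], tab$site[itr])
        S_te <- apply_preproc(st, Xs[ite, , drop = FALSE],
                              tab$age[ite], tab$site[ite])
        fit <- fit_candidate(S_tr, tab[itr, ], task, cfg,
                             derive_seed(seed, 2000L + m), pos_label)
        fold_scores[f] <- eval_candidate(fit, S_te, tab[ite, ], task, pos_label)
        ok[f] <- TRUE
      }
      scores[g] <- if (any(ok)) mean(fold_scores[ok]) else Inf
    }
    best <- which.min(scores)
    cfg <- grid[best, ]
    Xs <- smoothed[[as.character(cfg$fwhm)]]
    st <- fit_preproc(Xs[tr_rows, , drop = FALSE], tab$age[tr_rows],
                      tab$site[tr_rows], cfg$energy, cfg$fwhm)
    S_tr <- apply_preproc(st, Xs[tr_rows, , drop = FALSE],
                          tab$age[tr_rows], tab$site[tr_rows])
    S_te <- apply_preproc(st, Xs[te_rows, , drop = FALSE],
                          tab$age[te_rows], tab$site[te_rows])
    fit <- fit_candidate(S_tr, tab[tr_rows, ], task, cfg,
                         derive_seed(seed, 3000L + m), pos_label)
    pred_te <- predict(fit, S_te)
    oof_sum[te_ids] <- oof_sum[te_ids] + pred_te
    oof_n[te_ids] <- oof_n[te_ids] + 1L
    models[[m]] <- list(state = st, fit = fit, config = cfg,
                        train_ids = tr_ids, test_ids = te_ids,
                        S_train = S_tr, S_test = S_te,
                        repeat_i = outer[[m]]$repeat_i,
                        fold_i = outer[[m]]$fold_i)
    log_rows[[m]] <- cbind(model = m, cfg, inner_score = scores[best])
  }
  if (any(oof_n == 0L)) stopf("internal: subject without out-of-fold prediction")
  oof <- oof_sum / oof_n

  ens <- structure(list(task = task, models = models, oof = oof,
                        ids = ids, grid = grid, seed = seed,
                        pos_label = if (task == "dx") pos_label else NULL,
                        selection_log = do.call(rbind, log_rows),
                        outer_k = outer_k, outer_p = outer_p,
                        inner_k = inner_k, inner_p = inner_p),
                   class = "trained_ensemble")
  ens
}

#' @export
print.trained_ensemble <- function(x, ...) {
  cat(sprintf("<trained_ensemble task=%s, %d models (%dx%d outer), n=%d>\n",
              x$task, length(x$models), x$outer_p, x$outer_k, length(x$ids)))
  invisible(x)
}

#' Ensemble prediction for arbitrary subjects
#'
#' Training-pool subjects receive the mean of their out-of-fold predictions;
#' all other subjects receive the mean over all outer models, each applying
#' its own preprocessing state.
#'
#' @param ensemble `trained_ensemble`.
#' @param features `[n x p]` masked GMV matrix (rownames = subject_id).
#' @param table cohort data.frame covering the rows.
#' @param mask `voxel_mask` matching the features.
#' @return data.frame with `subject_id`, `prediction` (kg/m2 for task `bmi`,
#'   signed decision score for task `dx`), and `source`
#'   (`"out_of_fold"` / `"ensemble_mean"`).
#' @export
predict_ensemble <- function(ensemble, features, table, mask) {
  stopifnot(inherits(ensemble, "trained_ensemble"))
  if (ncol(features) != mask$n_features)
    stopf("feature count %d != mask n_features %d",
          ncol(features), mask$n_features)
  ids <- rownames(features)
  tab <- table[match(ids, table$subject_id), , drop = FALSE]
  in_pool <- ids %in% ensemble$ids
  pred <- setNames(numeric(length(ids)), ids)
  pred[in_pool] <- ensemble$oof[ids[in_pool]]
  if (any(!in_pool)) {
    rows <- which(!in_pool)
    fwhms <- unique(vapply(ensemble$models, function(m) m$config$fwhm, 1.0))
    sm <- lapply(fwhms, function(f)
      smooth_feature_matrix(features[rows, , drop = FALSE], mask, f))
    names(sm) <- as.character(fwhms)
    acc <- numeric(length(rows))
    for (m in ensemble$models) {
      Xs <- sm[[as.character(m$config$fwhm)]]
      S <- apply_preproc(m$state, Xs, tab$age[rows], tab$site[rows])
      acc <- acc + predict(m$fit, S)
    }
    pred[rows] <- acc / length(ensemble$models)
  }
  data.frame(subject_id = ids, prediction = as.numeric(pred),
             source = ifelse(in_pool, "out_of_fold", "ensemble_mean"),
             stringsAsFactors = FALSE)
}

#' Regression performance summary
#'
#' @param predicted,measured aligned numeric vectors.
#' @return list with `mae`, `r`, `r2` (squared Pearson correlation), `n`.
#' @export
regression_metrics <- function(predicted, measured) {
  ok <- is.finite(predicted) & is.finite(measured)
  r <- cor(predicted[ok], measured[ok])
  list(mae = mean(abs(predicted[ok] - measured[ok])), r = r, r2 = r^2,
       n = sum(ok))
}

#' Label-permutation significance test
#'
#' Permutes the outcome within the training pool and recomputes the
#' out-of-fold criterion with the per-partition preprocessing states and
#' winning configurations frozen (the preprocessing never sees the outcome,
#' so its fitted parameters are permutation-invariant; only the linear model
#' is refitted). p uses the add-one estimator and therefore never returns 0.
#'
#' @param ensemble `trained_ensemble`.
#' @param table cohort data.frame.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list with `p`, `observed` (MAE or BAC), `null` (permuted values).
#' @export
permutation_test <- function(ensemble, table, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stopf("n_perm must be >= 1")
  ids <- ensemble$ids
  tab <- table[match(ids, table$subject_id), , drop = FALSE]
  task <- ensemble$task
  y_obs <- if (task == "bmi") setNames(tab$bmi_measured, ids)
           else setNames(tab$group, ids)

  score_for <- function(y) {
    oof_sum <- setNames(numeric(length(ids)), ids)
    oof_n <- setNames(integer(length(ids)), ids)
    for (m in ensemble$models) {
      ytr <- y[m$train_ids]
      fit <- if (task == "bmi")
        nusvr_fit(m$S_train, ytr, C = m$config$C, nu = m$config$nu,
                  seed = ensemble$seed)
      else
        svc_fit(m$S_train, ytr, C = m$config$C,
                pos_label = ensemble$pos_label, seed = ensemble$seed)
      oof_sum[m$test_ids] <- oof_sum[m$test_ids] + predict(fit, m$S_test)
      oof_n[m$test_ids] <- oof_n[m$test_ids] + 1L
    }
    oof <- oof_sum / pmax(oof_n, 1L)
    if (task == "bmi") {
      mean(abs(oof - y_obs))       # MAE against the true labels
    } else {
      lab <- ifelse(oof >= 0, ensemble$pos_label,
                    setdiff(unique(y_obs), ensemble$pos_label)[1])
      bac_from_labels(y_obs, lab, ensemble$pos_label)$bac
    }
  }

  observed <- if (task == "bmi") mean(abs(ensemble$oof - y_obs)) else {
    lab <- ifelse(ensemble$oof >= 0, ensemble$pos_label,
                  setdiff(unique(y_obs), ensemble$pos_label)[1])
    bac_from_labels(y_obs, lab, ensemble$pos_label)$bac
  }
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    y_perm <- with_seed(derive_seed(seed, b), setNames(sample(y_obs), ids))
    null[b] <- score_for(y_perm)
  }
  extreme <- if (task == "bmi") sum(null <= observed) else sum(null >= observed)
  list(p = (1 + extreme) / (n_perm + 1), observed = observed, null = null)
}
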