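# Longitudinal weight outcomes: weight-change tables with percent-gain flags,
# age/sex/group-stratified gap-weight-change correlations under per-panel FDR,
# and the multivariate weight-gain classifier with BMIgap ablation.

#' Compute weight changes and percent-gain flags
#'
#' `dW1 = weight_t1 - weight_t0`, `dW2 = weight_t2 - weight_t0`,
#' `pct = 100 * dW / weight_t0`; gain flags use "at least" thresholds
#' (`pct >= k`) at +3/+5/+7%. Missing follow-ups stay missing (never
#' imputed); subjects with non-positive baseline weight are excluded with a
#' log message.
#'
#' @param table cohort data.frame with `weight_t0/t1/t2`.
#' @return data.frame `subject_id`, `dw1`, `dw2`, `pct1`, `pct2`, and flags
#'   `gain3_t1` .. `gain7_t2` (logical, NA when follow-up missing).
#' @export
compute_weight_change <- function(table) {
  bad <- !is.na(table$weight_t0) & table$weight_t0 <= 0
  if (any(bad))
    message(sprintf("compute_weight_change: excluding %d subject(s) with non-positive baseline weight",
                    sum(bad)))
  tab <- table[!bad, , drop = FALSE]
  out <- data.frame(subject_id = tab$subject_id, stringsAsFactors = FALSE)
  out$dw1 <- tab$weight_t1 - tab$weight_t0
  out$dw2 <- tab$weight_t2 - tab$weight_t0
  out$pct1 <- 100 * out$dw1 / tab$weight_t0
  out$pct2 <- 100 * out$dw2 / tab$weight_t0
  for (k in c(3, 5, 7)) {
    out[[sprintf("gain%d_t1", k)]] <- out$pct1 >= k
    out[[sprintf("gain%d_t2", k)]] <- out$pct2 >= k
  }
  out
}

#' Default age stratification grid
#'
#' Broad spans 15-40 .. 35-40 plus 5-year intervals, as used in the
#' correlation heatmaps.
#' @return named list of `c(lo, hi)` age intervals (inclusive).
#' @export
default_age_strata <- function() {
  broad <- lapply(seq(15, 35, 5), function(lo) c(lo, 40))
  fine <- lapply(seq(15, 35, 5), function(lo) c(lo, lo + 5))
  strata <- c(list(c(0, 200)), broad, fine)
  names(strata) <- c("all", vapply(c(broad, fine), function(r)
    sprintf("%d-%d", r[1], r[2]), ""))
  strata
}

#' Stratified BMIgap / weight-change correlations with FDR
#'
#' Pearson correlations per cell of group x horizon x age stratum x gain
#' threshold (and optionally sex); Benjamini-Hochberg FDR applied within each
#' (group x horizon) family, matching a per-panel correction. Cells with
#' `n < 3` are reported with NA.
#'
#' @param gaps named numeric of corrected gaps (by subject_id).
#' @param wct result of [compute_weight_change()].
#' @param table cohort data.frame (supplies age, sex, group).
#' @param groups groups to analyze.
#' @param horizons follow-up horizons (1, 2).
#' @param thresholds percent-gain subgroup thresholds; `NA` = all subjects
#'   with an observed change.
#' @param age_strata named list of inclusive age intervals.
#' @param by_sex additionally split cells by sex.
#' @return data.frame, one row per cell: `group`, `horizon`, `age_stratum`,
#'   `threshold`, (`sex`,) `n`, `r`, `p`, `p_fdr`.
#' @export
stratified_correlations <- function(gaps, wct, table,
                                    groups = c("HC", "CHR", "ROD"),
                                    horizons = c(1, 2),
                                    thresholds = c(NA, 3, 5, 7),
                                    age_strata = default_age_strata(),
                                    by_sex = FALSE) {
  tab <- table[match(wct$subject_id, table$subject_id), , drop = FALSE]
  sexes <- if (by_sex) c("F", "M") else NA_character_
  rows <- list()
  for (grp in groups) for (h in horizons) for (sx in sexes) {
    for (a in names(age_strata)) for (thr in thresholds) {
      rng <- age_strata[[a]]
      dw <- wct[[sprintf("dw%d", h)]]
      pct <- wct[[sprintf("pct%d", h)]]
      keep <- tab$group == grp & !is.na(dw) &
        tab$age >= rng[1] & tab$age <= rng[2] &
        wct$subject_id %in% names(gaps)
      if (!is.na(thr)) keep <- keep & pct >= thr
      if (!is.na(sx)) keep <- keep & tab$sex == sx
      g <- gaps[wct$subject_id[keep]]
      d <- dw[keep]
      n <- sum(keep)
      if (n >= 3 && sd(g) > 0 && sd(d) > 0) {
        ct <- cor.test(g, d)
        r <- unname(ct$estimate); p <- ct$p.value
      } else { r <- NA_real_; p <- NA_real_ }
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, horizon = h, sex = sx, age_stratum = a,
        threshold = thr, n = n, r = r, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  for (grp in unique(out$group)) for (h in unique(out$horizon)) {
    fam <- which(out$group == grp & out$horizon == h & !is.na(out$p))
    if (length(fam)) out$p_fdr[fam] <- p.adjust(out$p[fam], method = "BH")
  }
  if (!by_sex) out$sex <- NULL
  out
}

# z-scoring fitted on training rows only
fit_zscore <- function(X) list(mu = colMeans(X), sd = apply(X, 2, sd))
apply_zscore <- function(st, X) {
  s <- ifelse(st$sd > 0, st$sd, 1)
  sweep(sweep(X, 2, st$mu), 2, s, `/`)
}

#' Multivariate weight-gain classifier with BMIgap ablation
#'
#' Predicts a percent-gain label (>= `threshold`% at horizon T`horizon`) from
#' BMIgap, age, sex, study group, exercise, somatic history, and tobacco use
#' with a linear soft-margin classifier under the same repeated nested CV
#' machinery as the imaging models (features z-scored inside CV; inner
#' selection of C by balanced accuracy). Set `with_bmigap = FALSE` for the
#' ablated model.
#'
#' @param gaps named numeric of corrected gaps.
#' @param wct result of [compute_weight_change()].
#' @param table cohort data.frame.
#' @param threshold percent-gain threshold (3, 5, or 7).
#' @param horizon follow-up horizon (1 or 2).
#' @param groups subjects to include (default CHR + ROD).
#' @param with_bmigap include the BMIgap feature.
#' @param include_tobacco include tobacco use (default TRUE).
#' @param outer_k,outer_p,inner_k,inner_p CV geometry.
#' @param C_grid cost candidates.
#' @param n_perm label permutations for the significance of the BAC (0 = skip).
#' @param seed integer seed.
#' @return list with `bac`, `sensitivity`, `specificity` (from pooled
#'   out-of-fold labels), `fold_bac` (per outer fold), `feature_cvr`
#'   (mean weight / SE across models), `perm_p`, `n`, `features`.
#' @export
weight_gain_classifier <- function(gaps, wct, table, threshold = 7,
                                   horizon = 2, groups = c("CHR", "ROD"),
                                   with_bmigap = TRUE, include_tobacco = TRUE,
                                   outer_k = 5L, outer_p = 5L,
                                   inner_k = 5L, inner_p = 5L,
                                   C_grid = 4^(-1:1), n_perm = 0L,
                                   seed = 1L) {
  tab <- table[match(wct$subject_id, table$subject_id), , drop = FALSE]
  flag <- wct[[sprintf("gain%d_t%d", threshold, horizon)]]
  keep <- tab$group %in% groups & !is.na(flag) &
    wct$subject_id %in% names(gaps)
  tab <- tab[keep, , drop = FALSE]
  y <- ifelse(flag[keep], "gain", "no_gain")
  if (length(unique(y)) < 2L) stopf("single-class labels at +%d%% T%d",
                                    threshold, horizon)
  X <- cbind(
    bmigap = as.numeric(gaps[tab$subject_id]),
    age = tab$age,
    sex = as.numeric(tab$sex == "F"),
    group_rod = as.numeric(tab$group == "ROD"),
    exercise = as.numeric(tab$exercise),
    somatic_history = as.numeric(tab$somatic_history))
  if (include_tobacco) X <- cbind(X, tobacco = as.numeric(tab$tobacco))
  if (!with_bmigap) X <- X[, colnames(X) != "bmigap", drop = FALSE]
  rownames(X) <- tab$subject_id

  ids <- tab$subject_id
  outer <- build_cv(ids, K = outer_k, P = outer_p,
                    seed = derive_seed(seed, "wg_outer"), stratify_on = y)
  W <- matrix(NA_real_, length(outer), ncol(X),
              dimnames = list(NULL, colnames(X)))
  fold_bac <- numeric(length(outer))
  oof_sum <- setNames(numeric(length(ids)), ids)
  oof_n <- setNames(integer(length(ids)), ids)
  chosen_C <- numeric(length(outer))
  for (m in seq_along(outer)) {
    tr <- match(outer[[m]]$train_ids, ids)
    te <- match(outer[[m]]$test_ids, ids)
    inner <- build_cv(ids[tr], K = inner_k, P = inner_p,
                      seed = derive_seed(seed, 5000L + m),
                      stratify_on = y[tr])
    inner_bac <- vapply(C_grid, function(C) {
      vals <- vapply(inner, function(f) {
        itr <- match(f$train_ids, ids); ite <- match(f$test_ids, ids)
        if (length(unique(y[itr])) < 2L) return(NA_real_)
        zs <- fit_zscore(X[itr, , drop = FALSE])
        fit <- svc_fit(apply_zscore(zs, X[itr, , drop = FALSE]), y[itr],
                       C = C, pos_label = "gain",
                       seed = derive_seed(seed, 6000L + m))
        pred <- predict(fit, apply_zscore(zs, X[ite, , drop = FALSE]),
                        type = "label")
        bac_from_labels(y[ite], pred, "gain")$bac
      }, 1.0)
      mean(vals, na.rm = TRUE)
    }, 1.0)
    C_best <- C_grid[which.max(inner_bac)]
    chosen_C[m] <- C_best
    zs <- fit_zscore(X[tr, , drop = FALSE])
    fit <- svc_fit(apply_zscore(zs, X[tr, , drop = FALSE]), y[tr], C = C_best,
                   pos_label = "gain", seed = derive_seed(seed, 7000L + m))
    sc <- predict(fit, apply_zscore(zs, X[te, , drop = FALSE]))
    oof_sum[te] <- oof_sum[te] + sc
    oof_n[te] <- oof_n[te] + 1L
    pred <- ifelse(sc >= 0, "gain", "no_gain")
    fold_bac[m] <- bac_from_labels(y[te], pred, "gain")$bac
    W[m, ] <- fit$w
  }
  oof <- oof_sum / pmax(oof_n, 1L)
  oof_lab <- ifelse(oof >= 0, "gain", "no_gain")
  perf <- bac_from_labels(y, oof_lab, "gain")
  mw <- colMeans(W); sw <- apply(W, 2, sd) / sqrt(nrow(W))
  feature_cvr <- ifelse(sw > 0, mw / sw, sign(mw) * 1e6)

  perm_p <- NA_real_
  if (n_perm > 0L) {
    obs <- perf$bac
    null <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      yp <- with_seed(derive_seed(seed, 90000L + b), sample(y))
      accs <- vapply(seq_along(outer), function(m) {
        tr <- match(outer[[m]]$train_ids, ids)
        te <- match(outer[[m]]$test_ids, ids)
        if (length(unique(yp[tr])) < 2L) return(NA_real_)
        zs <- fit_zscore(X[tr, , drop = FALSE])
        fit <- svc_fit(apply_zscore(zs, X[tr, , drop = FALSE]), yp[tr],
                       C = chosen_C[m], pos_label = "gain",
                       seed = derive_seed(seed, 7000L + m))
        pred <- predict(fit, apply_zscore(zs, X[te, , drop = FALSE]),
                        type = "label")
        bac_from_labels(yp[te], pred, "gain")$bac
      }, 1.0)
      null[b] <- mean(accs, na.rm = TRUE)
    }
    perm_p <- (1 + sum(null >= obs)) / (n_perm + 1)
  }
  list(bac = perf$bac, sensitivity = perf$sensitivity,
       specificity = perf$specificity, fold_bac = fold_bac,
       feature_cvr = feature_cvr, feature_weights = W, perm_p = perm_p,
       n = length(ids), features = colnames(X), oof_score = oof, labels = y)
}

#' Compare two classifiers by paired fold-level balanced accuracy
#'
#' Two-sided paired t-test over aligned outer-fold BAC lists (25 folds give
#' d.f. 24). Constant differences (zero variance) are flagged instead of
#' producing an undefined statistic.
#'
#' @param bac_with,bac_without equal-length numeric vectors of per-fold BAC.
#' @return list with `t`, `df`, `p`, `mean_diff`, `degenerate` flag.
#' @export
compare_models <- function(bac_with, bac_without) {
  if (length(bac_with) != length(bac_without))
    stopf("fold lists differ in length: %d vs %d",
          length(bac_with), length(bac_without))
  d <- bac_with - bac_without
  if (sd(d) < 1e-12) {
    if (all(d == 0))
      return(list(t = 0, df = length(d) - 1L, p = 1, mean_diff = 0,
                  degenerate = TRUE))
    warnf("constant nonzero paired differences; t undefined")
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- t.test(bac_with, bac_without, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = mean(d), degenerate = FALSE)
}
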