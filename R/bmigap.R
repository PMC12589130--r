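# The gap score itself: raw gap = predicted - measured BMI, bias-corrected by
# residualizing on measured BMI with a line fitted once on the discovery
# out-of-fold gaps, then group / medication / dosage association analyses.

#' Compute raw BMIgap
#'
#' `gap_raw = bmi_predicted - bmi_measured`; positive values mean the brain
#' looks heavier than the measured phenotype. Subjects missing either value
#' are dropped with a message.
#'
#' @param predictions data.frame with `subject_id` and `prediction` (from
#'   [predict_ensemble()]), or a named numeric vector.
#' @param table cohort data.frame with `bmi_measured`.
#' @return object of class `bmigap_result`: data.frame columns `subject_id`,
#'   `bmi_measured`, `bmi_predicted`, `gap_raw`, `gap_corrected` (NA until
#'   corrected), plus a `correction` attribute.
#' @export
compute_gap <- function(predictions, table) {
  if (is.numeric(predictions))
    predictions <- data.frame(subject_id = names(predictions),
                              prediction = as.numeric(predictions))
  tab <- table[match(predictions$subject_id, table$subject_id), , drop = FALSE]
  ok <- is.finite(predictions$prediction) & !is.na(tab$bmi_measured)
  if (any(!ok))
    message(sprintf("compute_gap: dropping %d subject(s) with missing BMI or prediction",
                    sum(!ok)))
  res <- data.frame(subject_id = predictions$subject_id[ok],
                    bmi_measured = tab$bmi_measured[ok],
                    bmi_predicted = predictions$prediction[ok],
                    stringsAsFactors = FALSE)
  res$gap_raw <- res$bmi_predicted - res$bmi_measured
  res$gap_corrected <- NA_real_
  structure(res, class = c("bmigap_result", "data.frame"), correction = NULL)
}

#' Fit the BMI-dependent bias correction
#'
#' OLS of the raw gap on measured BMI, fitted on the discovery out-of-fold
#' gaps only (regression-to-the-mean: overestimation at low BMI,
#' underestimation at high BMI). Within the fitting sample the corrected gap
#' has exactly mean 0 and zero correlation with measured BMI.
#'
#' @param result `bmigap_result` restricted to the correction-fitting sample.
#' @return list with `intercept`, `slope`, `fit_ids`, `fit_sample` label.
#' @export
fit_bias_correction <- function(result, fit_sample = "discovery") {
  if (var(result$bmi_measured) < 1e-12)
    stopf("zero BMI variance in the correction-fitting sample")
  co <- coef(lm(gap_raw ~ bmi_measured, data = result))
  list(intercept = unname(co[1]), slope = unname(co[2]),
       fit_ids = result$subject_id, fit_sample = fit_sample)
}

#' Apply a fitted bias correction
#'
#' `gap_corrected = gap_raw - (intercept + slope * bmi_measured)` with the
#' coefficients from [fit_bias_correction()], applied unchanged to any sample.
#'
#' @param result `bmigap_result`.
#' @param correction result of [fit_bias_correction()].
#' @return the `bmigap_result` with `gap_corrected` filled and the correction
#'   recorded as an attribute.
#' @export
apply_bias_correction <- function(result, correction) {
  result$gap_corrected <- result$gap_raw -
    (correction$intercept + correction$slope * result$bmi_measured)
  attr(result, "correction") <- correction
  result
}

#' Group comparisons of corrected BMIgap
#'
#' One-way ANOVA across the provided sample labels, pairwise Welch t-tests of
#' a reference sample against every other, and a variance-ratio F test for
#' any requested pair.
#'
#' @param gaps numeric vector of corrected gaps.
#' @param sample_labels factor/character aligned with `gaps` (e.g. discovery /
#'   validation / SCZ / CHR / ROD).
#' @param reference label used for the pairwise contrasts.
#' @return list with `anova` (`F`, `df1`, `df2`, `p`), `group_means`,
#'   `pairwise` (data.frame), and `var_ratio(a, b)` left to [stats::var.test].
#' @export
group_tests <- function(gaps, sample_labels, reference = NULL) {
  keep <- !is.na(gaps) & !is.na(sample_labels)
  gaps <- gaps[keep]; sample_labels <- as.character(sample_labels)[keep]
  tabn <- table(sample_labels)
  small <- names(tabn)[tabn < 2]
  if (length(small)) {
    warnf("excluding group(s) with n < 2: %s", paste(small, collapse = ", "))
    keep <- !sample_labels %in% small
    gaps <- gaps[keep]; sample_labels <- sample_labels[keep]
  }
  if (length(unique(sample_labels)) < 2L) stopf("need >= 2 groups")
  fit <- aov(gaps ~ factor(sample_labels))
  an <- anova(fit)
  res <- list(anova = list(F = an$`F value`[1], df1 = an$Df[1],
                           df2 = an$Df[2], p = an$`Pr(>F)`[1]),
              group_means = tapply(gaps, sample_labels, mean),
              group_n = as.list(table(sample_labels)))
  ref <- reference %||% names(sort(table(sample_labels), decreasing = TRUE))[1]
  others <- setdiff(unique(sample_labels), ref)
  pw <- lapply(others, function(g) {
    tt <- t.test(gaps[sample_labels == ref], gaps[sample_labels == g])
    data.frame(reference = ref, group = g, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  })
  res$pairwise <- do.call(rbind, pw)
  res
}

#' Medication contrasts of corrected BMIgap
#'
#' Per group (and pooled): ANOVA over medication-naivety strata and a Welch
#' t-test of weight-gain-associated versus weight-neutral/none medication,
#' with stratum sizes and percentages reported alongside. Strata that are
#' empty or single-valued are skipped with a log entry.
#'
#' @param gaps named numeric (by subject_id) of corrected gaps.
#' @param table cohort data.frame with medication flag columns.
#' @param groups disease groups to analyze (default CHR and ROD).
#' @return list per group (plus `"pooled"`): `counts` (n and percent per
#'   stratum), `t_weightgain` (t, df, p) when both strata are populated.
#' @export
medication_contrasts <- function(gaps, table, groups = c("CHR", "ROD")) {
  out <- list()
  analyze <- function(rows, label) {
    tab <- table[rows, , drop = FALSE]
    g <- gaps[tab$subject_id]
    n <- length(g)
    med <- tab$weightgain_med
    counts <- lapply(c("yes", "neutral_or_none", "unknown"), function(lev) {
      k <- sum(med == lev, na.rm = TRUE)
      list(n = k, pct = if (n) round(100 * k / n, 2) else NA_real_)
    })
    names(counts) <- c("yes", "neutral_or_none", "unknown")
    res <- list(counts = counts, n = n)
    a <- g[!is.na(med) & med == "yes"]
    b <- g[!is.na(med) & med == "neutral_or_none"]
    if (length(a) >= 2 && length(b) >= 2) {
      tt <- t.test(a, b)
      res$t_weightgain <- list(t = unname(tt$statistic),
                               df = unname(tt$parameter), p = tt$p.value)
    } else {
      message(sprintf("medication_contrasts [%s]: weight-gain contrast skipped (n = %d vs %d)",
                      label, length(a), length(b)))
    }
    strata <- interaction(tab$antipsychotic_naive, tab$antidepressant_naive,
                          drop = TRUE)
    if (nlevels(strata) >= 2 && all(table(strata) >= 2)) {
      an <- anova(aov(g ~ strata))
      res$anova_naive <- list(F = an$`F value`[1], df1 = an$Df[1],
                              df2 = an$Df[2], p = an$`Pr(>F)`[1])
    }
    res
  }
  for (grp in groups) {
    rows <- which(table$group == grp & table$subject_id %in% names(gaps))
    if (length(rows)) out[[grp]] <- analyze(rows, grp)
  }
  rows <- which(table$group %in% groups & table$subject_id %in% names(gaps))
  if (length(rows)) out$pooled <- analyze(rows, "pooled")
  out
}

#' Correlate corrected BMIgap with antipsychotic dosage
#'
#' Two-sided Pearson correlation between gap and chlorpromazine equivalents.
#'
#' @param gaps named numeric (by subject_id).
#' @param table cohort data.frame with `cpz_equiv`.
#' @param group restrict to this group (default SCZ).
#' @return list with `r`, `p`, `n`; `r` is NA (flagged) for constant input.
#' @export
dosage_correlation <- function(gaps, table, group = "SCZ") {
  tab <- table[table$group == group & table$subject_id %in% names(gaps), ]
  g <- gaps[tab$subject_id]
  ok <- !is.na(g) & !is.na(tab$cpz_equiv)
  if (sum(ok) < 3L) stopf("need >= 3 paired observations, got %d", sum(ok))
  x <- g[ok]; y <- tab$cpz_equiv[ok]
  if (var(x) < 1e-12 || var(y) < 1e-12) {
    warnf("constant input; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  }
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
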