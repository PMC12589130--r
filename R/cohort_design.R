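# Discovery-sample construction: uniform BMI bins over the eligible range,
# per-bin balanced quotas, and greedy age matching toward the pooled eligible
# mean age. The remaining eligible HCs become the validation sample.

#' Build a uniform BMI bin scheme
#'
#' Contiguous half-open bins `[a, b)` tiling `[lo, hi)`; a BMI equal to `hi`
#' is assigned to the last bin (closed top edge), so every in-range value maps
#' to exactly one bin. The defaults give the standard 33 bins of width 0.5
#' over 18.5-35 kg/m2.
#'
#' @param lo,hi range in kg/m2, `hi > lo`.
#' @param width bin width; `(hi - lo) / width` must be integral (tol 1e-9).
#' @return object of class `bin_scheme` with `edges`, `n_bins`, `lo`, `hi`,
#'   `width`.
#' @export
make_bmi_bins <- function(lo = 18.5, hi = 35.0, width = 0.5) {
  if (hi <= lo || width <= 0) stopf("need hi > lo and width > 0")
  k <- (hi - lo) / width
  if (abs(k - round(k)) > 1e-9)
    stopf("(hi - lo) / width = %g is not an integer", k)
  k <- as.integer(round(k))
  structure(list(lo = lo, hi = hi, width = width, n_bins = k,
                 edges = lo + width * (0:k)),
            class = "bin_scheme")
}

#' Assign BMI values to bins
#'
#' @param bmi numeric vector.
#' @param scheme `bin_scheme`.
#' @return integer bin index (1-based); `NA` for out-of-range values.
#' @export
bin_assign <- function(bmi, scheme) {
  idx <- floor((bmi - scheme$lo) / scheme$width) + 1L
  idx[bmi == scheme$hi] <- scheme$n_bins          # closed top edge
  idx[bmi < scheme$lo | bmi > scheme$hi] <- NA_integer_
  as.integer(idx)
}

#' Stratified discovery selection with age matching
#'
#' Splits the eligible healthy controls into a discovery sample of size
#' `target_n` — balanced across BMI bins, with per-bin greedy age matching
#' toward the pooled eligible mean age — and a validation sample (everyone
#' else). Quota per bin is `floor(target_n / n_bins)`; the remainder is
#' handed out one slot at a time to bins ordered by candidate count ascending
#' (ties by bin index). Bins with fewer candidates than their quota contribute
#' everyone and the shortfall is redistributed to bins with spare candidates
#' (most spare first, ties by bin index).
#'
#' @param table eligible-HC cohort data.frame (`subject_id`, `age`,
#'   `bmi_measured`). Callers restrict eligibility (age, BMI range, HC) first;
#'   rows with out-of-range BMI are rejected here.
#' @param scheme `bin_scheme`.
#' @param target_n discovery sample size.
#' @param seed integer; used only to break age ties, so the selection is a
#'   deterministic function of `(table, scheme, target_n, seed)`.
#' @return list with `discovery_ids`, `validation_ids`, `bin_index` (named by
#'   subject_id), `per_bin_counts`, `per_bin_mean_age`.
#' @export
stratified_select <- function(table, scheme, target_n, seed = 1L) {
  if (target_n > nrow(table))
    stopf("target_n = %d exceeds eligible count %d", target_n, nrow(table))
  bins <- bin_assign(table$bmi_measured, scheme)
  if (anyNA(bins))
    stopf("BMI outside [%g, %g] in row(s): %s", scheme$lo, scheme$hi,
          paste(which(is.na(bins)), collapse = ", "))
  nb <- scheme$n_bins
  cand <- split(seq_len(nrow(table)), factor(bins, levels = seq_len(nb)))
  n_cand <- vapply(cand, length, 1L)

  quota <- rep(target_n %/% nb, nb)
  rem <- target_n - sum(quota)
  if (rem > 0) {
    ord <- order(n_cand, seq_len(nb))   # sparsest first, ties by bin index
    quota[ord[seq_len(rem)]] <- quota[ord[seq_len(rem)]] + 1L
  }
  take <- pmin(quota, n_cand)
  shortfall <- target_n - sum(take)
  while (shortfall > 0) {
    spare <- n_cand - take
    if (all(spare == 0)) stopf("cannot place %d remaining slots", shortfall)
    pick <- order(-spare, seq_len(nb))[1]
    take[pick] <- take[pick] + 1L
    shortfall <- shortfall - 1L
  }

  mu_age <- mean(table$age)
  sel_rows <- integer(0)
  for (b in seq_len(nb)) {
    if (take[b] == 0L || n_cand[b] == 0L) next
    rows <- cand[[b]]
    # seeded shuffle fixes the scan order; greedy then pulls the running bin
    # mean age toward the pooled mean
    rows <- rows[with_seed(derive_seed(seed, b), sample.int(length(rows)))]
    chosen <- integer(0)
    ages <- table$age[rows]
    for (s in seq_len(take[b])) {
      cur <- table$age[chosen]
      score <- abs((sum(cur) + ages) / (length(cur) + 1) - mu_age)
      j <- which.min(score)          # first minimum: deterministic tie-break
      chosen <- c(chosen, rows[j])
      rows <- rows[-j]; ages <- ages[-j]
    }
    sel_rows <- c(sel_rows, chosen)
  }
  disc <- table$subject_id[sort(sel_rows)]
  vali <- setdiff(table$subject_id, disc)
  sel_bins <- bins[sort(sel_rows)]
  list(discovery_ids = disc,
       validation_ids = vali,
       bin_index = setNames(bins, table$subject_id),
       per_bin_counts = tabulate(sel_bins, nbins = nb),
       per_bin_mean_age = vapply(seq_len(nb), function(b) {
         a <- table$age[sort(sel_rows)][sel_bins == b]
         if (length(a)) mean(a) else NA_real_
       }, 1.0))
}

#' Apply a selection to a cohort table
#'
#' Fills the `split` column: selected HCs become `discovery`, the rest of the
#' eligible HCs `validation`; non-HC rows keep their split.
#'
#' @param table cohort data.frame.
#' @param sel result of [stratified_select()].
#' @return the table with `split` filled.
#' @export
apply_selection <- function(table, sel) {
  if (!"split" %in% names(table)) table$split <- NA_character_
  table$split[table$subject_id %in% sel$discovery_ids] <- "discovery"
  table$split[table$subject_id %in% sel$validation_ids] <- "validation"
  table
}
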