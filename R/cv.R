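# Repeated (P permutations) K-fold cross-validation structures, optionally
# stratified by a label. Folds are a deterministic function of the seed.

#' Build a repeated K-fold CV structure
#'
#' @param ids subject identifiers.
#' @param K folds per repeat.
#' @param P repeats (independent shuffles).
#' @param seed integer seed; identical seeds give identical folds.
#' @param stratify_on optional label vector aligned with `ids`; folds then
#'   balance label proportions.
#' @return object of class `cv_structure`: list of `P * K` elements, each with
#'   `train_ids`, `test_ids`, `repeat_i`, `fold_i`.
#' @export
build_cv <- function(ids, K = 5L, P = 5L, seed = 1L, stratify_on = NULL) {
  n <- length(ids)
  if (n < K) stopf("n = %d < K = %d", n, K)
  if (!is.null(stratify_on) && length(stratify_on) != n)
    stopf("stratify_on must align with ids")
  out <- vector("list", P * K)
  m <- 0L
  for (p in seq_len(P)) {
    fold_of <- with_seed(derive_seed(seed, p), {
      if (is.null(stratify_on)) {
        sample(rep_len(seq_len(K), n))
      } else {
        f <- integer(n)
        for (lev in unique(stratify_on)) {
          rows <- which(stratify_on == lev)
          f[rows] <- sample(rep_len(seq_len(K), length(rows)))
        }
        f
      }
    })
    for (k in seq_len(K)) {
      m <- m + 1L
      out[[m]] <- list(train_ids = ids[fold_of != k],
                       test_ids = ids[fold_of == k],
                       repeat_i = p, fold_i = k)
    }
  }
  structure(out, class = "cv_structure", ids = ids, K = K, P = P, seed = seed)
}

#' @export
print.cv_structure <- function(x, ...) {
  cat(sprintf("<cv_structure %d repeats x %d folds over %d ids>\n",
              attr(x, "P"), attr(x, "K"), length(attr(x, "ids"))))
  invisible(x)
}
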