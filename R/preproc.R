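# The leakage-free preprocessing chain, fitted on training rows only and
# applied unchanged to any other rows. Order is fixed by construction:
# (1) smoothing (parameter-free, precomputed per FWHM) -> (2) age
# residualization -> (3) site mean-offset correction -> (4) PCA -> (5)
# per-component min-max scaling to [0, 1].

#' Fit/apply per-feature age residualization
#'
#' Per feature, OLS of feature on age with intercept fitted on the training
#' rows (the residual step of a partial correlation); the same fitted line is
#' subtracted from apply rows, extrapolating without clamping.
#'
#' @param X_train,age_train training matrix and ages.
#' @return list with `coefs` (2 x p: intercept, slope) and `skipped` flag; use
#'   [apply_residualize()] for new rows.
#' @export
fit_residualize <- function(X_train, age_train) {
  if (nrow(X_train) < 3L) stopf("residualization needs >= 3 training rows")
  if (!all(is.finite(age_train))) stopf("non-finite ages")
  if (var(age_train) < 1e-12) {
    warnf("zero age variance in training rows; residualization skipped")
    return(list(coefs = NULL, skipped = TRUE))
  }
  A <- cbind(1, age_train)
  coefs <- solve(crossprod(A), crossprod(A, X_train))   # 2 x p
  list(coefs = coefs, skipped = FALSE)
}

#' @rdname fit_residualize
#' @param state result of `fit_residualize`.
#' @param X,age rows to residualize with the fitted line.
#' @export
apply_residualize <- function(state, X, age) {
  if (isTRUE(state$skipped)) return(X)
  X - cbind(1, age) %*% state$coefs
}

#' Fit/apply site mean-offset correction
#'
#' Per site and feature, the training-set site mean minus the training grand
#' mean is subtracted. Sites unseen at fit time receive zero offset.
#'
#' @param X_train,sites_train training matrix and site labels.
#' @return list with `grand` and per-site `offsets`.
#' @export
fit_site_offset <- function(X_train, sites_train) {
  if (length(unique(sites_train)) < 1L) stopf("need >= 1 site")
  grand <- colMeans(X_train)
  offsets <- lapply(split(seq_len(nrow(X_train)), sites_train),
                    function(rows) colMeans(X_train[rows, , drop = FALSE]) - grand)
  list(grand = grand, offsets = offsets)
}

#' @rdname fit_site_offset
#' @param state result of `fit_site_offset`.
#' @param X,sites rows to correct.
#' @export
apply_site_offset <- function(state, X, sites) {
  for (s in unique(sites)) {
    off <- state$offsets[[s]]
    if (is.null(off)) next                      # unseen site: zero offset
    rows <- which(sites == s)
    X[rows, ] <- sweep(X[rows, , drop = FALSE], 2, off)
  }
  X
}

#' Fit/apply PCA at an energy level
#'
#' Centers on the training mean and retains the smallest number of components
#' whose cumulative explained-variance ratio reaches `energy`.
#'
#' @param X_train training matrix (n >= 2).
#' @param energy in `(0, 1]`.
#' @return list with `mean`, `basis` (p x k), `k`, `evr`.
#' @export
fit_pca <- function(X_train, energy) {
  if (energy <= 0 || energy > 1) stopf("energy must be in (0, 1]")
  if (nrow(X_train) < 2L) stopf("PCA needs >= 2 training rows")
  mu <- colMeans(X_train)
  Xc <- sweep(X_train, 2, mu)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2
  pos <- ev > max(ev) * 1e-12
  evr <- cumsum(ev[pos]) / sum(ev[pos])
  k <- which(evr >= energy - 1e-12)[1]
  list(mean = mu, basis = sv$v[, seq_len(k), drop = FALSE], k = k, evr = evr)
}

#' @rdname fit_pca
#' @param state result of `fit_pca`.
#' @param X rows to project on the training basis.
#' @export
apply_pca <- function(state, X) {
  sweep(X, 2, state$mean) %*% state$basis
}

#' Fit/apply min-max scaling to \[0, 1\]
#'
#' Column ranges come from the training rows; apply values are clipped to
#' `[0, 1]`; zero-range columns map to 0.
#'
#' @param S_train training score matrix.
#' @return list with `lo`, `hi`.
#' @export
fit_scale <- function(S_train) {
  list(lo = apply(S_train, 2, min), hi = apply(S_train, 2, max))
}

#' @rdname fit_scale
#' @param state result of `fit_scale`.
#' @param S rows to scale.
#' @export
apply_scale <- function(state, S) {
  rng <- state$hi - state$lo
  inv <- ifelse(rng > 0, 1 / rng, 0)            # constant column -> all 0
  out <- sweep(sweep(S, 2, state$lo), 2, inv, `*`)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Fit the full preprocessing chain on training rows
#'
#' @param X_train smoothed feature matrix (training rows, at the chain's FWHM
#'   level).
#' @param age_train,sites_train training covariates.
#' @param energy PCA energy level.
#' @param fwhm_mm recorded for bookkeeping (smoothing itself is parameter-free
#'   and applied upstream).
#' @return object of class `preproc_state`.
#' @export
fit_preproc <- function(X_train, age_train, sites_train, energy,
                        fwhm_mm = 0) {
  res <- fit_residualize(X_train, age_train)
  X1 <- apply_residualize(res, X_train, age_train)
  site <- fit_site_offset(X1, sites_train)
  X2 <- apply_site_offset(site, X1, sites_train)
  pca <- fit_pca(X2, energy)
  S <- apply_pca(pca, X2)
  sc <- fit_scale(S)
  structure(list(fwhm_mm = fwhm_mm, energy = energy, residualize = res,
                 site = site, pca = pca, scale = sc),
            class = "preproc_state")
}

#' Apply a fitted preprocessing chain
#'
#' @param state `preproc_state`.
#' @param X rows (already smoothed at `state$fwhm_mm`).
#' @param age,sites covariates for the rows.
#' @return `[n x k]` matrix of scaled component scores.
#' @export
apply_preproc <- function(state, X, age, sites) {
  X <- apply_residualize(state$residualize, X, age)
  X <- apply_site_offset(state$site, X, sites)
  S <- apply_pca(state$pca, X)
  apply_scale(state$scale, S)
}
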