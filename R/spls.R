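# Sparse partial least squares (PMD-style) between the six-feature clinical
# matrix and the overlap-region voxel matrix: alternating power iterations on
# the cross-covariance with L1-ball projection, projection deflation between
# latent variables, permutation reliability, and bootstrap-ratio stability.

# Project w onto {z : ||z||_2 = 1, ||z||_1 <= c} via soft-thresholding with
# the threshold found by bisection (Witten/Tibshirani/Hastie PMD).
l1_ball_unit <- function(w, c) {
  nrm <- sqrt(sum(w^2))
  if (nrm < 1e-300) return(w)
  z <- w / nrm
  if (sum(abs(z)) <= c + 1e-12) return(z)
  soft <- function(delta) {
    s <- sign(w) * pmax(abs(w) - delta, 0)
    n2 <- sqrt(sum(s^2))
    if (n2 < 1e-300) NULL else s / n2
  }
  lo <- 0; hi <- max(abs(w))
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    s <- soft(mid)
    if (is.null(s) || sum(abs(s)) < c) hi <- mid else lo <- mid
  }
  s <- soft(lo)
  if (is.null(s)) {
    # c at (or below) the 1-sparse vertex: keep the single largest entry
    s <- numeric(length(w))
    j <- which.max(abs(w))
    s[j] <- sign(w[j])
  }
  s
}

#' Assemble the standardized six-feature clinical matrix
#'
#' Columns: corrected BMIgap, disease expression score (classifier decision
#' value), PANSS total, age at onset, illness duration, hospitalizations.
#' Rows: disease-group subjects with all six features present (listwise
#' deletion); columns standardized to mean 0, sd 1.
#'
#' @param table cohort data.frame.
#' @param gaps named numeric of corrected gaps (by subject_id).
#' @param dx_scores named numeric of disease expression scores.
#' @param groups disease groups to include (default SCZ).
#' @return list with `Z` (`n x 6` matrix), `ids`, `center`, `scale`.
#' @export
build_clinical_matrix <- function(table, gaps, dx_scores, groups = "SCZ") {
  tab <- table[table$group %in% groups, , drop = FALSE]
  feat <- data.frame(
    bmigap_corrected = as.numeric(gaps[tab$subject_id]),
    dx_expression_score = as.numeric(dx_scores[tab$subject_id]),
    panss_total = tab$panss_total,
    age_at_onset = tab$age_at_onset,
    illness_duration = tab$illness_duration,
    n_hospitalizations = as.numeric(tab$n_hospitalizations))
  ok <- stats::complete.cases(feat)
  if (sum(ok) < 10L) stopf("only %d complete rows (< 10)", sum(ok))
  if (any(!ok))
    message(sprintf("build_clinical_matrix: %d row(s) dropped for missing features",
                    sum(!ok)))
  Z <- scale(as.matrix(feat[ok, ]))
  list(Z = Z[, , drop = FALSE], ids = tab$subject_id[ok],
       center = attr(Z, "scaled:center"), scale = attr(Z, "scaled:scale"))
}

fit_one_lv <- function(M, c_u, c_v, tol = 1e-6, max_iter = 500L) {
  sv <- svd(M, nu = 1, nv = 1)
  u <- sv$u[, 1]; v <- sv$v[, 1]
  converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    u_new <- l1_ball_unit(drop(M %*% v), c_u)
    v_new <- l1_ball_unit(drop(crossprod(M, u_new)), c_v)
    delta <- max(max(abs(u_new - u)), max(abs(v_new - v)))
    u <- u_new; v <- v_new
    if (delta < tol) { converged <- TRUE; break }
  }
  # orientation: largest-magnitude clinical salience positive
  j <- which.max(abs(u))
  if (u[j] < 0) { u <- -u; v <- -v }
  list(u = u, v = v, converged = converged, iterations = it)
}

#' Fit sparse PLS latent variables
#'
#' Alternating soft-thresholded power iterations on `X'Y` with L1-ball radii
#' `c_u` (clinical side) and `c_v` (voxel side), projection deflation of both
#' blocks between latent variables.
#'
#' @param X standardized clinical matrix (`n x q`).
#' @param Y voxel matrix over overlap voxels (`n x p`); columns are
#'   standardized internally (`scale_y`).
#' @param c_u,c_v L1-ball radii in `[1, sqrt(q)]` / `[1, sqrt(p)]`.
#' @param max_lv number of latent variables to extract.
#' @param tol,max_iter convergence controls.
#' @param scale_y standardize the voxel block (default TRUE).
#' @return object of class `spls_result`: per LV `u`, `v`, `rho` (latent
#'   correlation), convergence info, plus the deflated blocks entering each
#'   LV (needed for permutation and bootstrap).
#' @export
spls_fit <- function(X, Y, c_u = sqrt(ncol(X)), c_v = sqrt(ncol(Y)),
                     max_lv = 3L, tol = 1e-6, max_iter = 500L,
                     scale_y = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stopf("X and Y must have aligned rows")
  if (c_u < 1 || c_u > sqrt(ncol(X)) + 1e-9)
    stopf("c_u must be in [1, sqrt(ncol(X))]")
  if (c_v < 1 || c_v > sqrt(ncol(Y)) + 1e-9)
    stopf("c_v must be in [1, sqrt(ncol(Y))]")
  if (scale_y) {
    sdv <- apply(Y, 2, sd)
    Y <- sweep(Y, 2, colMeans(Y))
    Y <- sweep(Y, 2, ifelse(sdv > 0, sdv, 1), `/`)
  }
  lvs <- vector("list", max_lv)
  Xd <- X; Yd <- Y
  for (l in seq_len(max_lv)) {
    M <- crossprod(Xd, Yd)
    f <- fit_one_lv(M, c_u, c_v, tol, max_iter)
    if (!f$converged)
      warnf("LV%d did not converge in %d iterations", l, max_iter)
    xs <- drop(Xd %*% f$u); ys <- drop(Yd %*% f$v)
    rho <- if (sd(xs) > 0 && sd(ys) > 0) cor(xs, ys) else NA_real_
    lvs[[l]] <- list(u = f$u, v = f$v, rho = rho, converged = f$converged,
                     iterations = f$iterations, X_defl = Xd, Y_defl = Yd)
    Xd <- Xd - tcrossprod(xs, f$u)     # projection deflation
    Yd <- Yd - tcrossprod(ys, f$v)
  }
  structure(list(lvs = lvs, c_u = c_u, c_v = c_v,
                 q = ncol(X), p = ncol(Y), n = nrow(X)),
            class = "spls_result")
}

#' @export
print.spls_result <- function(x, ...) {
  rho <- vapply(x$lvs, `[[`, 1.0, "rho")
  cat(sprintf("<spls_result %d LVs, rho = %s>\n", length(x$lvs),
              paste(round(rho, 3), collapse = ", ")))
  invisible(x)
}

#' Permutation reliability of the latent variables
#'
#' Per LV, the rows of the deflated clinical block are permuted and the LV is
#' refitted; `p = (1 + #{rho_perm >= rho_obs}) / (n_perm + 1)`. Extraction is
#' declared reliable up to the first non-significant LV.
#'
#' @param fit `spls_result`.
#' @param n_perm permutations (>= 99).
#' @param seed integer seed.
#' @param alpha significance level for the stop rule.
#' @return list with `p` (per LV), `n_reliable`, `alpha`.
#' @export
lv_permutation_test <- function(fit, n_perm = 1000L, seed = 1L, alpha = 0.05) {
  if (n_perm < 99L) stopf("n_perm must be >= 99")
  p <- numeric(length(fit$lvs))
  for (l in seq_along(fit$lvs)) {
    lv <- fit$lvs[[l]]
    null <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      Xp <- with_seed(derive_seed(seed, l * 100000L + b),
                      lv$X_defl[sample(nrow(lv$X_defl)), , drop = FALSE])
      f <- fit_one_lv(crossprod(Xp, lv$Y_defl), fit$c_u, fit$c_v)
      xs <- drop(Xp %*% f$u); ys <- drop(lv$Y_defl %*% f$v)
      null[b] <- if (sd(xs) > 0 && sd(ys) > 0) cor(xs, ys) else 0
    }
    p[l] <- (1 + sum(null >= lv$rho)) / (n_perm + 1)
  }
  first_ns <- which(p > alpha)[1]
  list(p = p, n_reliable = if (is.na(first_ns)) length(p) else first_ns - 1L,
       alpha = alpha)
}

#' Bootstrap ratios for the saliences of one latent variable
#'
#' Rows are resampled with replacement, the LV refitted on its deflated
#' blocks, saliences sign-aligned to the original, and
#' `BSR = original salience / bootstrap SE`. Zero bootstrap SE with a nonzero
#' salience yields a signed `cap`.
#'
#' @param fit `spls_result`.
#' @param lv latent-variable index.
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param cap guard for degenerate (zero-SE) saliences.
#' @return list with `bsr_u`, `bsr_v`, `se_u`, `se_v`, `cutoff` (1.96).
#' @export
bootstrap_ratios <- function(fit, lv = 1L, n_boot = 500L, seed = 1L,
                             cap = 1e6) {
  if (n_boot < 100L) stopf("n_boot must be >= 100")
  l <- fit$lvs[[lv]]
  n <- nrow(l$X_defl)
  U <- matrix(NA_real_, n_boot, length(l$u))
  V <- matrix(NA_real_, n_boot, length(l$v))
  for (b in seq_len(n_boot)) {
    rows <- with_seed(derive_seed(seed, lv * 1000000L + b),
                      sample(n, n, replace = TRUE))
    f <- fit_one_lv(crossprod(l$X_defl[rows, , drop = FALSE],
                              l$Y_defl[rows, , drop = FALSE]),
                    fit$c_u, fit$c_v)
    flip <- if (sum(f$u * l$u) < 0) -1 else 1
    U[b, ] <- flip * f$u
    V[b, ] <- flip * f$v
  }
  se_u <- apply(U, 2, sd); se_v <- apply(V, 2, sd)
  ratio <- function(orig, se) {
    out <- ifelse(se > 0, orig / se, sign(orig) * cap)
    out[orig == 0 & se == 0] <- 0
    out
  }
  list(bsr_u = ratio(l$u, se_u), bsr_v = ratio(l$v, se_v),
       se_u = se_u, se_v = se_v, cutoff = 1.96)
}
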