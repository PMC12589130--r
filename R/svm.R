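# R-level wrappers for the linear support-vector solvers. The bias enters as
# an augmented constant feature; nu-SVR is realized through the
# nu <-> epsilon equivalence: epsilon is chosen by bisection so that the
# fraction of training points strictly outside the tube is at most nu while
# the fraction of support vectors is at least nu.

augment <- function(X) cbind(X, bias = 1)

#' Fit a linear epsilon-SVR
#'
#' @param X `[n x p]` feature matrix.
#' @param y numeric response.
#' @param C per-point cost.
#' @param eps half-width of the insensitive tube.
#' @param max_epochs,tol,seed solver controls (deterministic given `seed`).
#' @return object of class `linear_svr` with `w`, `b`, `beta` (dual), `eps`.
#' @export
svr_fit <- function(X, y, C = 1, eps = 0.1, max_epochs = 300, tol = 1e-4,
                    seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stopf("X rows != length(y)")
  fit <- .svr_dcd(augment(X), as.double(y), C, eps,
                  as.integer(max_epochs), tol, as.integer(seed))
  w <- fit$w
  structure(list(w = w[-length(w)], b = w[length(w)], beta = fit$beta,
                 eps = eps, C = C, epochs = fit$epochs),
            class = "linear_svr")
}

#' @export
predict.linear_svr <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$w) + object$b
}

#' Fit a linear nu-SVR
#'
#' `nu` bounds the fraction of margin errors from above and the fraction of
#' support vectors from below; the tube width epsilon realizing this is found
#' by bisection over epsilon-SVR fits.
#'
#' @inheritParams svr_fit
#' @param nu target fraction in (0, 1).
#' @param n_bisect bisection steps.
#' @return `linear_svr` with extra fields `nu`, `frac_err`, `frac_sv`.
#' @export
nusvr_fit <- function(X, y, C = 1, nu = 0.5, n_bisect = 12L, max_epochs = 300,
                      tol = 1e-4, seed = 1L) {
  if (nu <= 0 || nu >= 1) stopf("nu must be in (0, 1)")
  X <- as.matrix(X)
  lo <- 0
  hi <- max(abs(y - mean(y))) + 1e-9
  frac_err <- function(fit) mean(abs(y - predict(fit, X)) > fit$eps + 1e-8)
  fit <- NULL
  for (it in seq_len(n_bisect)) {
    mid <- (lo + hi) / 2
    fit <- svr_fit(X, y, C = C, eps = mid, max_epochs = max_epochs,
                   tol = tol, seed = seed)
    if (frac_err(fit) > nu) lo <- mid else hi <- mid
  }
  fit <- svr_fit(X, y, C = C, eps = hi, max_epochs = max_epochs,
                 tol = tol, seed = seed)
  fit$nu <- nu
  fit$frac_err <- frac_err(fit)
  fit$frac_sv <- mean(abs(fit$beta) > 1e-8)
  fit
}

#' Fit a linear soft-margin classifier (L1-loss SVC)
#'
#' Decision scores are oriented so that larger = more `pos_label`-like.
#'
#' @param X `[n x p]` feature matrix.
#' @param labels vector with exactly two distinct values.
#' @param C per-point cost.
#' @param pos_label label mapped to +1 (default: the lexicographically larger
#'   one, so `"SCZ"` beats `"HC"` naturally).
#' @param max_epochs,tol,seed solver controls.
#' @return object of class `linear_svc` with `w`, `b`, `alpha`, `levels`.
#' @export
svc_fit <- function(X, labels, C = 1, pos_label = NULL, max_epochs = 300,
                    tol = 1e-4, seed = 1L) {
  X <- as.matrix(X)
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2L) stopf("svc_fit needs exactly 2 classes, got %d",
                               length(lev))
  pos <- pos_label %||% lev[2]
  y <- ifelse(as.character(labels) == pos, 1, -1)
  fit <- .svc_dcd(augment(X), as.double(y), C,
                  as.integer(max_epochs), tol, as.integer(seed))
  w <- fit$w
  structure(list(w = w[-length(w)], b = w[length(w)], alpha = fit$alpha,
                 C = C, pos_label = pos, neg_label = setdiff(lev, pos),
                 epochs = fit$epochs),
            class = "linear_svc")
}

#' @export
predict.linear_svc <- function(object, newdata,
                               type = c("score", "label"), ...) {
  type <- match.arg(type)
  score <- drop(as.matrix(newdata) %*% object$w) + object$b
  if (type == "score") score
  else ifelse(score >= 0, object$pos_label, object$neg_label)
}

#' Balanced accuracy from sensitivity and specificity
#'
#' @param sensitivity,specificity percentages in `[0, 100]`.
#' @return their arithmetic mean (a percentage).
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 100) ||
      any(specificity < 0 | specificity > 100))
    stopf("sensitivity and specificity must be in [0, 100]")
  (sensitivity + specificity) / 2
}

# confusion-count helper used by classifier evaluation
bac_from_labels <- function(truth, predicted, pos_label) {
  is_pos <- truth == pos_label
  sens <- if (any(is_pos)) 100 * mean(predicted[is_pos] == pos_label) else NA_real_
  spec <- if (any(!is_pos)) 100 * mean(predicted[!is_pos] != pos_label) else NA_real_
  list(sensitivity = sens, specificity = spec,
       bac = balanced_accuracy(sens, spec))
}
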