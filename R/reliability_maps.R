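# Voxel-space reliability of the linear ensembles: back-projection of model
# weights through the fitted scaling and PCA, cross-validation-ratio (CVR)
# maps, exact-binomial sign-based consistency maps with Benjamini-Hochberg
# FDR, binarization, and overlap of two predictors' binary maps.

new_stat_map <- function(kind, values, threshold_meta = NULL) {
  structure(list(kind = kind, values = as.numeric(values),
                 threshold_meta = threshold_meta),
            class = "voxel_stat_map")
}

#' @export
print.voxel_stat_map <- function(x, ...) {
  cat(sprintf("<voxel_stat_map kind=%s, %d voxels, %d nonzero>\n",
              x$kind, length(x$values), sum(x$values != 0)))
  invisible(x)
}

#' Back-project a fitted linear model to voxel space
#'
#' The component-space weights are pushed back through the min-max scaling
#' (diagonal) and the PCA basis. Age/site corrections are affine shifts and
#' smoothing is applied upstream of the state, so neither contributes to the
#' direction; zero-range scaled columns contribute nothing.
#'
#' @param model one element of `trained_ensemble$models` (or a list with
#'   `state` and `fit`).
#' @return numeric voxel weight vector (canonical mask ordering).
#' @export
backproject <- function(model) {
  st <- model$state
  fit <- model$fit
  if (is.null(st) || is.null(fit)) stopf("model lacks state or fit")
  rng <- st$scale$hi - st$scale$lo
  inv <- ifelse(rng > 0, 1 / rng, 0)
  drop(st$pca$basis %*% (fit$w * inv))
}

#' Voxel weight vectors for every model of an ensemble
#'
#' @param ensemble `trained_ensemble`.
#' @return matrix `[n_models x n_voxels]`.
#' @export
ensemble_weights <- function(ensemble) {
  t(vapply(ensemble$models, backproject,
           numeric(length(backproject(ensemble$models[[1]])))))
}

#' Cross-validation-ratio map
#'
#' Per voxel, `CVR = mean(w) / (sd(w) / sqrt(M))` across the M CV models
#' (standard-error normalization; switch to `se = FALSE` for plain sd). Zero
#' variance with nonzero mean yields `sign(mean) * cap`; zero mean and zero
#' variance yields 0.
#'
#' @param W `[M x p]` weight matrix (one row per model).
#' @param se divide sd by `sqrt(M)` (default TRUE).
#' @param cap guard value for zero-variance voxels.
#' @return `voxel_stat_map` of kind `"cvr"`.
#' @export
cvr_map <- function(W, se = TRUE, cap = 1e6) {
  if (nrow(W) < 2L) stopf("CVR needs >= 2 models")
  m <- colMeans(W)
  s <- apply(W, 2, sd)
  if (se) s <- s / sqrt(nrow(W))
  v <- ifelse(s > 0, m / s, sign(m) * cap)
  new_stat_map("cvr", v)
}

#' Sign-based consistency map with FDR control
#'
#' Per voxel, the number of models with positive weight is tested against a
#' fair coin (exact two-sided binomial); p-values are Benjamini-Hochberg
#' adjusted over all masked voxels. Surviving voxels carry the majority sign
#' (+1/-1), all others 0.
#'
#' @param W `[M x p]` weight matrix.
#' @param alpha FDR level (default 0.05).
#' @return `voxel_stat_map` of kind `"sign_z"` with `threshold_meta` holding
#'   `alpha`, the method, and raw/adjusted p-values.
#' @export
sign_consistency_map <- function(W, alpha = 0.05) {
  if (nrow(W) < 2L) stopf("sign consistency needs >= 2 models")
  M <- nrow(W)
  k <- colSums(W > 0)
  p_raw <- pmin(1, 2 * pmin(pbinom(k, M, 0.5), 1 - pbinom(k - 1, M, 0.5)))
  p_adj <- p.adjust(p_raw, method = "BH")
  sig <- p_adj <= alpha
  v <- ifelse(sig, ifelse(k > M / 2, 1, -1), 0)
  new_stat_map("sign_z", v,
               threshold_meta = list(alpha = alpha, method = "BH",
                                     p_raw = p_raw, p_adj = p_adj, M = M))
}

#' Threshold a CVR map by a sign-consistency map and binarize
#'
#' @param cvr `voxel_stat_map` of kind `"cvr"`.
#' @param sign_map `voxel_stat_map` of kind `"sign_z"` on the same mask.
#' @return list with `binary` (`voxel_stat_map`, values 0/1) and
#'   `cvr_thresholded` (CVR retained where the sign map survives).
#' @export
threshold_and_binarize <- function(cvr, sign_map) {
  if (length(cvr$values) != length(sign_map$values))
    stopf("map lengths differ: %d vs %d",
          length(cvr$values), length(sign_map$values))
  keep <- sign_map$values != 0
  list(binary = new_stat_map("binary", as.numeric(keep),
                             threshold_meta = sign_map$threshold_meta),
       cvr_thresholded = new_stat_map("cvr", ifelse(keep, cvr$values, 0),
                                      threshold_meta = sign_map$threshold_meta))
}

#' Overlap of two binary maps
#'
#' @param a,b binary `voxel_stat_map`s on the same mask.
#' @return list with `overlap` (binary `voxel_stat_map`, the voxelwise AND)
#'   and `stats` (`n_a`, `n_b`, `n_overlap`, `dice`).
#' @export
overlap_maps <- function(a, b) {
  if (length(a$values) != length(b$values))
    stopf("map lengths differ: %d vs %d", length(a$values), length(b$values))
  av <- a$values != 0
  bv <- b$values != 0
  ov <- av & bv
  dice <- if (sum(av) + sum(bv) == 0) NA_real_
          else 2 * sum(ov) / (sum(av) + sum(bv))
  list(overlap = new_stat_map("binary", as.numeric(ov)),
       stats = list(n_a = sum(av), n_b = sum(bv), n_overlap = sum(ov),
                    dice = dice))
}

#' Export a stat map as NIfTI with a JSON sidecar
#'
#' @param map `voxel_stat_map`.
#' @param mask `voxel_mask` defining the geometry.
#' @param path output `.nii`/`.nii.gz` path; the sidecar replaces the
#'   extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, mask, path) {
  img <- vector_to_volume(map$values, mask)
  write_nifti(img$data, path, affine = img$affine,
              voxel_size_mm = mask$voxel_size_mm)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- list(kind = map$kind, n_nonzero = sum(map$values != 0))
  if (!is.null(map$threshold_meta))
    meta$threshold <- map$threshold_meta[c("alpha", "method")]
  jsonlite::write_json(meta, side, auto_unbox = TRUE)
  invisible(path)
}
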