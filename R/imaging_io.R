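# Containers for GMV volumes, brain masks, and cohort phenotype tables, plus
# the volume <-> masked-feature-vector conversions used by every later stage.
#
# Conventions (documented once, used everywhere): world coordinates are RAS,
# voxel indices are 0-based in the affine sense, and the canonical feature
# ordering over masked voxels is ascending linear index in R's column-major
# array memory order — `which(mask)`. This makes feature column j reproducible
# across calls, reloads, and exported maps.

GROUP_LEVELS <- c("HC", "SCZ", "CHR", "ROD")
SPLIT_LEVELS <- c("discovery", "validation", "external", "clinical")

#' Construct a GMV image
#'
#' @param data numeric 3-D array of modulated gray-matter volume.
#' @param affine 4x4 voxel-to-world matrix (RAS); default scaled identity.
#' @param voxel_size_mm voxel edge lengths in mm (scalar or length 3).
#' @return object of class `gmv_image`.
#' @export
gmv_image <- function(data, affine = NULL, voxel_size_mm = 3) {
  if (length(dim(data)) != 3L) stopf("gmv_image expects a 3-D array")
  if (!all(is.finite(data))) stopf("gmv_image: non-finite voxel values")
  vs <- rep_len(as.double(voxel_size_mm), 3L)
  if (any(vs <= 0)) stopf("gmv_image: voxel sizes must be positive")
  if (is.null(affine)) affine <- diag(c(vs, 1))
  if (abs(det(affine)) < 1e-12) stopf("gmv_image: affine must be invertible")
  structure(list(data = data, affine = affine, voxel_size_mm = vs),
            class = "gmv_image")
}

#' @export
print.gmv_image <- function(x, ...) {
  cat(sprintf("<gmv_image %s, voxel %s mm>\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x")))
  invisible(x)
}

#' Construct a voxel mask defining the feature space
#'
#' @param mask logical 3-D array; `TRUE` voxels are features.
#' @param affine optional 4x4 affine carried for geometry checks.
#' @param voxel_size_mm voxel size in mm.
#' @return object of class `voxel_mask` with `n_features` and the canonical
#'   `ordering` (linear indices of masked voxels, ascending).
#' @export
voxel_mask <- function(mask, affine = NULL, voxel_size_mm = 3) {
  if (length(dim(mask)) != 3L || !is.logical(mask))
    stopf("voxel_mask expects a logical 3-D array")
  ordering <- which(mask)
  if (length(ordering) < 1L) stopf("voxel_mask: mask is empty")
  vs <- rep_len(as.double(voxel_size_mm), 3L)
  if (is.null(affine)) affine <- diag(c(vs, 1))
  structure(list(mask = mask, n_features = length(ordering),
                 ordering = ordering, affine = affine, voxel_size_mm = vs),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask %s, %d features>\n",
              paste(dim(x$mask), collapse = "x"), x$n_features))
  invisible(x)
}

check_geometry <- function(img, mask, what = "image") {
  if (!identical(dim(img$data), dim(mask$mask)))
    stopf("%s grid %s does not match mask grid %s", what,
          paste(dim(img$data), collapse = "x"),
          paste(dim(mask$mask), collapse = "x"))
  if (max(abs(img$affine - mask$affine)) > 1e-4)
    stopf("%s affine differs from mask affine beyond 1e-4", what)
  invisible(TRUE)
}

#' Extract the masked feature vector from a volume
#'
#' @param img `gmv_image` (or bare 3-D array).
#' @param mask `voxel_mask`.
#' @return numeric vector of length `mask$n_features` in canonical ordering.
#' @export
volume_to_vector <- function(img, mask) {
  data <- if (inherits(img, "gmv_image")) { check_geometry(img, mask); img$data } else img
  as.double(data[mask$ordering])
}

#' Embed a feature vector back into a volume
#'
#' Inverse of the masking in [read_gmv_set()]: masked voxels carry `v` in
#' canonical ordering, out-of-mask voxels are 0.
#'
#' @param v numeric vector of length `mask$n_features`.
#' @param mask `voxel_mask`.
#' @return `gmv_image`.
#' @export
vector_to_volume <- function(v, mask) {
  if (length(v) != mask$n_features)
    stopf("vector length %d != mask n_features %d", length(v), mask$n_features)
  vol <- array(0, dim = dim(mask$mask))
  vol[mask$ordering] <- as.double(v)
  gmv_image(vol, affine = mask$affine, voxel_size_mm = mask$voxel_size_mm)
}

#' Read a set of GMV images into a subject-by-feature matrix
#'
#' @param paths character vector of NIfTI paths, one per subject; row order
#'   follows path order.
#' @param mask `voxel_mask` shared by all images (affine tolerance 1e-4).
#' @return numeric matrix `[n_subjects x n_features]`.
#' @export
read_gmv_set <- function(paths, mask) {
  X <- matrix(NA_real_, nrow = length(paths), ncol = mask$n_features)
  for (i in seq_along(paths)) {
    nii <- read_nifti(paths[i])
    img <- gmv_image(nii$data, nii$affine, nii$voxel_size_mm)
    check_geometry(img, mask, what = paths[i])
    if (!all(is.finite(img$data))) stopf("non-finite voxels in %s", paths[i])
    X[i, ] <- img$data[mask$ordering]
  }
  rownames(X) <- names(paths) %||% basename(paths)
  X
}

COHORT_REQUIRED <- c("subject_id", "site", "group", "age", "sex", "bmi_measured")
COHORT_OPTIONAL <- c("split", "weight_t0", "weight_t1", "weight_t2",
                     "panss_total", "age_at_onset", "illness_duration",
                     "n_hospitalizations", "antipsychotic_naive",
                     "antidepressant_naive", "weightgain_med", "cpz_equiv",
                     "exercise", "somatic_history", "tobacco")

#' Load and validate a cohort phenotype table
#'
#' @param path TSV path with one row per subject (see README column
#'   dictionary), or a data.frame to validate in place.
#' @param bmi_range length-2 numeric; rows outside it are reported in the
#'   error message. The hard plausibility bound `[10, 60]` is always enforced.
#' @return validated data.frame.
#' @export
load_cohort <- function(path, bmi_range = c(10, 60)) {
  tab <- if (is.data.frame(path)) path
         else read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  miss <- setdiff(COHORT_REQUIRED, names(tab))
  if (length(miss)) stopf("cohort table missing required column(s): %s",
                          paste(miss, collapse = ", "))
  dup <- tab$subject_id[duplicated(tab$subject_id)]
  if (length(dup)) stopf("duplicate subject_id: %s",
                         paste(unique(dup), collapse = ", "))
  bad_grp <- setdiff(unique(tab$group), GROUP_LEVELS)
  if (length(bad_grp)) stopf("unknown group label(s): %s (allowed: %s)",
                             paste(bad_grp, collapse = ", "),
                             paste(GROUP_LEVELS, collapse = ", "))
  if ("split" %in% names(tab)) {
    bad_split <- setdiff(unique(tab$split[!is.na(tab$split)]), SPLIT_LEVELS)
    if (length(bad_split)) stopf("unknown split label(s): %s",
                                 paste(bad_split, collapse = ", "))
  }
  bmi <- tab$bmi_measured
  present <- !is.na(bmi)
  out <- present & (bmi < bmi_range[1] | bmi > bmi_range[2] | bmi < 10 | bmi > 60)
  if (any(out))
    stopf("BMI out of range [%g, %g] in row(s): %s", bmi_range[1], bmi_range[2],
          paste(which(out), collapse = ", "))
  for (w in c("weight_t0", "weight_t1", "weight_t2")) {
    if (w %in% names(tab) && any(!is.na(tab[[w]]) & tab[[w]] <= 0))
      stopf("non-positive %s in row(s): %s", w,
            paste(which(!is.na(tab[[w]]) & tab[[w]] <= 0), collapse = ", "))
  }
  tab
}

#' Write a cohort table as TSV
#'
#' @param tab data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
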