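# Phantom GMV cohorts with planted, recoverable structure: a smooth anatomy
# template, a contiguous BMI-coupled pattern, a partially overlapping disease
# pattern, an age pattern, flat per-site offsets, and longitudinal weights
# whose change is correlated with the planted gap. Everything downstream
# (selection, nested CV, gap scores, maps, SPLS, weight outcomes) is testable
# against the returned ground truth.

#' Specify a synthetic GMV phantom cohort
#'
#' Defaults encode the cohort structure the analysis assumes: BMI uniform on
#' 18.5-35 kg/m2, ages 15-75, multi-site flat offsets, planted group gap
#' shifts mirroring the +1.0 / +0.5 / -0.8 kg/m2 pattern of the clinical
#' groups, and a gap-to-weight-change coupling of 0.3.
#'
#' @param grid_shape integer triple, voxels per axis.
#' @param voxel_size_mm isotropic voxel edge in mm.
#' @param n_per_group named counts for HC/SCZ/CHR/ROD.
#' @param sites named numeric vector: flat GMV offset per site.
#' @param bmi_range,age_range sampling intervals.
#' @param beta_bmi GMV decrease per effective-BMI unit along the BMI pattern.
#' @param beta_age GMV change per year along the age pattern.
#' @param beta_dx GMV decrease per unit disease load along the disease pattern.
#' @param anat_sd s.d. of the per-subject smooth anatomical field (GMV
#'   units); spreads the PCA spectrum the way real anatomy does.
#' @param group_shift named planted gap shift per group (kg/m2 equivalent).
#' @param gap_sd within-group s.d. of the planted gap (kg/m2).
#' @param overlap_fraction fraction of the disease-pattern support shared with
#'   the BMI pattern, in `[0, 1]`.
#' @param support_size voxels per planted pattern support.
#' @param noise_sd i.i.d. Gaussian voxel noise s.d. (GMV units).
#' @param dw_coupling target correlation between planted gap and 2-year
#'   weight change.
#' @param followup_rate length-2 probabilities of observed T1 / T2 weights.
#' @param seed integer; generation is a pure function of the spec + seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(16L, 16L, 16L),
                         voxel_size_mm = 3,
                         n_per_group = c(HC = 400L, SCZ = 150L, CHR = 150L, ROD = 150L),
                         sites = c(MUC = 0, OSLO = 0.04, TUR = -0.04),
                         bmi_range = c(18.5, 35),
                         age_range = c(15, 75),
                         beta_bmi = 0.14,
                         beta_age = -0.002,
                         beta_dx = 0.15,
                         anat_sd = 0.02,
                         group_shift = c(HC = 0, SCZ = 1.0, CHR = 0.5, ROD = -0.8),
                         gap_sd = 1.2,
                         overlap_fraction = 0.5,
                         support_size = 150L,
                         noise_sd = 0.04,
                         dw_coupling = 0.3,
                         followup_rate = c(0.8, 0.7),
                         seed = 1L) {
  if (any(n_per_group < 0)) stopf("n_per_group counts must be >= 0")
  bad <- setdiff(names(n_per_group), GROUP_LEVELS)
  if (length(bad)) stopf("unknown group label(s) in n_per_group: %s",
                         paste(bad, collapse = ", "))
  if (bmi_range[1] < 10 || bmi_range[2] > 60 || diff(bmi_range) <= 0)
    stopf("bmi_range must be an increasing interval inside [10, 60]")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stopf("overlap_fraction must be in [0, 1]")
  if (noise_sd <= 0) stopf("noise_sd must be > 0")
  if (length(sites) < 1L || is.null(names(sites))) stopf("sites must be named")
  structure(as.list(environment()), class = "phantom_spec")
}

# spherical brain mask on the phantom grid
phantom_mask <- function(spec) {
  d <- spec$grid_shape
  ctr <- (d + 1) / 2
  r <- min(d) / 2 - 1
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  inside <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <= r^2
  voxel_mask(array(inside, dim = d), voxel_size_mm = spec$voxel_size_mm)
}

# contiguous Gaussian-weighted blob: the `size` masked voxels nearest `center`
blob_weights <- function(mask, center, size, exclude = integer(0)) {
  d <- dim(mask$mask)
  idx <- arrayInd(mask$ordering, d)
  dist2 <- rowSums(sweep(idx, 2, center)^2)
  ord <- order(dist2, mask$ordering)
  ord <- ord[!ord %in% exclude]
  sel <- ord[seq_len(size)]
  w <- numeric(mask$n_features)
  sigma2 <- max(dist2[sel]) / 2 + 1e-9
  w[sel] <- exp(-dist2[sel] / sigma2)
  w / sqrt(sum(w^2))
}

#' Generate a phantom GMV cohort
#'
#' Each subject's masked GMV is
#' `template - (BMI + gap_true) * beta_bmi * w_bmi - dx_load * beta_dx * w_dx
#'  + age * beta_age * w_age + site_offset + noise`,
#' where `gap_true = group_shift[group] + N(0, gap_sd)`. Follow-up weights are
#' an affine function of the planted gap so that `cor(gap_true, dW2)`
#' converges to `dw_coupling`.
#'
#' @param spec `phantom_spec`.
#' @return object of class `gmv_cohort`: list with `spec`, `mask`
#'   (`voxel_mask`), `features` (`n x p` masked GMV matrix, canonical
#'   ordering), `table` (cohort data.frame), and `truth` (planted patterns,
#'   per-subject `gap_true`, per-site offsets).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  mask <- phantom_mask(spec)
  if (mask$n_features < 50L)
    stopf("grid too small: %d masked voxels (< 50)", mask$n_features)
  if (3L * spec$support_size > mask$n_features)
    stopf("grid too small for three supports of %d voxels in a %d-voxel mask",
          spec$support_size, mask$n_features)
  d <- spec$grid_shape
  ctr <- (d + 1) / 2
  r <- min(d) / 2 - 1

  with_seed(spec$seed, {
    # anatomy template: smoothed white noise, fixed per seed
    tpl_vol <- array(rnorm(prod(d)), dim = d)
    tpl_vol <- smooth_gmv(tpl_vol, fwhm_mm = 3 * spec$voxel_size_mm,
                          voxel_size_mm = spec$voxel_size_mm)
    tpl <- tpl_vol[mask$ordering]
    tpl <- 0.55 + 0.08 * (tpl - mean(tpl)) / sd(tpl)

    # planted supports: contiguous blobs at distinct centres
    c_bmi <- ctr + c(round(r / 2), 0, 0)
    c_dx  <- ctr + c(round(r / 4), round(r / 2), 0)
    c_age <- ctr - c(round(r / 2), round(r / 3), 0)
    w_bmi <- blob_weights(mask, c_bmi, spec$support_size)
    sup_bmi <- which(w_bmi != 0)
    n_ov <- round(spec$overlap_fraction * spec$support_size)
    # disease support: n_ov voxels from the BMI support nearest the disease
    # centre, remainder from outside it
    idx <- arrayInd(mask$ordering, d)
    dist2_dx <- rowSums(sweep(idx, 2, c_dx)^2)
    in_sup  <- sup_bmi[order(dist2_dx[sup_bmi], sup_bmi)][seq_len(n_ov)]
    out_cand <- setdiff(order(dist2_dx, mask$ordering), sup_bmi)
    sel_dx <- c(in_sup, out_cand[seq_len(spec$support_size - n_ov)])
    w_dx <- numeric(mask$n_features)
    sigma2 <- max(dist2_dx[sel_dx]) / 2 + 1e-9
    w_dx[sel_dx] <- exp(-dist2_dx[sel_dx] / sigma2)
    # Orthogonalize against the BMI pattern as seen at the analysis smoothing
    # scale (S'S w_bmi): the supports still overlap, so the binary maps do,
    # but disease load cannot masquerade as BMI in the smoothed feature space
    # the predictor operates on.
    h <- smooth_feature_matrix(
      smooth_feature_matrix(matrix(w_bmi, 1), mask, 2 * spec$voxel_size_mm),
      mask, 2 * spec$voxel_size_mm)[1, ]
    hs <- h[sel_dx]
    if (sum(hs^2) > 1e-12)
      w_dx[sel_dx] <- w_dx[sel_dx] -
        (sum(w_dx * h) / sum(hs^2)) * hs
    w_dx <- w_dx / sqrt(sum(w_dx^2))
    w_age <- blob_weights(mask, c_age, spec$support_size,
                          exclude = union(sup_bmi, sel_dx))

    groups <- rep(names(spec$n_per_group), times = spec$n_per_group)
    n <- length(groups)
    if (n < 1L) stopf("empty cohort: all group counts are zero")
    # round once at sampling time so the tabulated phenotype is exactly the
    # value that enters the image model
    bmi <- round(runif(n, spec$bmi_range[1], spec$bmi_range[2]), 2)
    age <- round(runif(n, spec$age_range[1], spec$age_range[2]), 1)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    site <- sample(names(spec$sites), n, replace = TRUE)
    gap_true <- spec$group_shift[groups] + rnorm(n, 0, spec$gap_sd)
    dx_base <- c(HC = 0, SCZ = 1, CHR = 0.5, ROD = 0.3)
    dx_load <- dx_base[groups] + ifelse(groups == "HC", 0, rnorm(n, 0, 0.25))

    p <- mask$n_features
    # per-subject smooth anatomical field: spreads the between-subject PCA
    # spectrum over many directions, as real anatomy does
    anat <- matrix(0, n, p)
    if (spec$anat_sd > 0) {
      dims <- spec$grid_shape
      sigma_vox <- 2 * FWHM_TO_SIGMA       # 2-voxel FWHM correlation length
      Sm <- lapply(1:3, function(ax) smooth_matrix_1d(dims[ax], sigma_vox))
      for (i in seq_len(n)) {
        v <- array(rnorm(prod(dims)), dim = dims)
        v <- apply_axis(apply_axis(apply_axis(v, 1, Sm[[1]]), 2, Sm[[2]]),
                        3, Sm[[3]])
        f <- v[mask$ordering]
        anat[i, ] <- spec$anat_sd * (f - mean(f)) / sd(f)
      }
    }
    noise <- matrix(rnorm(n * p, 0, spec$noise_sd), n, p)
    X <- matrix(tpl, n, p, byrow = TRUE) + anat -
      outer((bmi + gap_true) - mean(spec$bmi_range), spec$beta_bmi * w_bmi) -
      outer(dx_load, spec$beta_dx * w_dx) +
      outer(age - mean(spec$age_range), spec$beta_age * w_age) +
      spec$sites[site] + noise

    # longitudinal weights: dW2 correlated with the planted gap at dw_coupling
    height <- pmin(pmax(rnorm(n, 1.70, 0.09), 1.5), 2.0)
    weight_t0 <- round(bmi * height^2, 1)
    zg <- if (sd(gap_true) > 0) as.vector(scale(gap_true)) else numeric(n)
    # residualize the noise on the gap so the sample correlation equals the
    # coupling target exactly (up to weight rounding), not just in expectation
    ortho_noise <- function() {
      e <- rnorm(n)
      if (n > 2 && sd(zg) > 0) e <- resid(lm(e ~ zg))
      if (sd(e) > 0) e / sd(e) else e
    }
    s_dw <- 3
    rho2 <- spec$dw_coupling
    rho1 <- 0.7 * spec$dw_coupling
    dw2 <- s_dw * (rho2 * zg + sqrt(1 - rho2^2) * ortho_noise())
    dw1 <- s_dw * 0.6 * (rho1 * zg + sqrt(1 - rho1^2) * ortho_noise())
    has_t1 <- runif(n) < spec$followup_rate[1]
    has_t2 <- runif(n) < spec$followup_rate[2]
    weight_t1 <- ifelse(has_t1, round(weight_t0 + dw1, 1), NA_real_)
    weight_t2 <- ifelse(has_t2, round(weight_t0 + dw2, 1), NA_real_)

    ids <- sprintf("S%04d", seq_len(n))
    table <- data.frame(
      subject_id = ids, site = site, group = groups,
      split = ifelse(groups == "HC", NA_character_, "clinical"),
      age = age, sex = sex, bmi_measured = bmi,
      weight_t0 = weight_t0, weight_t1 = weight_t1, weight_t2 = weight_t2,
      exercise = as.integer(runif(n) < 0.5),
      somatic_history = as.integer(runif(n) < 0.3),
      tobacco = as.integer(runif(n) < 0.3),
      stringsAsFactors = FALSE
    )
    rownames(X) <- ids
    truth <- list(w_bmi = w_bmi, w_dx = w_dx, w_age = w_age,
                  support_bmi = sup_bmi, support_dx = sel_dx,
                  gap_true = setNames(as.numeric(gap_true), ids),
                  dx_load = setNames(as.numeric(dx_load), ids),
                  site_offset_true = spec$sites)
    structure(list(spec = spec, mask = mask, template = tpl,
                   features = X, table = table, truth = truth),
              class = "gmv_cohort")
  })
}

#' @export
print.gmv_cohort <- function(x, ...) {
  cat(sprintf("<gmv_cohort %d subjects x %d masked voxels (%s grid)>\n",
              nrow(x$features), x$mask$n_features,
              paste(dim(x$mask$mask), collapse = "x")))
  print(table(x$table$group))
  invisible(x)
}

#' Add clinical scores and medication flags to a cohort table
#'
#' Disease-group rows (SCZ/CHR/ROD) receive PANSS total, age at onset, illness
#' duration, hospitalizations, medication-naivety flags, a weight-gain
#' medication category and (SCZ only) chlorpromazine equivalents; HC rows keep
#' missing markers. Clinical severity can be correlated with the planted gap.
#'
#' @param table cohort data.frame with a `group` column.
#' @param seed integer seed.
#' @param gap_true optional named numeric (by subject_id); when present,
#'   PANSS is generated with correlation `coupling` to it.
#' @param coupling target gap-severity correlation in the disease groups.
#' @param prevalences named list: `weightgain_yes`, `weightgain_neutral`,
#'   `ap_naive`, `ad_naive` probabilities.
#' @return the table with clinical columns filled.
#' @export
clinical_fields <- function(table, seed = 1L, gap_true = NULL, coupling = 0.3,
                            prevalences = list(weightgain_yes = 0.5,
                                               weightgain_neutral = 0.15,
                                               ap_naive = 0.5, ad_naive = 0.5)) {
  if (!"group" %in% names(table)) stopf("table has no group column")
  n <- nrow(table)
  clin <- table$group != "HC"
  with_seed(seed, {
    table$panss_total <- NA_real_
    table$age_at_onset <- NA_real_
    table$illness_duration <- NA_real_
    table$n_hospitalizations <- NA_integer_
    table$antipsychotic_naive <- NA_integer_
    table$antidepressant_naive <- NA_integer_
    table$weightgain_med <- NA_character_
    table$cpz_equiv <- NA_real_
    if (any(clin)) {
      m <- sum(clin)
      z <- if (!is.null(gap_true)) {
        g <- gap_true[table$subject_id[clin]]
        as.vector(scale(g))
      } else rnorm(m)
      panss_mean <- c(SCZ = 52, CHR = 52, ROD = 48)[table$group[clin]]
      panss_sd <- c(SCZ = 25, CHR = 18, ROD = 14)[table$group[clin]]
      eff <- coupling * z + sqrt(max(0, 1 - coupling^2)) * rnorm(m)
      table$panss_total[clin] <- pmax(30, round(panss_mean + panss_sd * eff, 1))
      onset_lag <- pmax(0.5, stats::rexp(m, rate = 1 / 3))
      table$age_at_onset[clin] <- round(pmax(12, table$age[clin] - onset_lag), 1)
      table$illness_duration[clin] <-
        round(table$age[clin] - table$age_at_onset[clin], 1)
      table$n_hospitalizations[clin] <- rpois(m, 1.2)
      table$antipsychotic_naive[clin] <-
        as.integer(runif(m) < prevalences$ap_naive)
      table$antidepressant_naive[clin] <-
        as.integer(runif(m) < prevalences$ad_naive)
      u <- runif(m)
      table$weightgain_med[clin] <- ifelse(
        u < prevalences$weightgain_yes, "yes",
        ifelse(u < prevalences$weightgain_yes + prevalences$weightgain_neutral,
               "neutral_or_none", "unknown"))
      scz <- clin & table$group == "SCZ"
      if (any(scz))
        table$cpz_equiv[scz] <- round(stats::rlnorm(sum(scz), log(300), 0.6), 1)
    }
    table
  })
}

#' Write a phantom cohort to disk
#'
#' One NIfTI per subject, the brain mask, the cohort TSV, and the ground-truth
#' sidecar (JSON; planted patterns as vectors over masked voxels).
#'
#' @param cohort `gmv_cohort`.
#' @param dir output directory (created if needed).
#' @param gzip write `.nii.gz` (default) or plain `.nii`.
#' @return named list of written paths, invisibly.
#' @export
write_phantom <- function(cohort, dir, gzip = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  vs <- cohort$mask$voxel_size_mm
  img_paths <- character(nrow(cohort$features))
  for (i in seq_len(nrow(cohort$features))) {
    img <- vector_to_volume(cohort$features[i, ], cohort$mask)
    img_paths[i] <- file.path(dir, paste0(cohort$table$subject_id[i], ext))
    write_nifti(img$data, img_paths[i], affine = img$affine, voxel_size_mm = vs)
  }
  mask_path <- file.path(dir, paste0("mask", ext))
  write_nifti(array(as.double(cohort$mask$mask), dim = dim(cohort$mask$mask)),
              mask_path, affine = cohort$mask$affine, voxel_size_mm = vs)
  tsv_path <- file.path(dir, "cohort.tsv")
  write_cohort(cohort$table, tsv_path)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(w_bmi = cohort$truth$w_bmi, w_dx = cohort$truth$w_dx,
         gap_true = as.list(cohort$truth$gap_true),
         site_offset_true = as.list(cohort$truth$site_offset_true)),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(images = img_paths, mask = mask_path,
                 table = tsv_path, truth = truth_path))
}
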