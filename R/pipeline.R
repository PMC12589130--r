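# End-to-end orchestration: simulate -> design -> train -> predict -> gap ->
# maps -> spls -> outcomes -> report, with one seed namespace per stage
# derived from the master seed, per-stage output hashes in a manifest, and
# file-backed caching so later stages can rerun alone.

PIPELINE_STAGES <- c("simulate", "design", "train", "predict", "gap",
                     "maps", "spls", "outcomes", "report")
STAGE_DEPS <- list(
  simulate = character(0), design = "simulate", train = "design",
  predict = "train", gap = "predict", maps = "train",
  spls = c("gap", "maps"), outcomes = "gap",
  report = c("gap", "maps", "outcomes"))

#' Default pipeline configuration
#'
#' Desk-scale settings: a 16^3 phantom, discovery target of half the HCs,
#' reduced hyperparameter grid and 2x5 / 2x3 nested CV, modest permutation
#' and bootstrap counts. Every stochastic stage draws its seed from `seed`.
#'
#' @param seed master seed.
#' @param outdir output directory.
#' @return nested list of class `run_config`; round-trips through JSON via
#'   [write_config()] / [read_config()].
#' @export
default_config <- function(seed = 1L, outdir = tempfile("bmigap_run_")) {
  structure(list(
    seed = as.integer(seed), outdir = outdir,
    stages = PIPELINE_STAGES,
    phantom = list(),                        # overrides for phantom_spec()
    design = list(target_n = NULL, width = 0.5),
    train = list(grid = "small", outer_k = 5, outer_p = 2,
                 inner_k = 3, inner_p = 2),
    maps = list(alpha = 0.05),
    spls = list(groups = c("SCZ", "CHR", "ROD"), max_lv = 2,
                n_perm = 99, n_boot = 100),
    outcomes = list(threshold = 7, horizon = 2, C_grid = c(0.25, 1, 4))
  ), class = "run_config")
}

#' Write / read a pipeline configuration as JSON
#' @param config `run_config`.
#' @param path JSON path.
#' @return `path` / the configuration.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config(seed = cfg$seed %||% 1L,
                         outdir = cfg$outdir %||% tempfile("bmigap_run_"))
  out <- modifyList(unclass(base), cfg)
  structure(out, class = "run_config")
}

stage_seed <- function(config, stage) derive_seed(config$seed, stage)

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order; artifacts are cached in
#' `outdir/state.rds` so a later partial rerun can resume, and a manifest
#' (stage, content hash, outputs) is written to `outdir/manifest.json`.
#' Rerunning with an identical configuration reproduces identical numeric
#' outputs.
#'
#' @param config `run_config` (see [default_config()]).
#' @return the manifest list, invisibly; artifacts stay in
#'   `attr(manifest, "state")`.
#' @export
run_pipeline <- function(config = default_config()) {
  stages <- intersect(PIPELINE_STAGES, config$stages)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  state_path <- file.path(config$outdir, "state.rds")
  st <- if (file.exists(state_path)) readRDS(state_path) else list()
  for (s in stages) {
    earlier <- stages[seq_len(match(s, stages) - 1L)]
    miss <- setdiff(STAGE_DEPS[[s]], union(names(st), earlier))
    if (length(miss))
      stopf("stage '%s' requires stage(s) %s to run first", s,
            paste(miss, collapse = ", "))
  }
  manifest <- list(config_hash = content_hash(unclass(config)), stages = list())

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible())
    st[[name]] <<- fun(stage_seed(config, name))
    saveRDS(st, state_path)
    manifest$stages[[name]] <<- list(hash = content_hash(st[[name]]))
  }

  run_stage("simulate", function(seed) {
    args <- config$phantom
    args$seed <- seed
    spec <- do.call(phantom_spec, args)
    cohort <- generate_cohort(spec)
    cohort$table <- clinical_fields(cohort$table, seed = derive_seed(seed, 2L),
                                    gap_true = cohort$truth$gap_true)
    cohort
  })

  run_stage("design", function(seed) {
    cohort <- st$simulate
    hc <- cohort$table[cohort$table$group == "HC", ]
    scheme <- make_bmi_bins(cohort$spec$bmi_range[1], cohort$spec$bmi_range[2],
                            config$design$width)
    target <- config$design$target_n %||% floor(nrow(hc) / 2)
    sel <- stratified_select(hc, scheme, target, seed = seed)
    cohort$table <- apply_selection(cohort$table, sel)
    st$simulate <<- cohort
    list(scheme = scheme, selection = sel)
  })

  run_stage("train", function(seed) {
    cohort <- st$simulate
    grid_bmi <- if (identical(config$train$grid, "default"))
      default_grid("bmi") else small_grid("bmi")
    grid_dx <- if (identical(config$train$grid, "default"))
      default_grid("dx") else small_grid("dx")
    disc <- cohort$table$subject_id[cohort$table$split %in% "discovery"]
    tr <- config$train
    ens_bmi <- train_normative(cohort$features, cohort$table, cohort$mask,
                               ids = disc, task = "bmi", grid = grid_bmi,
                               outer_k = tr$outer_k, outer_p = tr$outer_p,
                               inner_k = tr$inner_k, inner_p = tr$inner_p,
                               seed = derive_seed(seed, 1L))
    dx_ids <- c(disc, cohort$table$subject_id[cohort$table$group == "SCZ"])
    ens_dx <- train_normative(cohort$features, cohort$table, cohort$mask,
                              ids = dx_ids, task = "dx", grid = grid_dx,
                              outer_k = tr$outer_k, outer_p = tr$outer_p,
                              inner_k = tr$inner_k, inner_p = tr$inner_p,
                              seed = derive_seed(seed, 2L), pos_label = "SCZ")
    list(bmi = ens_bmi, dx = ens_dx)
  })

  run_stage("predict", function(seed) {
    cohort <- st$simulate
    list(bmi = predict_ensemble(st$train$bmi, cohort$features,
                                cohort$table, cohort$mask),
         dx = predict_ensemble(st$train$dx, cohort$features,
                               cohort$table, cohort$mask))
  })

  run_stage("gap", function(seed) {
    cohort <- st$simulate
    gp <- compute_gap(st$predict$bmi, cohort$table)
    disc <- gp[gp$subject_id %in% st$train$bmi$ids, ]
    corr <- fit_bias_correction(disc)
    gp <- apply_bias_correction(gp, corr)
    gaps <- setNames(gp$gap_corrected, gp$subject_id)
    labels <- ifelse(cohort$table$group == "HC",
                     cohort$table$split, cohort$table$group)
    tests <- group_tests(gaps[cohort$table$subject_id],
                         labels, reference = "discovery")
    meds <- medication_contrasts(gaps, cohort$table)
    cpz <- tryCatch(dosage_correlation(gaps, cohort$table),
                    error = function(e) NULL)
    list(result = gp, correction = corr, gaps = gaps,
         group_tests = tests, medication = meds, cpz = cpz)
  })

  run_stage("maps", function(seed) {
    alpha <- config$maps$alpha
    mk <- function(ens) {
      W <- ensemble_weights(ens)
      cvr <- cvr_map(W)
      sgn <- sign_consistency_map(W, alpha = alpha)
      thr <- threshold_and_binarize(cvr, sgn)
      list(cvr = cvr, sign = sgn, binary = thr$binary,
           cvr_thresholded = thr$cvr_thresholded)
    }
    m_bmi <- mk(st$train$bmi)
    m_dx <- mk(st$train$dx)
    ov <- overlap_maps(m_bmi$binary, m_dx$binary)
    list(bmi = m_bmi, dx = m_dx, overlap = ov)
  })

  run_stage("spls", function(seed) {
    cohort <- st$simulate
    dx_scores <- setNames(st$predict$dx$prediction, st$predict$dx$subject_id)
    cm <- build_clinical_matrix(cohort$table, st$gap$gaps, dx_scores,
                                groups = config$spls$groups)
    ov_idx <- which(st$maps$overlap$overlap$values != 0)
    if (length(ov_idx) < 2L) {
      message("spls: overlap has < 2 voxels; falling back to the BMI binary map")
      ov_idx <- which(st$maps$bmi$binary$values != 0)
    }
    if (length(ov_idx) < 2L) {
      # few CV models make the sign maps conservative; keep the pipeline
      # runnable on the most reliable voxels of the BMI map
      message("spls: binary map empty; using the 50 largest-|CVR| voxels")
      ov_idx <- order(-abs(st$maps$bmi$cvr$values))[seq_len(50)]
    }
    Y <- cohort$features[match(cm$ids, rownames(cohort$features)), ov_idx,
                         drop = FALSE]
    fit <- spls_fit(cm$Z, Y, max_lv = config$spls$max_lv)
    perm <- lv_permutation_test(fit, n_perm = config$spls$n_perm, seed = seed)
    boot <- bootstrap_ratios(fit, lv = 1L, n_boot = config$spls$n_boot,
                             seed = derive_seed(seed, 2L))
    list(clinical = cm, overlap_voxels = ov_idx, fit = fit,
         permutation = perm, bootstrap = boot)
  })

  run_stage("outcomes", function(seed) {
    cohort <- st$simulate
    wct <- compute_weight_change(cohort$table)
    strat <- stratified_correlations(st$gap$gaps, wct, cohort$table)
    oc <- config$outcomes
    tr <- config$train
    run_cls <- function(with_bmigap)
      weight_gain_classifier(st$gap$gaps, wct, cohort$table,
                             threshold = oc$threshold, horizon = oc$horizon,
                             with_bmigap = with_bmigap,
                             outer_k = tr$outer_k, outer_p = tr$outer_p,
                             inner_k = tr$inner_k, inner_p = tr$inner_p,
                             C_grid = oc$C_grid, seed = seed)
    cls_with <- run_cls(TRUE)
    cls_without <- run_cls(FALSE)
    cmp <- compare_models(cls_with$fold_bac, cls_without$fold_bac)
    list(wct = wct, correlations = strat, with_bmigap = cls_with,
         without_bmigap = cls_without, comparison = cmp)
  })

  run_stage("report", function(seed) {
    out <- config$outdir
    cohort <- st$simulate
    write_cohort(cohort$table, file.path(out, "cohort.tsv"))
    write_cohort(as.data.frame(st$gap$result), file.path(out, "bmigap.tsv"))
    write_stat_map(st$maps$bmi$cvr_thresholded, cohort$mask,
                   file.path(out, "bmi_cvr_thresholded.nii.gz"))
    write_stat_map(st$maps$overlap$overlap, cohort$mask,
                   file.path(out, "overlap.nii.gz"))
    write_cohort(st$outcomes$correlations, file.path(out, "correlations.tsv"))
    summary <- list(
      n = nrow(cohort$table),
      discovery_metrics = regression_metrics(
        st$train$bmi$oof,
        cohort$table$bmi_measured[match(st$train$bmi$ids,
                                        cohort$table$subject_id)]),
      anova = st$gap$group_tests$anova,
      overlap = st$maps$overlap$stats,
      weight_gain = list(with = st$outcomes$with_bmigap$bac,
                         without = st$outcomes$without_bmigap$bac,
                         comparison = st$outcomes$comparison))
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    summary
  })

  manifest$completed <- names(manifest$stages)
  jsonlite::write_json(list(config_hash = manifest$config_hash,
                            stages = lapply(manifest$stages, `[`, "hash"),
                            completed = manifest$completed),
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE)
  attr(manifest, "state") <- st
  invisible(manifest)
}
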