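# Shared fixtures, memoized so expensive cohorts/ensembles are built once per
# test run. Everything is generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small, fast phantom for module-level tests (12^3 grid, ~460 masked voxels)
tiny_spec <- function(seed = 11, ...) {
  args <- list(grid_shape = c(12L, 12L, 12L),
               n_per_group = c(HC = 60L, SCZ = 20L, CHR = 20L, ROD = 20L),
               support_size = 60L, seed = seed)
  do.call(phantom_spec, modifyList(args, list(...)))
}

tiny_cohort <- function() memo("tiny_cohort", generate_cohort(tiny_spec()))

# the default stated world used by the acceptance recovery suite
accept_cohort <- function() memo("accept_cohort", {
  co <- generate_cohort(phantom_spec(seed = 11))
  co$table <- clinical_fields(co$table, seed = 12,
                              gap_true = co$truth$gap_true)
  hc <- co$table[co$table$group == "HC", ]
  sel <- stratified_select(hc, make_bmi_bins(18.5, 35, 0.5), 200, seed = 2)
  co$table <- apply_selection(co$table, sel)
  co
})

accept_ensemble <- function() memo("accept_ensemble", {
  co <- accept_cohort()
  disc <- co$table$subject_id[co$table$split %in% "discovery"]
  train_normative(co$features, co$table, co$mask, ids = disc, task = "bmi",
                  grid = small_grid("bmi"), outer_k = 5, outer_p = 2,
                  inner_k = 3, inner_p = 2, seed = 3)
})

accept_predictions <- function() memo("accept_predictions", {
  co <- accept_cohort()
  predict_ensemble(accept_ensemble(), co$features, co$table, co$mask)
})

accept_gaps <- function() memo("accept_gaps", {
  co <- accept_cohort()
  gp <- compute_gap(accept_predictions(), co$table)
  disc <- gp[gp$subject_id %in% accept_ensemble()$ids, ]
  apply_bias_correction(gp, fit_bias_correction(disc))
})
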