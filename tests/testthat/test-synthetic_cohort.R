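# Planted-structure guarantees of the phantom generator.

test_that("generation is a pure function of spec + seed", {
  a <- generate_cohort(tiny_spec())
  b <- generate_cohort(tiny_spec())
  expect_identical(a$features, b$features)
  expect_identical(a$table, b$table)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(tiny_spec(seed = 12))
  expect_false(identical(a$features, c2$features))
})

test_that("spec validation catches bad inputs", {
  expect_error(phantom_spec(bmi_range = c(5, 35)), "bmi_range")
  expect_error(phantom_spec(overlap_fraction = 1.2), "overlap_fraction")
  expect_error(phantom_spec(noise_sd = 0), "noise_sd")
  expect_error(phantom_spec(n_per_group = c(HC = 5, XX = 2)), "unknown group")
  expect_error(generate_cohort(phantom_spec(grid_shape = c(6L, 6L, 6L),
                                            n_per_group = c(HC = 4L))),
               "too small")
})

test_that("noise-free limit: subjects differing only in BMI differ by the planted pattern", {
  spec <- phantom_spec(grid_shape = c(12L, 12L, 12L), support_size = 60L,
                       n_per_group = c(HC = 6L),
                       sites = c(MUC = 0), age_range = c(30, 30),
                       group_shift = c(HC = 0), gap_sd = 0,
                       noise_sd = 1e-12, anat_sd = 0, seed = 5)
  co <- generate_cohort(spec)
  dbmi <- co$table$bmi_measured[1] - co$table$bmi_measured[2]
  diff <- co$features[1, ] - co$features[2, ]
  expect_equal(diff, -dbmi * spec$beta_bmi * co$truth$w_bmi,
               tolerance = 1e-6)
})

test_that("planted supports respect size, overlap, and unit norm", {
  co <- tiny_cohort()
  tr <- co$truth
  sp <- co$spec
  expect_equal(sqrt(sum(tr$w_bmi^2)), 1, tolerance = 1e-9)
  expect_equal(sqrt(sum(tr$w_dx^2)), 1, tolerance = 1e-9)
  expect_equal(length(tr$support_dx), sp$support_size)
  expect_equal(length(intersect(tr$support_bmi, tr$support_dx)),
               round(sp$overlap_fraction * length(tr$support_dx)))
})

test_that("gap / weight-change coupling converges to dw_coupling", {
  # Monte-Carlo check at the stated n
  spec <- phantom_spec(grid_shape = c(10L, 10L, 10L), support_size = 30L,
                       n_per_group = c(HC = 600L), dw_coupling = 0.4,
                       followup_rate = c(1, 1), seed = 21)
  co <- generate_cohort(spec)
  dw2 <- co$table$weight_t2 - co$table$weight_t0
  expect_lt(abs(cor(co$truth$gap_true, dw2) - 0.4), 0.1)
  # invariant at n = 2000, tolerance 0.05
  spec2 <- phantom_spec(grid_shape = c(10L, 10L, 10L), support_size = 30L,
                        n_per_group = c(HC = 2000L), dw_coupling = 0.3,
                        followup_rate = c(1, 1), seed = 22)
  co2 <- generate_cohort(spec2)
  dw2b <- co2$table$weight_t2 - co2$table$weight_t0
  expect_lt(abs(cor(co2$truth$gap_true, dw2b) - 0.3), 0.05)
})

test_that("emulated study counts are honoured", {
  # discovery + validation + external HCs and the three clinical groups
  spec <- phantom_spec(grid_shape = c(10L, 10L, 10L), support_size = 30L,
                       n_per_group = c(HC = 770L + 734L + 536L, SCZ = 146L,
                                       CHR = 213L, ROD = 200L), seed = 3)
  co <- generate_cohort(spec)
  counts <- table(co$table$group)
  expect_equal(unname(counts[c("HC", "SCZ", "CHR", "ROD")]),
               c(2040L, 146L, 213L, 200L), ignore_attr = TRUE)
})

test_that("planted BMI effect is identifiable by OLS on the pattern projection", {
  spec <- phantom_spec(grid_shape = c(12L, 12L, 12L), support_size = 60L,
                       n_per_group = c(HC = 250L), sites = c(MUC = 0),
                       group_shift = c(HC = 0), gap_sd = 0,
                       noise_sd = 0.01, seed = 9)
  co <- generate_cohort(spec)
  proj <- drop(co$features %*% co$truth$w_bmi)
  slope <- coef(lm(proj ~ co$table$bmi_measured))[2]
  expect_lt(abs(-slope - spec$beta_bmi) / spec$beta_bmi, 0.05)
})

test_that("clinical fields follow the stated missingness and prevalences", {
  co <- tiny_cohort()
  tab <- clinical_fields(co$table, seed = 7, gap_true = co$truth$gap_true)
  hc <- tab$group == "HC"
  expect_true(all(is.na(tab$panss_total[hc])))
  expect_true(all(is.na(tab$weightgain_med[hc])))
  expect_true(all(!is.na(tab$panss_total[!hc])))
  expect_true(all(tab$illness_duration[!hc] >= 0))
  # binomial CI at prevalence 0.5, n = 200
  spec <- phantom_spec(grid_shape = c(10L, 10L, 10L), support_size = 30L,
                       n_per_group = c(HC = 0L, CHR = 200L), seed = 31)
  co2 <- generate_cohort(spec)
  tab2 <- clinical_fields(co2$table, seed = 8,
                          prevalences = list(weightgain_yes = 0.3,
                                             weightgain_neutral = 0.2,
                                             ap_naive = 0.5, ad_naive = 0.5))
  prev <- mean(tab2$antipsychotic_naive == 1)
  expect_gte(prev, 0.4); expect_lte(prev, 0.6)
  # zero coupling: severity uncorrelated with the planted gap
  tab0 <- clinical_fields(co2$table, seed = 9, gap_true = co2$truth$gap_true,
                          coupling = 0)
  r0 <- cor(tab0$panss_total, co2$truth$gap_true[tab0$subject_id])
  expect_lt(abs(r0), 2 / sqrt(nrow(tab0)))
})

test_that("write_phantom exports images readable back to the same features", {
  spec <- phantom_spec(grid_shape = c(8L, 8L, 8L), support_size = 20L,
                       n_per_group = c(HC = 4L), seed = 2)
  co <- generate_cohort(spec)
  dir <- tempfile()
  paths <- write_phantom(co, dir)
  X <- read_gmv_set(paths$images, co$mask)
  expect_lt(max(abs(X - co$features)), 1e-5)   # float32 storage
  tab <- load_cohort(paths$table)
  expect_equal(tab$subject_id, co$table$subject_id)
  unlink(dir, recursive = TRUE)
})
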