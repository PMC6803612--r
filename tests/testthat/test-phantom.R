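test_that("zero irregularity yields a digital ball with zero central-slice concavity", {
  m <- generate_lesion_mask(c(24, 24, 24), c(2, 2, 2), radius_mm = 10, irregularity = 0)
  # exact digital ball: voxel included iff its centre is within the radius
  ctr <- (c(24, 24, 24) - 1) * 2 / 2
  co <- lapply(1:3, function(k) (0:23) * 2 - ctr[k])
  d2 <- outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`)
  expect_identical(m, d2 <= 10^2)
  z <- which.max(apply(m, 3, sum))
  morph <- compute_morphology(m[, , z])
  expect_equal(unname(morph["concavity"]), 0)
})

test_that("central-slice concavity magnitude grows with the irregularity amplitude", {
  n_ge <- 0
  mean_hi <- c(); mean_lo <- c()
  for (s in 1:20) {
    hi <- generate_lesion_mask(c(26, 26, 26), c(2, 2, 2), 9, irregularity = 0.35, seed = 100 + s)
    lo <- generate_lesion_mask(c(26, 26, 26), c(2, 2, 2), 9, irregularity = 0.10, seed = 100 + s)
    chi <- compute_morphology(hi[, , which.max(apply(hi, 3, sum))])["concavity"]
    clo <- compute_morphology(lo[, , which.max(apply(lo, 3, sum))])["concavity"]
    mean_hi <- c(mean_hi, abs(chi)); mean_lo <- c(mean_lo, abs(clo))
    if (abs(chi) >= abs(clo) - 1e-12) n_ge <- n_ge + 1
  }
  expect_gt(mean(mean_hi), mean(mean_lo))
  expect_gte(n_ge, 17)  # same-seed ordering can be broken only by digitization
})

test_that("lesion masks are a single connected component", {
  for (s in 1:8) {
    m <- generate_lesion_mask(c(26, 26, 26), c(2, 2, 2), runif(1, 6, 10),
                              irregularity = runif(1, 0, 0.4), seed = 400 + s)
    expect_equal(petradiomics:::count_components3(m), 1L)
  }
})

test_that("oversized lesions are rejected as configuration errors", {
  expect_error(generate_lesion_mask(c(16, 16, 16), c(2, 2, 2), radius_mm = 15),
               "configuration error")
  expect_error(phantom_config(grid_shape = c(10, 10, 10), lesion_radius_range = c(8, 14)),
               "configuration error")
})

test_that("zero heterogeneity and zero noise give a flat lesion with zero GLCM contrast", {
  cp <- default_class_params()
  cp$mutant$het_amp <- 0; cp$mutant$het_amp_sd <- 0; cp$mutant$suv_sd <- 0
  cfg <- tiny_phantom_config(seed = 3, class_params = cp, pet_noise_sd = 0)
  mask <- generate_lesion_mask(cfg$grid_shape, cfg$voxel_spacing, 8, seed = 5)
  # bypass the per-patient amplitude redraw: force the degenerate parameters
  params <- list(radius_mm = 8, boundary_amp = 0, suv_mean = 6.5, het_amp = 0,
                 corr_len_mm = 4, ct_hu_mean = 40, ct_texture_sd = 10,
                 ct_corr_len_mm = 4, axis_ratio = c(1, 1, 1))
  vp <- synthesize_pet_ct(mask, cfg, "mutant", 1, params = params)
  expect_true(all(abs(vp$pet[mask] - 6.5) < 1e-12))
  z <- which.max(apply(mask, 3, sum))
  q <- quantize_roi(vp$pet[, , z], mask[, , z], 16)
  glcm <- compute_glcm_features(q)
  expect_equal(unname(glcm["contrast"]), 0)
  expect_equal(unname(glcm["homogeneity"]), 1)
})

test_that("increasing heterogeneity amplitude does not decrease mean lesion GLCM contrast", {
  contrasts <- function(amp) {
    vapply(1:20, function(s) {
      cfg <- tiny_phantom_config(seed = 1000 + s)
      mask <- generate_lesion_mask(cfg$grid_shape, cfg$voxel_spacing, 8, seed = 2000 + s)
      params <- list(radius_mm = 8, boundary_amp = 0, suv_mean = 7, het_amp = amp,
                     corr_len_mm = 4, ct_hu_mean = 40, ct_texture_sd = 10,
                     ct_corr_len_mm = 4, axis_ratio = c(1, 1, 1))
      vp <- synthesize_pet_ct(mask, cfg, "mutant", s, params = params)
      z <- which.max(apply(mask, 3, sum))
      q <- quantize_roi(vp$pet[, , z], mask[, , z], 16)
      unname(compute_glcm_features(q)["contrast"])
    }, numeric(1))
  }
  expect_gte(mean(contrasts(0.45)), mean(contrasts(0.15)))
})

test_that("volume synthesis is bit-identical under a fixed seed", {
  cfg <- tiny_phantom_config(seed = 9)
  mask <- generate_lesion_mask(cfg$grid_shape, cfg$voxel_spacing, 7, seed = 77)
  v1 <- synthesize_pet_ct(mask, cfg, "wild", 4)
  v2 <- synthesize_pet_ct(mask, cfg, "wild", 4)
  expect_identical(v1$pet, v2$pet)
  expect_identical(v1$ct, v2$ct)
  c1 <- generate_cohort(tiny_phantom_config(n_mutant = 2, n_wild = 2, seed = 13))
  c2 <- generate_cohort(tiny_phantom_config(n_mutant = 2, n_wild = 2, seed = 13))
  expect_identical(c1$volumes[[3]]$pet, c2$volumes[[3]]$pet)
  expect_identical(c1$cohort_table, c2$cohort_table)
})

test_that("cohort table reproduces the target marginals", {
  cfg <- phantom_config(n_mutant = 64, n_wild = 51, seed = 2)
  tab <- simulate_cohort_table(cfg)
  expect_equal(nrow(tab), 115)
  expect_equal(sum(tab$egfr_label == "mutant"), 64)
  expect_false(anyDuplicated(tab$patient_id) > 0)
  expect_true(all(tab$age >= 28 & tab$age <= 77))

  big <- phantom_config(n_mutant = 2000, n_wild = 2000, seed = 4)
  bt <- simulate_cohort_table(big)
  expect_lt(abs(median(bt$age) - 63), 3)
  # per-class smoking prevalence within 3 binomial sd of the configured rates
  for (cl in c("mutant", "wild")) {
    p0 <- big$smoking_prevalence[[cl]]
    phat <- mean(bt$smoking[bt$egfr_label == cl] == "yes")
    expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / 2000))
  }
  p_early <- mean(bt$stage == "I-II")
  expect_lt(abs(p_early - 0.78), 3 * sqrt(0.78 * 0.22 / 4000) + 0.01)
})

test_that("classes separate on lesion SUV mean in the configured direction", {
  coh <- cached_cohort_features()
  suv <- coh$features$suv_mean
  lab <- coh$labels
  # mutant lesions are configured with the lower uptake level
  w <- wilcoxon_rank_sum(suv[lab == "mutant"], suv[lab == "wild"])
  expect_lt(median(suv[lab == "mutant"]), median(suv[lab == "wild"]))
  r <- roc_auc(suv, lab, direction = "auto")
  expect_gt(r$auc, 0.5)
})

test_that("SUV conversion path is exercised by the back-filled metadata", {
  coh <- cached_cohort_features()$cohort
  vp <- coh$volumes[[1]]
  activity <- vp$pet * vp$meta$injected_dose_mCi / vp$meta$body_weight_g
  expect_equal(activity_to_suv(activity, vp$meta$injected_dose_mCi, vp$meta$body_weight_g),
               vp$pet)
})
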