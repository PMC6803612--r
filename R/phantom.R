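#' Configuration for the synthetic PET/CT phantom cohort
#'
#' Defines a two-class cohort (`mutant` vs `wild`) of lesion-bearing PET/CT
#' volumes. Class contrast is placed predominantly in the PET channel: the
#' mutant class has a lower lesion SUV level, a higher and finer-grained
#' spatial heterogeneity, and a more irregular lesion boundary; the CT channel
#' carries a weaker density/texture contrast. Clinical covariates are drawn
#' from the cohort marginals the analysis emulates (median age 63, range
#' 28--77; smoking prevalence 23.4% / 41.2% per class; ~78% stage I--II).
#'
#' @param n_mutant,n_wild Patients per class (default 64 / 51).
#' @param grid_shape Voxels per axis (length 3).
#' @param voxel_spacing mm per axis (length 3).
#' @param lesion_radius_range Lesion radius range in mm (uniform draw).
#' @param class_params Named list with elements `mutant` and `wild`, each a
#'   list with: `suv_mean` (lesion SUV level), `suv_sd` (between-patient sd of
#'   that level), `het_amp` / `het_amp_sd` (relative PET heterogeneity
#'   amplitude and its between-patient sd), `corr_len_mm` (texture correlation
#'   length), `boundary_amp` / `boundary_amp_sd` (radial boundary
#'   irregularity), `ct_hu_mean` / `ct_hu_sd` (lesion HU level and
#'   between-patient sd), `ct_texture_sd` / `ct_texture_sd_sd` (HU texture
#'   amplitude), `ct_corr_len_mm`.
#' @param pet_occult_rate Fraction of lesions (either class) that are
#'   metabolically non-discriminative: their PET-side parameters (uptake
#'   level, heterogeneity, correlation length, boundary irregularity) are
#'   drawn from the across-class pooled means while their CT density
#'   phenotype carries an amplified class contrast
#'   (see `ct_occult_params`). This encodes the complementarity of the two
#'   modalities: a minority subgroup is separable on CT but not on PET.
#' @param ct_occult_params Per-class CT parameters (`ct_hu_mean`,
#'   `ct_texture_sd`, `ct_corr_len_mm`) used for PET-occult lesions.
#' @param background_suv_mean,background_suv_noise_sd Background PET level.
#' @param pet_noise_sd Additive white noise on lesion PET voxels (SUV).
#' @param ct_background_hu,ct_background_noise_sd Background CT level (lung).
#' @param smoking_prevalence Length-2 vector `c(mutant, wild)`.
#' @param seed Integer master seed; every volume and table draw is a
#'   deterministic function of `(seed, patient index)`.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_mutant = 64L, n_wild = 51L,
                           grid_shape = c(44L, 44L, 44L),
                           voxel_spacing = c(2, 2, 2),
                           lesion_radius_range = c(8, 14),
                           class_params = default_class_params(),
                           pet_occult_rate = 0.25,
                           ct_occult_params = default_ct_occult_params(),
                           background_suv_mean = 0.4,
                           background_suv_noise_sd = 0.05,
                           pet_noise_sd = 0.15,
                           ct_background_hu = -750,
                           ct_background_noise_sd = 20,
                           smoking_prevalence = c(mutant = 0.234, wild = 0.412),
                           seed = 1L) {
  cfg <- list(n_mutant = as.integer(n_mutant), n_wild = as.integer(n_wild),
              grid_shape = as.integer(grid_shape), voxel_spacing = as.numeric(voxel_spacing),
              lesion_radius_range = as.numeric(lesion_radius_range),
              class_params = class_params,
              pet_occult_rate = pet_occult_rate,
              ct_occult_params = ct_occult_params,
              background_suv_mean = background_suv_mean,
              background_suv_noise_sd = background_suv_noise_sd,
              pet_noise_sd = pet_noise_sd,
              ct_background_hu = ct_background_hu,
              ct_background_noise_sd = ct_background_noise_sd,
              smoking_prevalence = smoking_prevalence,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

#' Default per-class lesion parameters
#'
#' The defaults encode the qualitative class differences the analysis targets
#' (mutant lesions: lower uptake, higher/finer heterogeneity, more irregular
#' boundary; CT contrast weaker than PET), scaled so that end-to-end
#' discrimination is non-trivial rather than saturated.
#'
#' @return Named list with `mutant` and `wild` parameter lists.
#' @export
default_class_params <- function() {
  list(
    mutant = list(suv_mean = 6.5, suv_sd = 2.2,
                  het_amp = 0.23, het_amp_sd = 0.05,
                  corr_len_mm = 4.3, corr_len_sd = 1.3,
                  boundary_amp = 0.22, boundary_amp_sd = 0.07,
                  ct_hu_mean = 40, ct_hu_sd = 15,
                  ct_texture_sd = 40, ct_texture_sd_sd = 12,
                  ct_corr_len_mm = 5.4, ct_corr_len_sd = 1.3),
    wild = list(suv_mean = 8.5, suv_sd = 2.2,
                het_amp = 0.13, het_amp_sd = 0.05,
                corr_len_mm = 6.5, corr_len_sd = 1.3,
                boundary_amp = 0.10, boundary_amp_sd = 0.07,
                ct_hu_mean = 37, ct_hu_sd = 15,
                ct_texture_sd = 37, ct_texture_sd_sd = 12,
                ct_corr_len_mm = 5.4, ct_corr_len_sd = 1.3)
  )
}

#' CT parameters of PET-occult lesions
#'
#' Class-specific CT levels used for the minority of lesions whose PET
#' phenotype carries no class contrast; the density contrast is amplified so
#' that these patients are separable on CT alone.
#'
#' @return Named list with `mutant` and `wild` CT parameter lists.
#' @export
default_ct_occult_params <- function() {
  list(mutant = list(ct_hu_mean = 48, ct_texture_sd = 48, ct_corr_len_mm = 4.6),
       wild = list(ct_hu_mean = 29, ct_texture_sd = 29, ct_corr_len_mm = 6.2))
}

validate_phantom_config <- function(cfg) {
  if (cfg$n_mutant < 2L || cfg$n_wild < 2L) stopf("need at least 2 patients per class")
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 8L)) stopf("grid_shape must be 3 values >= 8")
  if (any(cfg$voxel_spacing <= 0)) stopf("voxel_spacing must be positive")
  if (diff(cfg$lesion_radius_range) < 0 || cfg$lesion_radius_range[1] <= 0)
    stopf("lesion_radius_range must be increasing and positive")
  for (cl in c("mutant", "wild")) {
    p <- cfg$class_params[[cl]]
    if (is.null(p)) stopf("class_params must contain '%s'", cl)
    if (p$het_amp < 0 || p$boundary_amp < 0 || p$ct_texture_sd < 0)
      stopf("amplitudes must be >= 0")
  }
  # the largest perturbed lesion (radius cap factor 1.8, see generate_lesion_mask)
  # must fit strictly inside the grid
  max_r <- cfg$lesion_radius_range[2] * 1.8
  half_extent <- min(cfg$grid_shape * cfg$voxel_spacing) / 2
  if (max_r >= half_extent)
    stopf("configuration error: largest lesion (%.1f mm) does not fit in the grid (half-extent %.1f mm)",
          max_r, half_extent)
  invisible(cfg)
}

# Low-order direction harmonics (Cartesian polynomials of the unit vector)
# used for the radial boundary perturbation.
.dir_harmonics <- function(u) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  cbind(x * y, y * z, x * z, x^2 - y^2, 3 * z^2 - 1,
        x * y * z, x * (x^2 - 3 * y^2), z * (5 * z^2 - 3))
}

#' Generate a synthetic lesion mask
#'
#' A star-convex lesion: an ellipsoid whose radius is modulated along each
#' direction by a smooth random combination of low-order direction harmonics,
#' scaled by `irregularity`. Amplitude 0 yields a digitized ellipsoid (zero
#' concavity on the central slice); larger amplitudes yield increasingly
#' concave boundaries. The result is guaranteed to be a single 26-connected
#' component.
#'
#' @param grid_shape Integer length-3 vector of voxels per axis.
#' @param spacing Voxel spacing in mm (length 3).
#' @param center_mm Lesion centre in world mm (default grid centre).
#' @param radius_mm Mean lesion radius in mm.
#' @param irregularity Boundary irregularity amplitude (>= 0); the radial
#'   multiplier is clamped to the interval 0.4 to 1.8.
#' @param axis_ratio Length-3 relative ellipsoid semi-axes (default isotropic).
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @return Logical 3-d array.
#' @export
generate_lesion_mask <- function(grid_shape, spacing, radius_mm,
                                 center_mm = NULL, irregularity = 0,
                                 axis_ratio = c(1, 1, 1), seed = NULL) {
  if (irregularity < 0) stopf("irregularity must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  grid_shape <- as.integer(grid_shape)
  if (radius_mm * 1.8 >= min(grid_shape * spacing) / 2)
    stopf("configuration error: lesion radius %.1f mm too large for grid", radius_mm)
  if (is.null(center_mm)) center_mm <- (grid_shape - 1) * spacing / 2
  co <- lapply(1:3, function(k) (seq_len(grid_shape[k]) - 1) * spacing[k] - center_mm[k])
  X <- array(co[[1]], grid_shape)
  Y <- array(rep(co[[2]], each = grid_shape[1]), grid_shape)
  Z <- array(rep(co[[3]], each = grid_shape[1] * grid_shape[2]), grid_shape)
  axes <- radius_mm * axis_ratio / mean(axis_ratio)
  # normalized ellipsoidal radius and unit direction
  Q <- sqrt((X / axes[1])^2 + (Y / axes[2])^2 + (Z / axes[3])^2)
  R <- sqrt(X^2 + Y^2 + Z^2)
  R[R < 1e-9] <- 1e-9
  u <- cbind(as.vector(X / R), as.vector(Y / R), as.vector(Z / R))
  if (irregularity > 0) {
    B <- .dir_harmonics(u)
    coef <- stats::rnorm(ncol(B))
    s <- as.vector(B %*% coef)
    s <- s / max(stats::sd(s), 1e-9)
    mult <- pmin(pmax(1 + irregularity * s, 0.4), 1.8)
  } else {
    mult <- 1
  }
  mask <- array(as.vector(Q) <= mult, grid_shape)
  if (!any(mask)) stopf("configuration error: lesion mask empty")
  # star-convexity makes disconnection rare; enforce the single-component
  # postcondition by keeping the component containing the centre
  ctr <- pmin(pmax(as.integer(round(center_mm / spacing)) + 1L, 1L), grid_shape)
  if (!mask[ctr[1], ctr[2], ctr[3]]) {
    w <- which(mask, arr.ind = TRUE)
    d <- colSums((t(w) - ctr)^2)
    ctr <- w[which.min(d), ]
  }
  connected_component3(mask, ctr)
}

#' Synthesize the PET and CT channels for a lesion mask
#'
#' Lesion voxels are drawn from a spatially correlated Gaussian random field
#' (smoothed white noise; kernel width = correlation length) with
#' class-specific level and amplitude; the background sits at
#' `background_suv_mean` (PET) / `ct_background_hu` (CT) with white noise.
#' Deterministic given `(config$seed, patient_index)`.
#'
#' @param mask Logical 3-d lesion mask from [generate_lesion_mask()].
#' @param config A [phantom_config()].
#' @param class_label `"mutant"` or `"wild"`.
#' @param patient_index Integer patient index (seeds the draw).
#' @param patient_id Identifier for the resulting [volume_pair()].
#' @param params Optional pre-drawn per-patient parameter list (internal use).
#' @return A [volume_pair()].
#' @export
synthesize_pet_ct <- function(mask, config, class_label, patient_index,
                              patient_id = sprintf("P%03d", patient_index),
                              params = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  cl <- match.arg(class_label, c("mutant", "wild"))
  set.seed(patient_seed(config$seed, patient_index, stage = 2L))
  if (is.null(params)) params <- draw_patient_params(config, cl)
  dm <- dim(mask)
  sp <- config$voxel_spacing

  field_pet <- gaussian_random_field3(dm, rep(params$corr_len_mm, 3) / sp / 2.355)
  field_ct <- gaussian_random_field3(dm, rep(params$ct_corr_len_mm, 3) / sp / 2.355)

  pet <- config$background_suv_mean +
    stats::rnorm(prod(dm), sd = config$background_suv_noise_sd)
  pet <- array(pet, dm)
  lesion_vals <- params$suv_mean * (1 + params$het_amp * field_pet[mask]) +
    stats::rnorm(sum(mask), sd = config$pet_noise_sd)
  pet[mask] <- lesion_vals
  pet[pet < 0.01] <- 0.01

  ct <- config$ct_background_hu +
    stats::rnorm(prod(dm), sd = config$ct_background_noise_sd)
  ct <- array(ct, dm)
  ct[mask] <- params$ct_hu_mean + params$ct_texture_sd * field_ct[mask]

  # metadata back-filled consistently: 4 MBq/kg injected dose (1 mCi = 37 MBq)
  weight_g <- min(max(stats::rnorm(1, 65000, 10000), 42000), 95000)
  dose_mCi <- weight_g / 1000 * 4 / 37
  volume_pair(pet, ct, sp, patient_id,
              injected_dose_mCi = dose_mCi, body_weight_g = weight_g)
}

patient_seed <- function(master_seed, patient_index, stage = 1L) {
  (as.integer(master_seed) %% 100000L) * 10000L + patient_index * 10L + stage
}

draw_patient_params <- function(config, class_label) {
  p <- config$class_params[[class_label]]
  occult <- stats::runif(1) < (config$pet_occult_rate %||% 0)
  if (occult) {
    # PET side: pooled across classes (no class contrast); CT side: amplified
    q <- config$class_params[[setdiff(c("mutant", "wild"), class_label)]]
    pool <- function(f) (p[[f]] + q[[f]]) / 2
    pet_means <- list(suv_mean = pool("suv_mean"), het_amp = pool("het_amp"),
                      corr_len_mm = pool("corr_len_mm"),
                      boundary_amp = pool("boundary_amp"))
    ct <- config$ct_occult_params[[class_label]]
  } else {
    pet_means <- p[c("suv_mean", "het_amp", "corr_len_mm", "boundary_amp")]
    ct <- p[c("ct_hu_mean", "ct_texture_sd", "ct_corr_len_mm")]
  }
  list(
    radius_mm = stats::runif(1, config$lesion_radius_range[1], config$lesion_radius_range[2]),
    boundary_amp = max(stats::rnorm(1, pet_means$boundary_amp, p$boundary_amp_sd), 0),
    suv_mean = max(stats::rnorm(1, pet_means$suv_mean, p$suv_sd), 1.5),
    het_amp = max(stats::rnorm(1, pet_means$het_amp, p$het_amp_sd), 0.02),
    corr_len_mm = max(stats::rnorm(1, pet_means$corr_len_mm, p$corr_len_sd %||% 0), 2),
    ct_hu_mean = stats::rnorm(1, ct$ct_hu_mean, p$ct_hu_sd),
    ct_texture_sd = max(stats::rnorm(1, ct$ct_texture_sd, p$ct_texture_sd_sd), 2),
    ct_corr_len_mm = max(stats::rnorm(1, ct$ct_corr_len_mm, p$ct_corr_len_sd %||% 0), 2),
    pet_occult = occult,
    axis_ratio = stats::runif(3, 0.85, 1.15)
  )
}

# Cohort marginals emulated by simulate_cohort_table (per-class proportions):
# gender (female), stage I-II, and lobe location (upper/middle/lower/overlapping).
.cohort_marginals <- list(
  female = c(mutant = 0.578, wild = 0.490),
  stage_early = c(mutant = 0.781, wild = 0.784),
  location = list(
    mutant = c(upper = 0.625, middle = 0.109, lower = 0.234, overlapping = 0.032),
    wild = c(upper = 0.569, middle = 0.039, lower = 0.373, overlapping = 0.019)
  )
)

#' Simulate the clinical covariate table for a phantom cohort
#'
#' One row per patient: age (drawn on 28--77 with median near 63), gender,
#' smoking status (per-class Bernoulli at the configured prevalences), clinical
#' stage (~78% I--II), lesion lobe location, EGFR class label, and the
#' dose/weight metadata used by the SUV conversion path. Covariates are
#' independent of image texture given the class label.
#'
#' @param config A [phantom_config()].
#' @return Data frame with `n_mutant + n_wild` rows.
#' @export
simulate_cohort_table <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$n_mutant + config$n_wild
  labels <- rep(c("mutant", "wild"), c(config$n_mutant, config$n_wild))
  set.seed(patient_seed(config$seed, 0L, stage = 3L))
  # beta(2.5, 1.2) rescaled to [28, 77] has median ~ 0.714 -> age ~ 63
  age <- round(28 + 49 * stats::rbeta(n, 2.5, 1.2))
  smoking <- ifelse(stats::runif(n) < config$smoking_prevalence[match(labels, c("mutant", "wild"))],
                    "yes", "no")
  gender <- ifelse(stats::runif(n) < .cohort_marginals$female[labels], "female", "male")
  stage <- ifelse(stats::runif(n) < .cohort_marginals$stage_early[labels], "I-II", "III-IV")
  location <- vapply(labels, function(cl) {
    sample(names(.cohort_marginals$location[[cl]]), 1L,
           prob = .cohort_marginals$location[[cl]])
  }, character(1))
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             age = age, gender = gender, smoking = smoking, stage = stage,
             location = unname(location), egfr_label = labels,
             injected_dose_mCi = NA_real_, body_weight_g = NA_real_,
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic PET/CT cohort
#'
#' Draws per-patient lesion parameters, builds the lesion mask and the PET/CT
#' channels for every patient, and assembles the cohort table. Fully
#' deterministic given `config$seed`.
#'
#' @param config A [phantom_config()].
#' @return An object of class `synthetic_cohort`: list with `volumes` (list of
#'   [volume_pair()]), `cohort_table` (data frame, dose/weight back-filled from
#'   the volumes), and `truth` (per-patient generating parameters, including
#'   the lesion centre voxel usable as a segmentation seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  tab <- simulate_cohort_table(config)
  n <- nrow(tab)
  volumes <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- tab$egfr_label[i]
    set.seed(patient_seed(config$seed, i, stage = 1L))
    pp <- draw_patient_params(config, cl)
    center_mm <- (dim_center_mm(config) + stats::runif(3, -3, 3))
    mask <- generate_lesion_mask(config$grid_shape, config$voxel_spacing,
                                 radius_mm = pp$radius_mm, center_mm = center_mm,
                                 irregularity = pp$boundary_amp,
                                 axis_ratio = pp$axis_ratio)
    volumes[[i]] <- synthesize_pet_ct(mask, config, cl, i,
                                      patient_id = tab$patient_id[i], params = pp)
    tab$injected_dose_mCi[i] <- volumes[[i]]$meta$injected_dose_mCi
    tab$body_weight_g[i] <- volumes[[i]]$meta$body_weight_g
    seed_vox <- round(center_mm / config$voxel_spacing) + 1
    truth[[i]] <- data.frame(patient_id = tab$patient_id[i], label = cl,
                             pet_occult = isTRUE(pp$pet_occult),
                             radius_mm = pp$radius_mm, suv_mean = pp$suv_mean,
                             het_amp = pp$het_amp, boundary_amp = pp$boundary_amp,
                             ct_hu_mean = pp$ct_hu_mean, ct_texture_sd = pp$ct_texture_sd,
                             seed_x = seed_vox[1], seed_y = seed_vox[2], seed_z = seed_vox[3],
                             stringsAsFactors = FALSE)
  }
  structure(list(volumes = volumes, cohort_table = tab,
                 truth = do.call(rbind, truth), config = config),
            class = "synthetic_cohort")
}

dim_center_mm <- function(config) (config$grid_shape - 1) * config$voxel_spacing / 2

#' Write a synthetic cohort to disk
#'
#' One PET and one CT NIfTI per patient plus `cohort.csv`.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (vp in cohort$volumes) write_volume_pair(vp, dir)
  write_table_csv(cohort$cohort_table, file.path(dir, "cohort.csv"))
  invisible(dir)
}
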