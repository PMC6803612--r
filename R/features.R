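#' Canonical radiomic feature names
#'
#' The fixed, ordered 38-feature catalog: 4 morphological + 9 grayscale
#' statistical (GSS) + 6 co-occurrence (GLCM) + 15 gray-gradient co-occurrence
#' (GGCM) + 4 difference-statistic (GLDS) features.
#'
#' @param modality Optional prefix (`"pet"` or `"ct"`) prepended as
#'   `<modality>_<name>`.
#' @return Character vector of length 38.
#' @export
radiomic_feature_names <- function(modality = NULL) {
  nm <- c(paste0("morph_", c("area", "perimeter", "diameter", "concavity")),
          paste0("gss_", c("mean", "sd", "skewness", "kurtosis", "cm5", "cm6",
                           "energy", "entropy", "span")),
          paste0("glcm_", c("asm", "contrast", "correlation", "entropy",
                            "homogeneity", "dissimilarity")),
          paste0("ggcm_", c("small_grad_dominance", "big_grad_dominance",
                            "gray_asymmetry", "grad_asymmetry", "energy",
                            "gray_mean", "grad_mean", "gray_variance",
                            "grad_variance", "correlation", "gray_entropy",
                            "grad_entropy", "mixed_entropy", "inertia", "idm")),
          paste0("glds_", c("mean", "contrast", "asm", "entropy")))
  if (!is.null(modality)) nm <- paste0(modality, "_", nm)
  nm
}

# Feature vector for one slice of one modality.
slice_feature_vector <- function(slice, mask2, G, distance, concavity_absolute) {
  q <- quantize_roi(slice, mask2, G)
  v <- c(compute_morphology(mask2, concavity_absolute = concavity_absolute),
         compute_gss(slice, mask2, G),
         compute_glcm_features(q, distance = distance),
         compute_ggcm_features(slice, mask2, G = G, Gs = G),
         compute_glds_features(q))
  names(v) <- radiomic_feature_names()
  v
}

#' Extract the 38-feature radiomic vector for one modality
#'
#' Applies the five feature families (morphology, GSS, GLCM, GGCM, GLDS) to
#' the 2-d analysis slice(s) of the chosen modality, restricted to the VOI
#' mask. In `slice_mode = "largest"` (default) the single axial slice with the
#' most in-mask pixels is analysed (falling back to the next-largest slice if
#' the largest cannot support a 3x3 gradient stencil); in `"average"` the
#' feature vector is the mean over all axial slices large enough to support
#' every family.
#'
#' @param volume A [volume_pair()].
#' @param roi A `tumor_roi` from [segment_isocontour()].
#' @param modality `"pet"` or `"ct"`.
#' @param slice_mode `"largest"` or `"average"`.
#' @param G Gray-level count (default 16).
#' @param distance Co-occurrence pixel distance (default 1).
#' @param concavity_absolute See [compute_morphology()].
#' @return Named numeric vector of length 38 in the fixed catalog order.
#' @export
extract_feature_vector <- function(volume, roi, modality = c("pet", "ct"),
                                   slice_mode = c("largest", "average"),
                                   G = 16L, distance = 1L,
                                   concavity_absolute = FALSE) {
  stopifnot(inherits(volume, "volume_pair"), inherits(roi, "tumor_roi"))
  modality <- match.arg(modality)
  slice_mode <- match.arg(slice_mode)
  grid <- if (modality == "pet") volume$pet else volume$ct
  if (!identical(dim(grid), dim(roi$voi_mask))) stopf("ROI grid does not match the volume")

  if (slice_mode == "largest") {
    # largest in-mask slice that also supports the 3x3 gradient stencil
    counts <- apply(roi$voi_mask, 3, sum)
    for (z in order(counts, decreasing = TRUE)) {
      if (counts[z] == 0L) break
      if (!any(erode_mask2(roi$voi_mask[, , z]))) next
      return(slice_feature_vector(grid[, , z], roi$voi_mask[, , z], G, distance,
                                  concavity_absolute))
    }
    stopf("no slice supports the 3x3 gradient stencil")
  }
  zs <- which(apply(roi$voi_mask, 3, function(m) any(erode_mask2(m))))
  if (length(zs) == 0L) stopf("no slice supports the 3x3 gradient stencil")
  vecs <- lapply(zs, function(z)
    slice_feature_vector(grid[, , z], roi$voi_mask[, , z], G, distance,
                         concavity_absolute))
  colMeans(do.call(rbind, vecs))
}

#' Build the per-patient feature table for a cohort
#'
#' Segments each patient's lesion, computes the conventional PET metrics and
#' the 38-feature radiomic vector for both modalities, and assembles one row
#' per patient: `patient_id`, `egfr_label`, `pet_*` and `ct_*` radiomic
#' columns (fixed order), then `suv_max`, `suv_mean`, `suv_peak`, `mtv`,
#' `tlg`.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()], or a list with
#'   elements `volumes`, `cohort_table` and (optionally) `truth` containing
#'   seed voxels `seed_x/seed_y/seed_z`.
#' @param voi_fraction,mtv_cutoff Segmentation parameters
#'   (see [segment_isocontour()]).
#' @param slice_mode,G,distance Feature parameters
#'   (see [extract_feature_vector()]).
#' @return Data frame with one row per patient.
#' @export
extract_cohort_features <- function(cohort, voi_fraction = 0.42, mtv_cutoff = 2.5,
                                    slice_mode = "largest", G = 16L, distance = 1L) {
  vols <- cohort$volumes
  tab <- cohort$cohort_table
  n <- length(vols)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    vp <- vols[[i]]
    seed <- if (!is.null(cohort$truth)) {
      as.integer(cohort$truth[i, c("seed_x", "seed_y", "seed_z")])
    } else {
      which(vp$pet == max(vp$pet), arr.ind = TRUE)[1, ]
    }
    if (vp$pet[seed[1], seed[2], seed[3]] <= 0.10 * max(vp$pet))
      seed <- which(vp$pet == max(vp$pet), arr.ind = TRUE)[1, ]
    roi <- segment_isocontour(vp$pet, seed, voi_fraction = voi_fraction,
                              mtv_cutoff = mtv_cutoff)
    conv <- compute_conventional_metrics(vp$pet, roi, vp$spacing)
    fpet <- extract_feature_vector(vp, roi, "pet", slice_mode, G, distance)
    fct <- extract_feature_vector(vp, roi, "ct", slice_mode, G, distance)
    rows[[i]] <- data.frame(patient_id = vp$patient_id,
                            egfr_label = tab$egfr_label[i],
                            as.list(stats::setNames(fpet, radiomic_feature_names("pet"))),
                            as.list(stats::setNames(fct, radiomic_feature_names("ct"))),
                            suv_max = conv$suv_max, suv_mean = conv$suv_mean,
                            suv_peak = conv$suv_peak, mtv = conv$mtv, tlg = conv$tlg,
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  do.call(rbind, rows)
}
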