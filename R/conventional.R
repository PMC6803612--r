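#' Conventional PET metrics for a segmented lesion
#'
#' Computes the standard semi-quantitative PET parameters over a tumor ROI:
#' \itemize{
#'   \item `suv_max`, `suv_mean`: maximum and mean SUV over the VOI mask.
#'   \item `suv_peak`: mean SUV in a 1 cm^3 sphere centred on the hottest
#'     voxel (PERCIST-style neighbourhood mean), clipped to the grid.
#'   \item `mtv`: metabolic tumor volume in mL — the number of voxels in the
#'     SUV > 2.5 metabolic mask times the voxel volume. 0 when the lesion
#'     SUVmax does not exceed the cutoff.
#'   \item `tlg`: total lesion glycolysis = MTV x mean SUV over the metabolic
#'     region (`tlg_region = "mtv"`, default) or over the VOI
#'     (`tlg_region = "voi"`); 0 when MTV is 0.
#' }
#'
#' @param pet 3-d array of SUV values.
#' @param roi A `tumor_roi` from [segment_isocontour()].
#' @param spacing Voxel spacing in mm (length 3).
#' @param peak_volume_ml Volume of the SUVpeak sphere in mL (default 1).
#' @param tlg_region Region whose SUVmean multiplies MTV in the TLG product.
#' @return Named list of class `conventional_metrics` with fields `suv_max`,
#'   `suv_mean`, `suv_peak`, `mtv`, `tlg`.
#' @export
compute_conventional_metrics <- function(pet, roi, spacing,
                                         peak_volume_ml = 1,
                                         tlg_region = c("mtv", "voi")) {
  stopifnot(inherits(roi, "tumor_roi"))
  tlg_region <- match.arg(tlg_region)
  if (!any(roi$voi_mask)) stopf("empty VOI")
  vals <- pet[roi$voi_mask]
  suv_max <- max(vals)
  suv_mean <- mean(vals)

  # SUVpeak: mean over voxels whose centres fall in a sphere of peak_volume_ml
  # centred on the hottest voxel
  r_mm <- (3 * peak_volume_ml * 1000 / (4 * pi))^(1 / 3)
  ctr <- roi$suv_max_index
  dm <- dim(pet)
  half <- pmax(ceiling(r_mm / spacing), 1)
  rng <- lapply(1:3, function(k) max(1L, ctr[k] - half[k]):min(dm[k], ctr[k] + half[k]))
  sub <- pet[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  dist2 <- outer(outer(((rng[[1]] - ctr[1]) * spacing[1])^2,
                       ((rng[[2]] - ctr[2]) * spacing[2])^2, `+`),
                 ((rng[[3]] - ctr[3]) * spacing[3])^2, `+`)
  suv_peak <- mean(sub[dist2 <= r_mm^2])

  voxel_ml <- prod(spacing) / 1000
  n_mtv <- sum(roi$mtv_mask)
  mtv <- n_mtv * voxel_ml
  tlg <- if (n_mtv == 0L) 0 else {
    mtv * if (tlg_region == "mtv") mean(pet[roi$mtv_mask]) else suv_mean
  }
  structure(list(suv_max = suv_max, suv_mean = suv_mean, suv_peak = suv_peak,
                 mtv = mtv, tlg = tlg),
            class = "conventional_metrics")
}

#' @export
print.conventional_metrics <- function(x, ...) {
  cat(sprintf("SUVmax %.3f  SUVmean %.3f  SUVpeak %.3f  MTV %.3f mL  TLG %.3f\n",
              x$suv_max, x$suv_mean, x$suv_peak, x$mtv, x$tlg))
  invisible(x)
}
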