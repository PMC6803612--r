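#' Segment a tumor VOI by a relative SUV isocontour
#'
#' Finds the lesion SUVmax inside the connected high-uptake region around a
#' caller-supplied seed voxel, then delineates the volume of interest as all
#' voxels with SUV at or above `voi_fraction` x SUVmax (default 42%) that are
#' 26-connected to the SUVmax voxel. The SUVmax is located iteratively: the
#' isocontour component is regrown until the in-component maximum stabilizes.
#' Because the threshold is relative, the resulting mask is invariant under any
#' positive rescaling of the PET grid. The metabolic (MTV) mask at the
#' absolute SUV 2.5 cutoff is attached via [segment_mtv_region()].
#'
#' @param pet 3-d array of SUV values.
#' @param seed_point Integer length-3 voxel index inside the lesion's
#'   high-uptake region.
#' @param voi_fraction Relative threshold (default 0.42, inclusive `>=`).
#' @param seed_min_fraction Seed validity floor: the seed voxel must exceed
#'   this fraction of the global PET maximum (relative, so scale invariance is
#'   preserved); default 0.10.
#' @param mtv_cutoff Absolute SUV cutoff for the metabolic mask (strict `>`,
#'   default 2.5).
#' @return An object of class `tumor_roi`: list with `voi_mask`, `mtv_mask`,
#'   `analysis_slice_index` (axial slice maximizing in-mask pixel count),
#'   `threshold_suv` (the absolute cutoff applied, `voi_fraction * SUVmax`),
#'   `suv_max` and `suv_max_index`.
#' @export
segment_isocontour <- function(pet, seed_point, voi_fraction = 0.42,
                               seed_min_fraction = 0.10, mtv_cutoff = 2.5) {
  if (length(dim(pet)) != 3L) stopf("pet must be a 3-d array")
  seed_point <- as.integer(seed_point)
  if (length(seed_point) != 3L || any(seed_point < 1L) || any(seed_point > dim(pet)))
    stopf("seed_point must be a voxel index inside the grid")
  seed_val <- pet[seed_point[1], seed_point[2], seed_point[3]]
  if (seed_val <= seed_min_fraction * max(pet))
    stopf("segmentation error: seed voxel (SUV %.3g) is not above the background threshold", seed_val)

  m <- seed_val
  pt <- seed_point
  repeat {
    comp <- connected_component3(pet >= voi_fraction * m, pt)
    m_new <- max(pet[comp])
    if (m_new <= m) break
    m <- m_new
    pt <- which(comp & (pet == m), arr.ind = TRUE)[1, ]
  }
  idx_max <- which(comp & (pet == m), arr.ind = TRUE)[1, ]
  voi <- connected_component3(pet >= voi_fraction * m, idx_max)

  counts <- apply(voi, 3, sum)
  roi <- structure(list(voi_mask = voi, mtv_mask = NULL,
                        analysis_slice_index = which.max(counts),
                        threshold_suv = voi_fraction * m,
                        suv_max = m, suv_max_index = as.integer(idx_max),
                        voi_fraction = voi_fraction, mtv_cutoff = mtv_cutoff),
                   class = "tumor_roi")
  roi$mtv_mask <- segment_mtv_region(pet, roi, cutoff = mtv_cutoff)
  roi
}

#' Segment the metabolic tumor region at an absolute SUV cutoff
#'
#' Returns the voxels of the lesion's connected component with SUV strictly
#' above `cutoff` (default 2.5). When the lesion SUVmax does not exceed the
#' cutoff the mask is empty, encoding the convention that such lesions have a
#' metabolic tumor volume of 0.
#'
#' @param pet 3-d array of SUV values.
#' @param roi A `tumor_roi` from [segment_isocontour()].
#' @param cutoff Absolute SUV cutoff (strict `>`).
#' @return Logical 3-d mask (possibly all-FALSE).
#' @export
segment_mtv_region <- function(pet, roi, cutoff = 2.5) {
  stopifnot(inherits(roi, "tumor_roi"))
  if (roi$suv_max <= cutoff) return(array(FALSE, dim(pet)))
  connected_component3(pet > cutoff, roi$suv_max_index)
}

#' @export
print.tumor_roi <- function(x, ...) {
  cat(sprintf("<tumor_roi> VOI %d voxels (threshold SUV %.3f = %.0f%% of SUVmax %.3f); MTV mask %d voxels; analysis slice %d\n",
              sum(x$voi_mask), x$threshold_suv, 100 * x$voi_fraction, x$suv_max,
              sum(x$mtv_mask), x$analysis_slice_index))
  invisible(x)
}

#' Write an ROI mask as NIfTI on the source grid
#'
#' @param roi A `tumor_roi`.
#' @param spacing Voxel spacing of the source PET grid (mm).
#' @param path Output path (`.nii.gz`).
#' @param which Which mask to write: `"voi"` or `"mtv"`.
#' @export
write_roi_mask <- function(roi, spacing, path, which = c("voi", "mtv")) {
  which <- match.arg(which)
  m <- if (which == "voi") roi$voi_mask else roi$mtv_mask
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(m), dim(m)), pixdim = spacing),
                     path, datatype = "uint8")
  invisible(path)
}
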