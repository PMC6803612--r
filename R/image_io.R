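#' Convert PET activity concentration to standardized uptake values
#'
#' SUV normalizes the measured activity concentration in a region by the
#' injected dose per gram of body weight:
#' \deqn{SUV = \frac{\mathrm{activity\ (mCi/mL)}}{\mathrm{injected\ dose\ (mCi)} / \mathrm{body\ weight\ (g)}}}
#' The result is dimensionless (assuming ~1 g/mL tissue density).
#'
#' @param activity Numeric array (any shape) of activity concentration in
#'   mCi/mL. Must be non-negative.
#' @param injected_dose_mCi Injected tracer dose in mCi; must be positive.
#' @param body_weight_g Patient body weight in grams; must be positive.
#' @return Array of the same shape as `activity`, in SUV units.
#' @examples
#' activity_to_suv(0.005, injected_dose_mCi = 10, body_weight_g = 70000)
#' @export
activity_to_suv <- function(activity, injected_dose_mCi, body_weight_g) {
  if (!is.numeric(injected_dose_mCi) || length(injected_dose_mCi) != 1L || injected_dose_mCi <= 0)
    stopf("injected_dose_mCi must be a single positive number")
  if (!is.numeric(body_weight_g) || length(body_weight_g) != 1L || body_weight_g <= 0)
    stopf("body_weight_g must be a single positive number")
  if (any(activity < 0)) stopf("activity values must be non-negative")
  activity / (injected_dose_mCi / body_weight_g)
}

#' Construct a co-registered PET/CT volume pair
#'
#' Bundles a PET volume (SUV units), a CT volume (Hounsfield units), the voxel
#' spacing and per-patient metadata. Both grids must share shape and spacing;
#' world coordinates are axis-aligned (0-based voxel index times spacing).
#'
#' @param pet 3-d numeric array of SUV values (non-negative).
#' @param ct 3-d numeric array of HU values, same shape as `pet`.
#' @param spacing Numeric length-3 vector of voxel spacing in mm, all positive.
#' @param patient_id Character scalar identifier.
#' @param injected_dose_mCi,body_weight_g Metadata used by the SUV conversion
#'   path (see [activity_to_suv()]).
#' @return An object of class `volume_pair`.
#' @export
volume_pair <- function(pet, ct, spacing, patient_id,
                        injected_dose_mCi = NA_real_, body_weight_g = NA_real_) {
  if (length(dim(pet)) != 3L || length(dim(ct)) != 3L)
    stopf("pet and ct must be 3-d arrays")
  if (!identical(dim(pet), dim(ct)))
    stopf("pet and ct grids must have identical shape (got %s vs %s)",
          paste(dim(pet), collapse = "x"), paste(dim(ct), collapse = "x"))
  if (length(spacing) != 3L || any(spacing <= 0)) stopf("spacing must be 3 positive values (mm)")
  if (any(pet < 0)) stopf("PET SUV values must be non-negative")
  structure(list(pet = pet, ct = ct, spacing = as.numeric(spacing),
                 patient_id = as.character(patient_id),
                 meta = list(injected_dose_mCi = injected_dose_mCi,
                             body_weight_g = body_weight_g)),
            class = "volume_pair")
}

#' @export
print.volume_pair <- function(x, ...) {
  cat(sprintf("<volume_pair> %s: %s voxels @ %s mm; SUVmax %.2f, HU range [%.0f, %.0f]\n",
              x$patient_id, paste(dim(x$pet), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              max(x$pet), min(x$ct), max(x$ct)))
  invisible(x)
}

#' Write / read a PET/CT volume pair as NIfTI
#'
#' Volumes are persisted as `<patient_id>_pet.nii.gz` and
#' `<patient_id>_ct.nii.gz` with voxel spacing in the NIfTI header. Grids are
#' stored as float64 so the round-trip is lossless.
#'
#' @param vp A [volume_pair()].
#' @param dir Output directory (created if missing).
#' @return `write_volume_pair` returns the two paths invisibly;
#'   `read_volume_pair` returns a `volume_pair`.
#' @export
write_volume_pair <- function(vp, dir) {
  stopifnot(inherits(vp, "volume_pair"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(vp$patient_id, c("_pet.nii.gz", "_ct.nii.gz")))
  pet_img <- RNifti::asNifti(vp$pet)
  ct_img <- RNifti::asNifti(vp$ct)
  RNifti::pixdim(pet_img) <- vp$spacing
  RNifti::pixdim(ct_img) <- vp$spacing
  RNifti::writeNifti(pet_img, paths[1], datatype = "double")
  RNifti::writeNifti(ct_img, paths[2], datatype = "double")
  invisible(paths)
}

#' @rdname write_volume_pair
#' @param pet_path,ct_path Paths to the PET (SUV) and CT (HU) NIfTI files.
#' @param meta_row Optional single-row data frame (or list) with columns
#'   `patient_id`, `injected_dose_mCi`, `body_weight_g`.
#' @export
read_volume_pair <- function(pet_path, ct_path, meta_row = NULL) {
  if (!file.exists(pet_path)) stopf("PET file not found: %s", pet_path)
  if (!file.exists(ct_path)) stopf("CT file not found: %s", ct_path)
  pet <- RNifti::readNifti(pet_path)
  ct <- RNifti::readNifti(ct_path)
  sp_pet <- RNifti::pixdim(pet)[1:3]
  sp_ct <- RNifti::pixdim(ct)[1:3]
  if (!isTRUE(all.equal(sp_pet, sp_ct, tolerance = 1e-6)))
    stopf("PET/CT voxel spacing mismatch")
  pid <- if (!is.null(meta_row)) meta_row$patient_id else sub("_pet\\.nii(\\.gz)?$", "", basename(pet_path))
  volume_pair(array(as.numeric(pet), dim(pet)), array(as.numeric(ct), dim(ct)),
              spacing = sp_pet, patient_id = pid,
              injected_dose_mCi = if (!is.null(meta_row)) meta_row$injected_dose_mCi else NA_real_,
              body_weight_g = if (!is.null(meta_row)) meta_row$body_weight_g else NA_real_)
}

#' Write / read tabular artifacts (cohort and feature tables)
#'
#' Plain UTF-8 comma-separated files with a header row. Column order is
#' preserved on the round trip.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8", check.names = FALSE)
}
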