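# Small fixture builders shared across test files.

# Compact phantom configuration: small grid, small lesions, defaults otherwise.
tiny_phantom_config <- function(n_mutant = 3, n_wild = 3, seed = 11, ...) {
  phantom_config(n_mutant = n_mutant, n_wild = n_wild,
                 grid_shape = c(28L, 28L, 28L), voxel_spacing = c(2, 2, 2),
                 lesion_radius_range = c(6, 9), seed = seed, ...)
}

# Uniform-intensity lesion ball in a cold background; returns list(pet, center).
uniform_lesion_pet <- function(dim = c(20, 20, 20), spacing = c(2, 2, 2),
                               radius_mm = 8, lesion_suv = 3, background_suv = 0.1) {
  ctr <- (dim - 1) * spacing / 2
  co <- lapply(1:3, function(k) (seq_len(dim[k]) - 1) * spacing[k] - ctr[k])
  d2 <- outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`)
  pet <- array(background_suv, dim)
  pet[d2 <= radius_mm^2] <- lesion_suv
  list(pet = pet, center = as.integer(round(ctr / spacing)) + 1L,
       mask = d2 <= radius_mm^2)
}

# A small cached feature table + labels for signature tests (built once per run).
cached_cohort_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- generate_cohort(tiny_phantom_config(n_mutant = 10, n_wild = 10, seed = 5))
      cache <<- list(features = extract_cohort_features(coh),
                     labels = coh$cohort_table$egfr_label,
                     cohort = coh)
    }
    cache
  }
})
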