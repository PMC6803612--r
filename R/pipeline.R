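#' Configuration for a full pipeline run
#'
#' Either builds the default configuration or loads one from a YAML file with
#' the same top-level fields. All defaults match the analysis parameters the
#' package implements: 42% SUVmax delineation, SUV 2.5 metabolic cutoff, 16
#' gray levels, 4 co-occurrence angles at distance 1, 4 difference
#' displacements, 10-fold cross-validation repeated 10 times, FDR 10%.
#'
#' @param seed Master seed for the whole run.
#' @param out_dir Output directory for the report bundle.
#' @param phantom List of [phantom_config()] overrides (e.g. `n_mutant`),
#'   or `NULL` to use `input_dir`.
#' @param input_dir Directory with per-patient NIfTI pairs and `cohort.csv`
#'   (as written by [write_cohort()]); used when `phantom` is `NULL`.
#' @param voi_fraction,mtv_cutoff Segmentation parameters.
#' @param slice_mode,n_gray_levels,glcm_distance Feature parameters.
#' @param fdr_q FDR threshold for the feature comparison.
#' @param scopes Signature scopes to evaluate.
#' @param clinical Logical vector: evaluate each scope without and/or with the
#'   clinical covariates (default `c(FALSE, TRUE)`).
#' @param folds,repeats,rounds,depth Cross-validation and boosting settings.
#' @param make_plots Emit diagnostic plots from [render_report()]?
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("petrad_run_"),
                       phantom = list(), input_dir = NULL,
                       voi_fraction = 0.42, mtv_cutoff = 2.5,
                       slice_mode = "largest", n_gray_levels = 16L,
                       glcm_distance = 1L, fdr_q = 0.10,
                       scopes = c("petct", "pet", "ct"),
                       clinical = c(FALSE, TRUE),
                       folds = 10L, repeats = 10L, rounds = 100L, depth = 1L,
                       make_plots = FALSE) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 phantom = phantom, input_dir = input_dir,
                 voi_fraction = voi_fraction, mtv_cutoff = mtv_cutoff,
                 slice_mode = slice_mode, n_gray_levels = as.integer(n_gray_levels),
                 glcm_distance = as.integer(glcm_distance), fdr_q = fdr_q,
                 scopes = scopes, clinical = clinical,
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 rounds = as.integer(rounds), depth = as.integer(depth),
                 make_plots = isTRUE(make_plots)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with `run_config` fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  do.call(run_config, yaml::read_yaml(path))
}

load_cohort_dir <- function(dir) {
  tab <- read_table_csv(file.path(dir, "cohort.csv"))
  vols <- lapply(seq_len(nrow(tab)), function(i) {
    read_volume_pair(file.path(dir, paste0(tab$patient_id[i], "_pet.nii.gz")),
                     file.path(dir, paste0(tab$patient_id[i], "_ct.nii.gz")),
                     meta_row = tab[i, ])
  })
  list(volumes = vols, cohort_table = tab, truth = NULL)
}

#' Run the full radiomic analysis pipeline
#'
#' Orchestrates phantom generation (or cohort loading), segmentation, feature
#' extraction, the statistical battery and signature evaluation, and writes
#' six artifacts into `config$out_dir`: `features.csv`, `comparison.csv`,
#' `spearman.csv`, `roc.csv`, `signatures.csv` and `manifest.json`. The run
#' is idempotent given the seed (re-running produces byte-identical CSVs).
#'
#' @param config A [run_config()].
#' @return An object of class `pipeline_bundle` with the artifact paths and
#'   in-memory results, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stopf("[stage %s] %s", name, conditionMessage(e)))
  }

  cohort <- stage("cohort", {
    if (is.null(config$phantom) && !is.null(config$input_dir)) {
      load_cohort_dir(config$input_dir)
    } else {
      generate_cohort(do.call(phantom_config, c(config$phantom, list(seed = config$seed))))
    }
  })
  labels <- cohort$cohort_table$egfr_label

  features <- stage("features", extract_cohort_features(
    cohort, voi_fraction = config$voi_fraction, mtv_cutoff = config$mtv_cutoff,
    slice_mode = config$slice_mode, G = config$n_gray_levels,
    distance = config$glcm_distance))
  feat_cols <- grep("^(pet|ct)_", names(features), value = TRUE)
  conv_cols <- c("suv_max", "suv_mean", "suv_peak", "mtv", "tlg")

  comparison <- stage("comparison", compare_features(
    features[c(feat_cols, conv_cols)], labels, q = config$fdr_q))

  sp <- stage("spearman", spearman_matrix(
    features[grep("^pet_", names(features), value = TRUE)], features[conv_cols]))
  spearman_long <- data.frame(
    feature = rep(rownames(sp$r), times = ncol(sp$r)),
    metric = rep(colnames(sp$r), each = nrow(sp$r)),
    r = as.vector(sp$r), p_value = as.vector(sp$p))

  roc <- stage("roc", roc_table(features[c(feat_cols, conv_cols)], labels))

  feats_clin <- stage("clinical", combine_with_clinical(features, cohort$cohort_table))
  sig_grid <- expand.grid(scope = config$scopes, clinical = config$clinical,
                          stringsAsFactors = FALSE)
  signatures <- stage("signatures", lapply(seq_len(nrow(sig_grid)), function(i) {
    spec <- signature_spec(scope = sig_grid$scope[i],
                           include_clinical = sig_grid$clinical[i],
                           folds = config$folds, repeats = config$repeats,
                           rounds = config$rounds, depth = config$depth,
                           seed = config$seed)
    evaluate_signature(feats_clin, labels, spec)
  }))
  signature_table <- if (length(signatures) == 0L) {
    data.frame(signature = character(0), clinical = logical(0), auc = numeric(0),
               accuracy_pct = numeric(0), sensitivity = numeric(0),
               specificity = numeric(0))
  } else {
    do.call(rbind, lapply(signatures, function(s)
      data.frame(signature = toupper(s$scope), clinical = s$include_clinical,
                 auc = s$auc, accuracy_pct = s$accuracy,
                 sensitivity = s$sensitivity, specificity = s$specificity)))
  }

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("petradiomics")),
    n_patients = nrow(features),
    parameters = list(voi_fraction = config$voi_fraction,
                      mtv_cutoff = config$mtv_cutoff,
                      n_gray_levels = config$n_gray_levels,
                      glcm_angles = 4L, glcm_distance = config$glcm_distance,
                      glds_displacements = 4L, slice_mode = config$slice_mode,
                      fdr_q = config$fdr_q,
                      cv_folds = config$folds, cv_repeats = config$repeats,
                      boost_rounds = config$rounds, boost_depth = config$depth))

  paths <- c(features = "features.csv", comparison = "comparison.csv",
             spearman = "spearman.csv", roc = "roc.csv",
             signatures = "signatures.csv", manifest = "manifest.json")
  paths <- stats::setNames(file.path(config$out_dir, paths), names(paths))
  write_table_csv(features, paths["features"])
  write_table_csv(comparison, paths["comparison"])
  write_table_csv(spearman_long, paths["spearman"])
  write_table_csv(roc, paths["roc"])
  write_table_csv(signature_table, paths["signatures"])
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(structure(list(paths = paths, features = features,
                           comparison = comparison, spearman = spearman_long,
                           roc = roc, signature_table = signature_table,
                           signatures = signatures, manifest = manifest,
                           config = config),
                      class = "pipeline_bundle"))
}

#' Render a human-readable summary of a pipeline run
#'
#' Writes `report.txt` (and optional PNG box plots of the most discriminative
#' features) next to the bundle artifacts.
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @param plots Emit PNG plots? Defaults to the run configuration's setting.
#' @return Path of the report file, invisibly.
#' @export
render_report <- function(bundle, plots = bundle$config$make_plots) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  for (p in bundle$paths) if (!file.exists(p)) stopf("missing artifact: %s", p)
  out <- file.path(bundle$config$out_dir, "report.txt")
  con <- file(out, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Radiomic signature analysis (seed %d, %d patients)", bundle$manifest$seed,
    bundle$manifest$n_patients)
  w("Applied parameters: VOI isocontour %.0f%% of SUVmax; MTV cutoff SUV %.1f; %d gray levels; %d angles at distance %d; %d GLDS displacements; FDR %.0f%%; %d-fold CV x %d repeats",
    100 * bundle$manifest$parameters$voi_fraction, bundle$manifest$parameters$mtv_cutoff,
    bundle$manifest$parameters$n_gray_levels, bundle$manifest$parameters$glcm_angles,
    bundle$manifest$parameters$glcm_distance, bundle$manifest$parameters$glds_displacements,
    100 * bundle$manifest$parameters$fdr_q, bundle$manifest$parameters$cv_folds,
    bundle$manifest$parameters$cv_repeats)
  w("")
  if (nrow(bundle$signature_table) == 0L) {
    w("no signatures evaluated")
  } else {
    w("Signature performance (means over repeats):")
    w("  %-8s %-9s %-6s %-12s %-11s %-11s", "scope", "clinical", "AUC", "accuracy(%)",
      "sensitivity", "specificity")
    for (i in seq_len(nrow(bundle$signature_table))) {
      s <- bundle$signature_table[i, ]
      w("  %-8s %-9s %.3f  %7.3f      %.3f       %.3f", s$signature,
        ifelse(s$clinical, "yes", "no"), s$auc, s$accuracy_pct, s$sensitivity, s$specificity)
    }
  }
  w("")
  sig <- bundle$comparison[bundle$comparison$significant, "feature"]
  w("Features significant at FDR %.0f%%: %d of %d", 100 * bundle$config$fdr_q,
    length(sig), nrow(bundle$comparison))
  if (isTRUE(plots)) {
    top <- utils::head(bundle$roc[order(-bundle$roc$auc), "feature"], 4)
    labs <- bundle$features$egfr_label
    for (f in top) {
      png_path <- file.path(bundle$config$out_dir, paste0("boxplot_", f, ".png"))
      grDevices::png(png_path, width = 500, height = 400)
      graphics::boxplot(bundle$features[[f]] ~ labs, xlab = "", ylab = f,
                        main = sprintf("%s (AUC %.3f)", f,
                                       bundle$roc$auc[bundle$roc$feature == f]))
      grDevices::dev.off()
    }
  }
  invisible(out)
}
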