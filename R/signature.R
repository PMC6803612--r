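#' Specification of a radiomic signature evaluation
#'
#' @param scope Feature scope: `"petct"`, `"pet"` or `"ct"` (which modality's
#'   radiomic columns enter the model).
#' @param include_clinical Append the clinical covariate columns (`clin_*`)?
#' @param folds,repeats Stratified cross-validation design (default 10 x 10).
#' @param rounds,depth Boosting hyperparameters (default 100 rounds of
#'   stumps).
#' @param inner_folds Inner folds for the LASSO penalty search (default 10).
#' @param seed Integer seed controlling fold assignment and penalty search.
#' @return An object of class `signature_spec`.
#' @export
signature_spec <- function(scope = c("petct", "pet", "ct"),
                           include_clinical = FALSE,
                           folds = 10L, repeats = 10L,
                           rounds = 100L, depth = 1L, inner_folds = 10L,
                           seed = 1L) {
  scope <- match.arg(scope)
  if (folds < 2L) stopf("folds must be >= 2")
  if (repeats < 1L) stopf("repeats must be >= 1")
  structure(list(scope = scope, include_clinical = include_clinical,
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 rounds = as.integer(rounds), depth = as.integer(depth),
                 inner_folds = as.integer(inner_folds), seed = as.integer(seed)),
            class = "signature_spec")
}

# Deterministic stratified fold assignment (uses the current RNG state).
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k && length(idx) < 1L) stopf("class '%s' empty", cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' LASSO feature selection for a binary outcome
#'
#' L1-penalized logistic regression along a penalty path; the penalty is
#' chosen by inner k-fold (stratified) deviance minimization. The selected
#' set is the features with nonzero coefficients at the chosen penalty; when
#' that set is empty (no signal at the deviance-optimal penalty) the largest
#' penalty admitting at least one nonzero coefficient is used instead, so a
#' classifier can always be fit downstream. Constant feature columns are
#' dropped with a warning. Inputs are expected standardized (zero mean, unit
#' variance); no rescaling is applied internally.
#'
#' @param x Standardized numeric matrix (samples x features), no missing
#'   values.
#' @param y Two-class label vector.
#' @param inner_folds Folds for the penalty search (default 10).
#' @param positive Positive class (see [roc_auc()]).
#' @return List with `features` (selected names), `coefficients` (named,
#'   nonzero, excluding the intercept), `lambda`.
#' @export
lasso_select <- function(x, y, inner_folds = 10L, positive = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) stopf("missing values in the feature matrix")
  rp <- resolve_positive(y, positive)
  yy <- as.integer(rp$labels == rp$positive)
  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  if (!all(keep)) {
    warning(sprintf("dropping %d constant feature column(s)", sum(!keep)))
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) < 2L) {
    # glmnet needs >= 2 columns; a single (non-constant) feature is trivially selected
    return(list(features = colnames(x), coefficients = stats::setNames(NA_real_, colnames(x)),
                lambda = NA_real_))
  }
  # cap the inner fold count so every fold keeps >= 3 observations
  k_inner <- max(3L, min(inner_folds, min(table(rp$labels)), nrow(x) %/% 3L))
  foldid <- stratified_folds(rp$labels, k_inner)
  cvfit <- glmnet::cv.glmnet(x, yy, family = "binomial", alpha = 1,
                             foldid = foldid, type.measure = "deviance",
                             standardize = FALSE)
  co <- stats::coef(cvfit, s = "lambda.min")
  co <- stats::setNames(as.numeric(co), rownames(co))[-1]
  lambda <- cvfit$lambda.min
  if (all(co == 0)) {
    df <- cvfit$glmnet.fit$df
    i <- which(df >= 1L)[1]
    if (is.na(i)) return(list(features = character(0), coefficients = numeric(0),
                              lambda = lambda))
    lambda <- cvfit$glmnet.fit$lambda[i]
    co <- stats::coef(cvfit$glmnet.fit, s = lambda)
    co <- stats::setNames(as.numeric(co), rownames(co))[-1]
  }
  sel <- co[co != 0]
  list(features = names(sel), coefficients = sel, lambda = lambda)
}

# Training-fold standardization parameters; constant columns are dropped.
standardizer <- function(x_train) {
  ctr <- colMeans(x_train)
  scl <- apply(x_train, 2, stats::sd)
  keep <- scl > 0
  list(center = ctr[keep], scale = scl[keep], keep = keep)
}

apply_standardizer <- function(std, x) {
  x <- x[, std$keep, drop = FALSE]
  sweep(sweep(x, 2, std$center), 2, std$scale, `/`)
}

#' Train on one fold and score held-out samples
#'
#' The single-fold unit of the signature evaluation: standardization
#' parameters, LASSO selection and the boosting fit are all computed on the
#' training rows only; the held-out rows are only ever transformed and
#' scored. Exposed so that fold-level audits (e.g. leakage canaries) can
#' drive it directly.
#'
#' @param x_train,x_test Numeric feature matrices with identical columns.
#' @param y_train Training labels.
#' @param rounds,depth,inner_folds See [signature_spec()].
#' @param positive Positive class.
#' @return List with `scores` (for `x_test` rows) and `selected` (feature
#'   names used by the classifier).
#' @export
fit_score_fold <- function(x_train, y_train, x_test,
                           rounds = 100L, depth = 1L, inner_folds = 10L,
                           positive = NULL) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  std <- standardizer(x_train)
  if (!any(std$keep)) return(list(scores = rep(0, nrow(x_test)), selected = character(0)))
  xtr <- apply_standardizer(std, x_train)
  xte <- apply_standardizer(std, x_test)
  sel <- suppressWarnings(lasso_select(xtr, y_train, inner_folds = inner_folds,
                                       positive = positive))
  if (length(sel$features) == 0L)
    return(list(scores = rep(0, nrow(x_test)), selected = character(0)))
  model <- fit_boosting(xtr[, sel$features, drop = FALSE], y_train,
                        rounds = rounds, depth = depth, positive = positive)
  list(scores = predict(model, xte[, sel$features, drop = FALSE]),
       selected = sel$features)
}

scope_columns <- function(feature_table, spec) {
  nm <- names(feature_table)
  pat <- switch(spec$scope,
                petct = "^(pet|ct)_", pet = "^pet_", ct = "^ct_")
  cols <- grep(pat, nm, value = TRUE)
  if (spec$include_clinical) {
    clin <- grep("^clin_", nm, value = TRUE)
    if (length(clin) == 0L) stopf("include_clinical = TRUE but no clin_* columns present; use combine_with_clinical()")
    cols <- c(cols, clin)
  }
  if (length(cols) == 0L) stopf("no feature columns match scope '%s'", spec$scope)
  cols
}

#' Evaluate a radiomic signature by repeated stratified cross-validation
#'
#' For each repeat: a stratified k-fold split is drawn; within every training
#' fold only, features are standardized, LASSO-selected and fed to the
#' boosting classifier; held-out scores are pooled over the folds of the
#' repeat and summarized by AUC, and by accuracy / sensitivity / specificity
#' at the Youden-optimal threshold. Means across repeats are reported
#' (accuracy as a percentage). Deterministic given `spec$seed`.
#'
#' @param feature_table Data frame containing the modality-prefixed feature
#'   columns (`pet_*`, `ct_*`, optionally `clin_*`); other columns are
#'   ignored.
#' @param labels Two-class vector aligned with the rows.
#' @param spec A [signature_spec()].
#' @param positive Positive class (default `"mutant"` when present).
#' @return An object of class `signature_result`: list with `scope`,
#'   `include_clinical`, `auc`, `accuracy` (%), `sensitivity`, `specificity`,
#'   `per_repeat` (data frame), `feature_frequency` (fraction of training
#'   folds selecting each feature), `spec`.
#' @export
evaluate_signature <- function(feature_table, labels, spec = signature_spec(),
                               positive = NULL) {
  stopifnot(inherits(spec, "signature_spec"))
  x <- as.matrix(as.data.frame(feature_table)[, scope_columns(feature_table, spec), drop = FALSE])
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n != length(labels)) stopf("feature rows and labels differ in length")
  if (n < spec$folds) stopf("need at least as many samples as folds")
  rp <- resolve_positive(labels, positive)
  sel_count <- stats::setNames(numeric(ncol(x)), colnames(x))
  n_fold_fits <- 0L
  per_repeat <- vector("list", spec$repeats)
  for (r in seq_len(spec$repeats)) {
    set.seed((spec$seed %% 100000L) * 1000L + r)
    fold <- stratified_folds(rp$labels, spec$folds)
    scores <- numeric(n)
    for (k in seq_len(spec$folds)) {
      te <- fold == k
      fs <- fit_score_fold(x[!te, , drop = FALSE], rp$labels[!te], x[te, , drop = FALSE],
                           rounds = spec$rounds, depth = spec$depth,
                           inner_folds = spec$inner_folds, positive = rp$positive)
      scores[te] <- fs$scores
      sel_count[fs$selected] <- sel_count[fs$selected] + 1
      n_fold_fits <- n_fold_fits + 1L
    }
    roc <- roc_auc(scores, rp$labels, positive = rp$positive, direction = "positive")
    per_repeat[[r]] <- data.frame(repeat_id = r, auc = roc$auc,
                                  accuracy = 100 * roc$accuracy,
                                  sensitivity = roc$sensitivity,
                                  specificity = roc$specificity)
  }
  per_repeat <- do.call(rbind, per_repeat)
  structure(list(scope = spec$scope, include_clinical = spec$include_clinical,
                 auc = mean(per_repeat$auc), accuracy = mean(per_repeat$accuracy),
                 sensitivity = mean(per_repeat$sensitivity),
                 specificity = mean(per_repeat$specificity),
                 per_repeat = per_repeat,
                 feature_frequency = sort(sel_count / n_fold_fits, decreasing = TRUE),
                 spec = spec),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("Radiomic signature [%s%s]: AUC %.3f, accuracy %.3f%%, sensitivity %.3f, specificity %.3f (%d-fold CV x %d repeats)\n",
              toupper(x$scope), if (x$include_clinical) " + clinical" else "",
              x$auc, x$accuracy, x$sensitivity, x$specificity,
              x$spec$folds, x$spec$repeats))
  top <- utils::head(x$feature_frequency[x$feature_frequency > 0], 8)
  if (length(top)) cat("  top selected features:",
                       paste(sprintf("%s (%.0f%%)", names(top), 100 * top), collapse = ", "), "\n")
  invisible(x)
}

#' Append clinical covariates to a radiomic feature table
#'
#' Adds seven `clin_*` columns: age (numeric), male gender, smoking and
#' advanced stage (binary), and lesion location dummies for the
#' middle / lower / overlapping lobes (upper lobe is the reference level).
#' Rows are matched by `patient_id` and must align exactly.
#'
#' @param feature_table Data frame with a `patient_id` column.
#' @param cohort_table Clinical covariate table with columns `patient_id`,
#'   `age`, `gender`, `smoking`, `stage`, `location`.
#' @return `feature_table` with the clinical columns appended.
#' @export
combine_with_clinical <- function(feature_table, cohort_table) {
  need <- c("patient_id", "age", "gender", "smoking", "stage", "location")
  miss <- setdiff(need, names(cohort_table))
  if (length(miss)) stopf("cohort table is missing covariate(s): %s", paste(miss, collapse = ", "))
  if (!identical(as.character(feature_table$patient_id), as.character(cohort_table$patient_id)))
    stopf("patient_id mismatch between feature table and cohort table")
  if (anyNA(cohort_table[need])) stopf("missing covariate values")
  loc <- factor(cohort_table$location, levels = c("upper", "middle", "lower", "overlapping"))
  if (anyNA(loc)) stopf("unknown lesion location value(s)")
  cbind(feature_table,
        clin_age = as.numeric(cohort_table$age),
        clin_male = as.numeric(cohort_table$gender == "male"),
        clin_smoker = as.numeric(cohort_table$smoking == "yes"),
        clin_stage_advanced = as.numeric(cohort_table$stage == "III-IV"),
        clin_loc_middle = as.numeric(loc == "middle"),
        clin_loc_lower = as.numeric(loc == "lower"),
        clin_loc_overlapping = as.numeric(loc == "overlapping"))
}

#' Descriptive full-cohort LASSO selection
#'
#' A single LASSO pass over the whole cohort (after standardization),
#' mirroring the descriptive "identified features" report; honest performance
#' estimates come from [evaluate_signature()], which re-selects per training
#' fold.
#'
#' @inheritParams evaluate_signature
#' @param seed Seed for the penalty search folds.
#' @return The [lasso_select()] result.
#' @export
describe_selected_features <- function(feature_table, labels, spec = signature_spec(),
                                       seed = 1L, positive = NULL) {
  x <- as.matrix(as.data.frame(feature_table)[, scope_columns(feature_table, spec), drop = FALSE])
  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  x <- x[, keep, drop = FALSE]
  x <- scale(x)
  set.seed(seed)
  lasso_select(x, labels, inner_folds = spec$inner_folds, positive = positive)
}
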