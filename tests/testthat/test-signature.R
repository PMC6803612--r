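# standardize, mapping constant columns to zero instead of NaN
scale_keep <- function(x) {
  s <- scale(x)
  s[is.nan(s)] <- 0
  s
}

test_that("boosting reaches perfect training accuracy on a separable toy set", {
  set.seed(21)
  x <- cbind(f1 = c(rnorm(20, -2), rnorm(20, 2)), f2 = rnorm(40))
  y <- rep(c("wild", "mutant"), each = 20)
  m <- fit_boosting(x, y, rounds = 20)
  score <- predict(m, x)
  expect_equal(mean((score > 0) == (y == "mutant")), 1)
})

test_that("boosting scores are invariant to monotone feature rescaling", {
  set.seed(22)
  x <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- ifelse(x[, 1] + 0.8 * rnorm(60) > 0, "mutant", "wild")
  m1 <- fit_boosting(x, y, rounds = 30)
  x2 <- x
  x2[, 1] <- exp(x2[, 1])          # strictly increasing transform
  x2[, 2] <- 100 * x2[, 2] + 3
  m2 <- fit_boosting(x2, y, rounds = 30)
  expect_equal(predict(m1, x), predict(m2, x2))
})

test_that("boosting rejects single-class input and stays deterministic", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_boosting(x, rep("mutant", 10)), "two classes")
  set.seed(1); y <- sample(c("mutant", "wild"), 10, TRUE)
  m1 <- fit_boosting(x, y, rounds = 10)
  m2 <- fit_boosting(x, y, rounds = 10)
  expect_identical(predict(m1, x), predict(m2, x))
})

test_that("LASSO recovers a planted informative feature", {
  hits <- 0
  for (s in 1:50) {
    set.seed(s)
    n <- 100
    y <- rep(c("mutant", "wild"), each = n / 2)
    x <- cbind(signal = ifelse(y == "mutant", 1, -1) * 1.5 + rnorm(n) * 0.5,
               matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("n", 1:20))))
    x <- scale(x)
    sel <- lasso_select(x, y)
    if ("signal" %in% sel$features) hits <- hits + 1
  }
  expect_gt(hits / 50, 0.9)
})

test_that("LASSO handles constant and duplicated columns", {
  set.seed(30)
  n <- 80
  y <- rep(c("mutant", "wild"), each = n / 2)
  base <- ifelse(y == "mutant", 1, -1) + rnorm(n) * 0.6
  x <- cbind(a = base, a_copy = base, flat = rep(0, n),
             noise = rnorm(n))
  expect_warning(sel <- lasso_select(scale_keep(x), y), "constant")
  expect_true(any(c("a", "a_copy") %in% sel$features))
  expect_gte(length(sel$features), 1)

  # all-constant input: nothing selectable
  allflat <- matrix(1, n, 3, dimnames = list(NULL, c("c1", "c2", "c3")))
  expect_warning(sel2 <- lasso_select(allflat, y), "constant")
  expect_length(sel2$features, 0)
})

test_that("signature evaluation is deterministic and shaped by the spec", {
  cf <- cached_cohort_features()
  spec <- signature_spec("pet", folds = 5, repeats = 2, rounds = 25, seed = 42)
  r1 <- evaluate_signature(cf$features, cf$labels, spec)
  r2 <- evaluate_signature(cf$features, cf$labels, spec)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_equal(nrow(r1$per_repeat), 2)
  expect_true(r1$auc >= 0 && r1$auc <= 1)
  expect_true(r1$accuracy >= 0 && r1$accuracy <= 100)
  expect_named(r1$feature_frequency)

  single <- evaluate_signature(cf$features, cf$labels,
                               signature_spec("pet", folds = 5, repeats = 1,
                                              rounds = 25, seed = 42))
  expect_equal(single$per_repeat$auc, r1$per_repeat$auc[1])
})

test_that("permuted labels drive the cross-validated AUC to chance", {
  cf <- cached_cohort_features()
  set.seed(55)
  aucs <- vapply(1:5, function(s) {
    perm <- sample(cf$labels)
    evaluate_signature(cf$features, perm,
                       signature_spec("pet", folds = 5, repeats = 1,
                                      rounds = 25, seed = s))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("clinical covariates append exactly seven aligned columns", {
  cf <- cached_cohort_features()
  aug <- combine_with_clinical(cf$features, cf$cohort$cohort_table)
  expect_equal(ncol(aug), ncol(cf$features) + 7)
  expect_equal(sum(grepl("^clin_", names(aug))), 7)
  expect_equal(sum(grepl("^(pet|ct)_", names(aug))), 38 * 2)

  shuffled <- cf$cohort$cohort_table[rev(seq_len(nrow(cf$cohort$cohort_table))), ]
  expect_error(combine_with_clinical(cf$features, shuffled), "mismatch")
  broken <- cf$cohort$cohort_table
  broken$smoking <- NULL
  expect_error(combine_with_clinical(cf$features, broken), "missing covariate")
})

test_that("scope filtering selects the matching feature columns", {
  cf <- cached_cohort_features()
  aug <- combine_with_clinical(cf$features, cf$cohort$cohort_table)
  expect_length(petradiomics:::scope_columns(aug, signature_spec("pet")), 38)
  expect_length(petradiomics:::scope_columns(aug, signature_spec("ct")), 38)
  expect_length(petradiomics:::scope_columns(aug, signature_spec("petct")), 76)
  expect_length(petradiomics:::scope_columns(aug, signature_spec("petct", include_clinical = TRUE)), 83)
  expect_error(petradiomics:::scope_columns(cf$features, signature_spec("pet", include_clinical = TRUE)),
               "clin_")
})

test_that("fold-level training never sees held-out rows (leakage canary)", {
  set.seed(61)
  n <- 200
  y <- rep(c("mutant", "wild"), n / 2)
  folds <- rep(1:5, each = n / 5)
  # canary: equals the label on a fold's rows only when that fold is held out
  noise <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("x", 1:3)))
  scores <- numeric(n)
  for (k in 1:5) {
    te <- folds == k
    x <- cbind(noise, canary = rnorm(n))
    x[te, "canary"] <- ifelse(y[te] == "mutant", 1, -1)  # informative in test rows only
    fs <- fit_score_fold(x[!te, ], y[!te], x[te, ], rounds = 30)
    scores[te] <- fs$scores
  }
  auc_canary <- roc_auc(scores, y)$auc
  expect_lt(abs(auc_canary - 0.5), 0.15)

  # a genuinely informative feature is learned and scores near-perfectly
  x_good <- cbind(noise, signal = ifelse(y == "mutant", 1, -1) + 0.2 * rnorm(n))
  scores2 <- numeric(n)
  for (k in 1:5) {
    te <- folds == k
    fs <- fit_score_fold(x_good[!te, ], y[!te], x_good[te, ], rounds = 30)
    scores2[te] <- fs$scores
  }
  expect_gt(roc_auc(scores2, y)$auc, 0.95)
})

test_that("full-cohort descriptive selection reports a nonempty feature set", {
  cf <- cached_cohort_features()
  sel <- describe_selected_features(cf$features, cf$labels, signature_spec("petct"), seed = 3)
  expect_gte(length(sel$features), 1)
  expect_true(all(sel$features %in% c(radiomic_feature_names("pet"),
                                      radiomic_feature_names("ct"))))
})
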