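#' Adaptive boosting of decision stumps
#'
#' Discrete AdaBoost: at each round the threshold stump (axis-aligned split
#' `x_j > t` with either polarity) minimizing the weighted 0-1 error is fit,
#' misclassified samples are up-weighted by `exp(alpha)`, and the ensemble
#' score is the alpha-weighted vote `sum_t alpha_t h_t(x)`. Stumps are
#' threshold-based, so the score is invariant to any strictly increasing
#' monotone rescaling of individual features. Training stops early when a
#' round's weighted error reaches 0 or 0.5. For `depth > 1`, depth-limited
#' `rpart` classification trees are used as weak learners instead of the
#' built-in stump search.
#'
#' @param x Numeric matrix (samples x features).
#' @param y Two-class label vector.
#' @param rounds Number of boosting rounds (default 100).
#' @param depth Weak-learner depth (default 1 = stumps).
#' @param positive Positive class (see [roc_auc()]).
#' @return An object of class `boost_model`.
#' @export
fit_boosting <- function(x, y, rounds = 100L, depth = 1L, positive = NULL) {
  x <- as.matrix(x)
  rp <- resolve_positive(y, positive)
  yy <- ifelse(rp$labels == rp$positive, 1, -1)
  n <- nrow(x)
  if (n != length(yy)) stopf("x and y sizes differ")
  if (depth > 1L && !requireNamespace("rpart", quietly = TRUE))
    stopf("depth > 1 requires the rpart package")
  w <- rep(1 / n, n)
  learners <- vector("list", rounds)
  alphas <- numeric(rounds)
  used <- 0L
  for (t in seq_len(rounds)) {
    if (depth == 1L) {
      st <- best_stump(x, yy, w)
      h <- stump_predict(st, x)
    } else {
      df <- data.frame(y = factor(yy), x)
      st <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                         control = rpart::rpart.control(maxdepth = depth, cp = 0,
                                                        minsplit = 2, xval = 0))
      h <- ifelse(predict(st, df, type = "class") == "1", 1, -1)
    }
    err <- sum(w[h != yy])
    if (err >= 0.5 - 1e-12) break
    err_c <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err_c) / err_c)
    used <- used + 1L
    learners[[used]] <- st
    alphas[used] <- alpha
    if (err <= 1e-12) break
    w <- w * exp(-alpha * yy * h)
    w <- w / sum(w)
  }
  if (used == 0L) {
    # no stump beats chance: fall back to the majority-class constant score
    learners[[1]] <- list(feature = NA_integer_, threshold = -Inf,
                          polarity = if (mean(yy) >= 0) 1 else -1)
    alphas[1] <- 1e-3
    used <- 1L
  }
  structure(list(learners = learners[seq_len(used)], alphas = alphas[seq_len(used)],
                 depth = depth, positive = rp$positive,
                 feature_names = colnames(x)),
            class = "boost_model")
}

# Best weighted threshold stump over all features and both polarities.
# Rule: predict `polarity` when x[, feature] > threshold, `-polarity` otherwise.
best_stump <- function(x, yy, w) {
  n <- nrow(x)
  wp <- w * (yy > 0)
  wn <- w * (yy < 0)
  Wp <- sum(wp); Wn <- sum(wn)
  best <- list(err = Inf)
  for (j in seq_len(ncol(x))) {
    xs <- x[, j]
    ord <- order(xs)
    sx <- xs[ord]
    cp <- cumsum(wp[ord])   # positive weight at or below cut k
    cn <- cumsum(wn[ord])
    valid <- c(sx[-n] < sx[-1], TRUE)   # cuts between distinct values, plus k = n
    ks <- c(0L, which(valid))
    # polarity +1 (x > t -> +1): err(k) = pos weight below cut + neg weight above
    e_pos <- c(Wn, cp[ks[-1]] + (Wn - cn[ks[-1]]))
    errs <- pmin(e_pos, 1 - e_pos)      # polarity -1 error is the complement (weights sum to 1)
    i <- which.min(errs)
    if (errs[i] < best$err - 1e-15) {
      k <- ks[i]
      thr <- if (k == 0L) -Inf else if (k == n) Inf else (sx[k] + sx[k + 1]) / 2
      best <- list(err = errs[i], feature = j, threshold = thr,
                   polarity = if (e_pos[i] <= 1 - e_pos[i]) 1 else -1)
    }
  }
  list(feature = best$feature, threshold = best$threshold, polarity = best$polarity)
}

stump_predict <- function(st, x) {
  st$polarity * ifelse(x[, st$feature] > st$threshold, 1, -1)
}

#' Continuous ensemble score of a boosting model
#'
#' The normalized ensemble margin `sum_t alpha_t h_t(x) / sum_t alpha_t`,
#' in `[-1, 1]`; positive values favour the positive class. Normalizing by
#' the total vote weight makes scores comparable across models trained on
#' different folds (whose selected features and learner counts differ), which
#' matters when held-out scores are pooled before ROC analysis. Set
#' `normalize = FALSE` for the raw weighted vote.
#'
#' @param object A `boost_model`.
#' @param newdata Numeric matrix with the training feature columns.
#' @param normalize Divide by the total alpha weight (default `TRUE`).
#' @param ... Unused.
#' @return Numeric score vector.
#' @export
predict.boost_model <- function(object, newdata, normalize = TRUE, ...) {
  newdata <- as.matrix(newdata)
  score <- numeric(nrow(newdata))
  for (t in seq_along(object$learners)) {
    h <- if (object$depth == 1L) {
      st <- object$learners[[t]]
      if (is.na(st$feature)) rep(st$polarity, nrow(newdata)) else stump_predict(st, newdata)
    } else {
      df <- data.frame(newdata)
      ifelse(predict(object$learners[[t]], df, type = "class") == "1", 1, -1)
    }
    score <- score + object$alphas[t] * h
  }
  if (normalize) score <- score / sum(object$alphas)
  score
}
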