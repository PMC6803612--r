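#' Two-sided Wilcoxon rank-sum test
#'
#' Midrank tie handling; the exact null distribution is enumerated when the
#' combined sample size is at most 10 and there are no ties, otherwise the
#' normal approximation with continuity correction is used.
#'
#' @param x,y Numeric vectors, each with at least one observation.
#' @return List with `statistic` (the rank-sum W of `x`), `p_value`, and
#'   `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stopf("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 10L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = min(wt$p.value, 1), exact = exact)
}

#' Benjamini-Hochberg step-up false-discovery-rate adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q Significance threshold on the adjusted values (default 0.10).
#' @return List with `q_values` (monotone BH-adjusted values) and `reject`
#'   (logical, `q_values <= q`).
#' @export
bh_fdr <- function(p, q = 0.10) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  qv <- stats::p.adjust(p, method = "BH")
  list(q_values = qv, reject = qv <= q)
}

#' Per-feature two-group comparison with FDR control
#'
#' Wilcoxon rank-sum test per feature column, Benjamini-Hochberg adjustment
#' across features, significance flag at FDR `q`.
#'
#' @param features Data frame or matrix of numeric feature columns.
#' @param labels Two-level grouping vector aligned with the rows.
#' @param q FDR threshold (default 0.10).
#' @return Data frame: `feature`, `statistic`, `p_value`, `q_value`,
#'   `significant`.
#' @export
compare_features <- function(features, labels, q = 0.10) {
  features <- as.data.frame(features)
  lv <- unique(labels)
  if (length(lv) != 2L) stopf("labels must have exactly two levels")
  res <- lapply(names(features), function(nm) {
    v <- features[[nm]]
    w <- wilcoxon_rank_sum(v[labels == lv[1]], v[labels == lv[2]])
    data.frame(feature = nm, statistic = w$statistic, p_value = w$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  adj <- bh_fdr(out$p_value, q)
  out$q_value <- adj$q_values
  out$significant <- adj$reject
  out
}

#' Spearman correlation grid between two feature sets
#'
#' Rank correlation (midrank ties) for every (column of `x`, column of `y`)
#' pair, with two-sided p-values from the t approximation. A constant column
#' yields correlation 0 with p = 1 (with a warning).
#'
#' @param x,y Data frames or matrices with the same number of rows (>= 3).
#' @return List with matrices `r` and `p` (rows = columns of `x`, cols =
#'   columns of `y`).
#' @export
spearman_matrix <- function(x, y) {
  x <- as.data.frame(x); y <- as.data.frame(y)
  if (nrow(x) != nrow(y)) stopf("x and y must have the same number of rows")
  if (nrow(x) < 3L) stopf("need at least 3 paired observations")
  r <- matrix(NA_real_, ncol(x), ncol(y), dimnames = list(names(x), names(y)))
  p <- r
  warned <- FALSE
  for (i in seq_len(ncol(x))) for (j in seq_len(ncol(y))) {
    xi <- x[[i]]; yj <- y[[j]]
    if (stats::sd(xi) == 0 || stats::sd(yj) == 0) {
      r[i, j] <- 0; p[i, j] <- 1
      warned <- TRUE
    } else {
      ct <- suppressWarnings(stats::cor.test(xi, yj, method = "spearman", exact = FALSE))
      r[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
    }
  }
  if (warned) warning("constant column(s): correlation defined as 0 with p = 1")
  list(r = r, p = p)
}

resolve_positive <- function(labels, positive = NULL) {
  if (is.logical(labels)) labels <- ifelse(labels, "TRUE", "FALSE")
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stopf("labels must contain exactly two classes")
  if (is.null(positive)) {
    positive <- if ("mutant" %in% lv) "mutant" else if ("TRUE" %in% lv) "TRUE" else sort(lv)[2]
  }
  if (!positive %in% lv) stopf("positive class '%s' not present in labels", positive)
  list(labels = labels, positive = positive)
}

#' ROC analysis of a continuous score
#'
#' AUC by the Mann-Whitney pairwise-concordance formula (ties receive 0.5
#' credit), the Youden-optimal operating point (score >= threshold classified
#' positive), and the Noether test of AUC > 0.5 (see [noether_auc_test()]).
#' With `direction = "auto"` the score is negated when the raw AUC is below
#' 0.5, so the reported AUC lies in `[0.5, 1]`.
#'
#' @param scores Numeric vector.
#' @param labels Two-class vector aligned with `scores`.
#' @param positive Positive class (default: `"mutant"` if present, else the
#'   lexicographically larger level; `TRUE` for logical labels).
#' @param direction `"positive"` (higher score = positive class, default) or
#'   `"auto"`.
#' @return An object of class `roc_result`: list with `auc`, `p_value` (one-
#'   sided Noether), `sensitivity`, `specificity`, `accuracy`, `threshold`,
#'   `flipped`.
#' @export
roc_auc <- function(scores, labels, positive = NULL, direction = c("positive", "auto")) {
  direction <- match.arg(direction)
  rp <- resolve_positive(labels, positive)
  pos <- rp$labels == rp$positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  auc <- auc_mann_whitney(scores, pos)
  flipped <- FALSE
  if (direction == "auto" && auc < 0.5) {
    scores <- -scores
    auc <- 1 - auc
    flipped <- TRUE
  }
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), numeric(1))
  k <- which.max(sens + spec)
  acc <- (sum(scores[pos] >= thr[k]) + sum(scores[!pos] < thr[k])) / (n1 + n0)
  nt <- noether_auc_test(scores, rp$labels, positive = rp$positive)
  structure(list(auc = auc, p_value = nt$p_value,
                 sensitivity = sens[k], specificity = spec[k], accuracy = acc,
                 threshold = thr[k], flipped = flipped),
            class = "roc_result")
}

auc_mann_whitney <- function(scores, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (Noether one-sided p = %.3g); sens %.3f spec %.3f acc %.1f%% @ threshold %.4g\n",
              x$auc, x$p_value, x$sensitivity, x$specificity, 100 * x$accuracy, x$threshold))
  invisible(x)
}

#' Noether test of AUC against chance (0.5)
#'
#' Nonparametric z-test of whether the AUC exceeds 0.5, with the DeLong
#' structural-components variance estimate:
#' `var = var(V10)/n1 + var(V01)/n0`, where `V10`/`V01` are the per-subject
#' placement values. One-sided p for AUC > 0.5. When the placement variance
#' degenerates (perfect separation), the standard error falls back to the
#' continuity bound `1/sqrt(n1 n0)` with a message.
#'
#' @param scores Numeric vector.
#' @param labels Two-class vector; each class needs >= 2 observations.
#' @param positive Positive class (see [roc_auc()]).
#' @return List with `auc`, `z`, `se`, `p_value`.
#' @export
noether_auc_test <- function(scores, labels, positive = NULL) {
  rp <- resolve_positive(labels, positive)
  pos <- rp$labels == rp$positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 < 2L || n0 < 2L) stopf("need at least 2 observations per class")
  xs <- scores[pos]; ys <- scores[!pos]
  cmp <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(cmp)
  v10 <- rowMeans(cmp)
  v01 <- colMeans(cmp)
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  if (!is.finite(se) || se < 1e-12) {
    message("degenerate placement variance; using the continuity bound 1/sqrt(n1*n0)")
    se <- 1 / sqrt(n1 * n0)
  }
  z <- (auc - 0.5) / se
  list(auc = auc, z = z, se = se, p_value = stats::pnorm(z, lower.tail = FALSE))
}

#' Per-feature ROC screening table
#'
#' Whole-cohort AUC (auto-oriented into `[0.5, 1]`) and one-sided Noether
#' p-value for every feature column.
#'
#' @inheritParams compare_features
#' @return Data frame: `feature`, `auc`, `p_value`, `sensitivity`,
#'   `specificity`.
#' @export
roc_table <- function(features, labels, positive = NULL) {
  features <- as.data.frame(features)
  rows <- lapply(names(features), function(nm) {
    r <- roc_auc(features[[nm]], labels, positive = positive, direction = "auto")
    data.frame(feature = nm, auc = r$auc, p_value = r$p_value,
               sensitivity = r$sensitivity, specificity = r$specificity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
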