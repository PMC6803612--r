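# Texture feature families: gray-level quantization, grayscale statistics
# (GSS), gray-level co-occurrence (GLCM), gray level-gradient co-occurrence
# (GGCM) and gray-level difference statistics (GLDS). All statistics are
# restricted to in-mask pixels; pixel pairs crossing the mask boundary are
# excluded. Logarithms are base 2 with the 0*log(0) := 0 convention.

xlog2x <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Quantize in-mask intensities to G gray levels
#'
#' Equal-width binning of the in-mask intensity range `[min, max]` into `G`
#' bins, mapped to levels `0 .. G-1`. A constant region maps entirely to level
#' 0. The mapping depends only on the relative position of each intensity in
#' the range, so any strictly increasing affine rescaling of the intensities
#' leaves the levels unchanged.
#'
#' @param intensities Numeric matrix (the analysis slice).
#' @param mask Logical matrix, same shape; at least one in-mask pixel.
#' @param G Number of gray levels (default 16).
#' @return An object of class `quantized_roi`: list with `levels` (integer
#'   matrix, `NA` outside the mask), `mask`, and `G`.
#' @export
quantize_roi <- function(intensities, mask, G = 16L) {
  if (!is.matrix(intensities) || !is.matrix(mask) || !all(dim(intensities) == dim(mask)))
    stopf("intensities and mask must be matrices of identical shape")
  mask <- mask > 0
  if (!any(mask)) stopf("empty mask")
  G <- as.integer(G)
  vals <- intensities[mask]
  rng <- range(vals)
  lv <- matrix(NA_integer_, nrow(mask), ncol(mask))
  if (diff(rng) < .Machine$double.eps * max(abs(rng), 1)) {
    lv[mask] <- 0L
  } else {
    q <- floor((vals - rng[1]) / diff(rng) * G)
    q[q >= G] <- G - 1L
    lv[mask] <- as.integer(q)
  }
  structure(list(levels = lv, mask = mask, G = G), class = "quantized_roi")
}

#' Grayscale statistical features
#'
#' Nine first-order features of the in-mask intensity distribution: mean,
#' standard deviation, skewness, kurtosis (non-excess), the raw 5th and 6th
#' central moments (all population / biased moments), histogram energy and
#' entropy (computed on the `G`-bin quantized histogram), and gray span
#' (max - min of the raw intensities). Skewness and kurtosis of a constant
#' region are defined as 0.
#'
#' @param intensities Numeric matrix.
#' @param mask Logical matrix; at least one in-mask pixel.
#' @param G Gray-level count for the histogram-based energy/entropy.
#' @return Named numeric vector of length 9.
#' @export
compute_gss <- function(intensities, mask, G = 16L) {
  mask <- mask > 0
  if (!any(mask)) stopf("empty mask")
  x <- intensities[mask]
  n <- length(x)
  mu <- mean(x)
  cm <- function(k) sum((x - mu)^k) / n
  m2 <- cm(2)
  sdev <- sqrt(m2)
  skew <- if (m2 > 0) cm(3) / m2^1.5 else 0
  kurt <- if (m2 > 0) cm(4) / m2^2 else 0
  q <- quantize_roi(intensities, mask, G)
  p <- tabulate(q$levels[mask] + 1L, nbins = q$G) / n
  c(mean = mu, sd = sdev, skewness = skew, kurtosis = kurt,
    cm5 = cm(5), cm6 = cm(6),
    energy = sum(p^2), entropy = -sum(xlog2x(p)),
    span = max(x) - min(x))
}

# Offsets (row, col) for the four co-occurrence angles at a given distance.
# 0 deg scans along the row (columns), 90 deg along the column.
glcm_offsets <- function(distance = 1L) {
  d <- as.integer(distance)
  list(`0` = c(0L, d), `45` = c(-d, d), `90` = c(-d, 0L), `135` = c(-d, -d))
}

#' Symmetric gray-level co-occurrence matrix for one offset
#'
#' Counts ordered level pairs `(levels[r, c], levels[r + dr, c + dc])` over
#' pixel positions where both ends are in-mask, symmetrizes (both directions),
#' and normalizes to sum 1.
#'
#' @param q A [quantize_roi()] result.
#' @param offset Integer `(dr, dc)` pixel offset.
#' @return `G x G` matrix summing to 1, or `NULL` when no valid pair exists.
#' @export
glcm_matrix <- function(q, offset) {
  stopifnot(inherits(q, "quantized_roi"))
  G <- q$G
  ok <- q$mask & shift2(q$mask, -offset)   # position p such that p + offset is in-mask
  if (!any(ok)) return(NULL)
  a <- q$levels[ok]
  lv_to <- shift2(q$levels, -offset)
  b <- lv_to[ok]
  cnt <- matrix(tabulate(a * G + b + 1L, nbins = G * G), G, G, byrow = TRUE)
  cnt <- cnt + t(cnt)
  cnt / sum(cnt)
}

glcm_features_one <- function(p) {
  G <- nrow(p)
  i <- matrix(0:(G - 1), G, G)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((0:(G - 1)) * px); muy <- sum((0:(G - 1)) * py)
  sx <- sqrt(sum(((0:(G - 1)) - mux)^2 * px))
  sy <- sqrt(sum(((0:(G - 1)) - muy)^2 * py))
  corr <- if (sx > 1e-12 && sy > 1e-12)
    sum((i - mux) * (j - muy) * p) / (sx * sy) else 0
  c(asm = sum(p^2),
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    entropy = -sum(xlog2x(p)),
    homogeneity = sum(p / (1 + (i - j)^2)),
    dissimilarity = sum(abs(i - j) * p))
}

#' Gray-level co-occurrence features (4-angle average)
#'
#' Builds the symmetric, normalized co-occurrence matrix at angles 0, 45, 90
#' and 135 degrees (distance `distance`, default 1 pixel), restricted to
#' in-mask pixel pairs, computes ASM, contrast, correlation, entropy,
#' homogeneity and dissimilarity for each angle, and reports the mean over the
#' angles. Correlation of a zero-variance marginal is defined as 0. Angles
#' with no valid pair are dropped from the mean with a warning.
#'
#' @param q A [quantize_roi()] result.
#' @param distance Pixel offset distance (default 1).
#' @return Named numeric vector of length 6.
#' @export
compute_glcm_features <- function(q, distance = 1L) {
  per_angle <- lapply(glcm_offsets(distance), function(off) {
    p <- glcm_matrix(q, off)
    if (is.null(p)) NULL else glcm_features_one(p)
  })
  keep <- !vapply(per_angle, is.null, logical(1))
  if (!any(keep)) stopf("no valid co-occurrence pairs in the mask")
  if (!all(keep)) warning("co-occurrence angles without valid pairs were dropped from the mean")
  colMeans(do.call(rbind, per_angle[keep]))
}

#' Gray-level difference statistics (4-displacement average)
#'
#' For each displacement delta = (dx, dy) in (0,1), (1,1), (1,0), (1,-1)
#' (x = column, y = row), forms the absolute level differences
#' `|f(x, y) - f(x + dx, y + dy)|` over pixel pairs fully in-mask, normalizes
#' the difference histogram `p(d)`, and computes mean, contrast
#' (`sum d^2 p(d)`), ASM and entropy; the four displacement values are
#' averaged. Displacements with no valid pair are dropped with a warning.
#'
#' @param q A [quantize_roi()] result.
#' @param displacements List of `(dx, dy)` integer pairs.
#' @return Named numeric vector of length 4.
#' @export
compute_glds_features <- function(q,
                                  displacements = list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))) {
  stopifnot(inherits(q, "quantized_roi"))
  G <- q$G
  per_d <- lapply(displacements, function(d) {
    off <- c(d[2], d[1])  # (dx, dy) -> (row, col) offset
    ok <- q$mask & shift2(q$mask, -off)
    if (!any(ok)) return(NULL)
    lv_to <- shift2(q$levels, -off)
    dd <- abs(q$levels[ok] - lv_to[ok])
    p <- tabulate(dd + 1L, nbins = G) / length(dd)
    dvals <- 0:(G - 1)
    c(mean = sum(dvals * p), contrast = sum(dvals^2 * p),
      asm = sum(p^2), entropy = -sum(xlog2x(p)))
  })
  keep <- !vapply(per_d, is.null, logical(1))
  if (!any(keep)) stopf("no valid difference pairs in the mask")
  if (!all(keep)) warning("displacements without valid pairs were dropped from the mean")
  colMeans(do.call(rbind, per_d[keep]))
}

# 3x3 Sobel gradient magnitude of a matrix (valid only where the full 3x3
# neighbourhood exists; callers restrict to eroded masks).
sobel_magnitude <- function(m) {
  gx <- shift2(m, c(0L, -1L)) - shift2(m, c(0L, 1L))
  gx <- gx + 0.5 * (shift2(m, c(-1L, -1L)) - shift2(m, c(-1L, 1L)) +
                    shift2(m, c(1L, -1L)) - shift2(m, c(1L, 1L)))
  gx <- 2 * gx
  gy <- shift2(m, c(-1L, 0L)) - shift2(m, c(1L, 0L))
  gy <- gy + 0.5 * (shift2(m, c(-1L, -1L)) - shift2(m, c(1L, -1L)) +
                    shift2(m, c(-1L, 1L)) - shift2(m, c(1L, 1L)))
  gy <- 2 * gy
  sqrt(gx^2 + gy^2)
}

#' Joint gray level / gradient histogram
#'
#' Gradient magnitude is computed with 3x3 Sobel stencils at pixels whose full
#' 3x3 neighbourhood is in-mask; gray levels are quantized to `G` bins over the
#' in-mask intensity range, gradient magnitudes to `Gs` equal-width bins over
#' `[0, max in-mask gradient]`. Returns the normalized joint histogram over
#' the stencil-valid pixels.
#'
#' @param intensities Numeric matrix.
#' @param mask Logical matrix.
#' @param G,Gs Gray and gradient bin counts (default 16 each).
#' @return List with `p` (`G x Gs` matrix summing to 1), `gray_levels`,
#'   `grad_levels` and `interior` (the stencil-valid mask).
#' @export
ggcm_matrix <- function(intensities, mask, G = 16L, Gs = 16L) {
  mask <- mask > 0
  interior <- erode_mask2(mask)
  if (!any(interior)) stopf("mask too small for a 3x3 gradient stencil")
  grad <- sobel_magnitude(intensities)
  gvals <- grad[interior]
  gmax <- max(gvals)
  if (gmax <= 0) {
    gl <- rep(0L, length(gvals))
  } else {
    gl <- as.integer(floor(gvals / gmax * Gs))
    gl[gl >= Gs] <- Gs - 1L
  }
  q <- quantize_roi(intensities, mask, G)
  il <- q$levels[interior]
  cnt <- matrix(tabulate(il * Gs + gl + 1L, nbins = G * Gs), G, Gs, byrow = TRUE)
  list(p = cnt / sum(cnt), gray_levels = il, grad_levels = gl, interior = interior)
}

#' Gray level-gradient co-occurrence features
#'
#' The 15 canonical features of the normalized joint gray/gradient histogram
#' `p(i, j)` (gray level `i = 0..G-1`, gradient level `j = 0..Gs-1`):
#' small-gradient dominance `sum p/(j+1)^2`, big-gradient dominance
#' `sum p j^2`, gray and gradient (distribution) asymmetry
#' `sum_i (sum_j p)^2` / `sum_j (sum_i p)^2`, energy, gray and gradient
#' marginal means and variances, correlation (0 when a marginal is
#' degenerate), gray/gradient/mixed entropies, inertia `sum (i-j)^2 p` and
#' inverse difference moment `sum p/(1+(i-j)^2)`.
#'
#' @inheritParams ggcm_matrix
#' @return Named numeric vector of length 15.
#' @export
compute_ggcm_features <- function(intensities, mask, G = 16L, Gs = 16L) {
  p <- ggcm_matrix(intensities, mask, G, Gs)$p
  gi <- matrix(0:(G - 1), G, Gs)
  gj <- matrix(0:(Gs - 1), G, Gs, byrow = TRUE)
  pi_ <- rowSums(p); pj <- colSums(p)
  mu_i <- sum((0:(G - 1)) * pi_); mu_j <- sum((0:(Gs - 1)) * pj)
  var_i <- sum(((0:(G - 1)) - mu_i)^2 * pi_)
  var_j <- sum(((0:(Gs - 1)) - mu_j)^2 * pj)
  corr <- if (var_i > 1e-24 && var_j > 1e-24)
    sum((gi - mu_i) * (gj - mu_j) * p) / sqrt(var_i * var_j) else 0
  c(small_grad_dominance = sum(p / (gj + 1)^2),
    big_grad_dominance = sum(p * gj^2),
    gray_asymmetry = sum(pi_^2),
    grad_asymmetry = sum(pj^2),
    energy = sum(p^2),
    gray_mean = mu_i,
    grad_mean = mu_j,
    gray_variance = var_i,
    grad_variance = var_j,
    correlation = corr,
    gray_entropy = -sum(xlog2x(pi_)),
    grad_entropy = -sum(xlog2x(pj)),
    mixed_entropy = -sum(xlog2x(p)),
    inertia = sum((gi - gj)^2 * p),
    idm = sum(p / (1 + (gi - gj)^2)))
}
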