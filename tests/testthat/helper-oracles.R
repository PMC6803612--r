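# Independent brute-force oracles used to verify the texture, morphology and
# ROC implementations. These deliberately use naive per-pixel loops and direct
# formula transcriptions, sharing no code with the package internals.

# Symmetric normalized co-occurrence matrix by exhaustive pixel enumeration.
oracle_glcm_matrix <- function(levels, mask, G, offset) {
  cnt <- matrix(0, G, G)
  nr <- nrow(levels); nc <- ncol(levels)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + offset[1]; c2 <- c + offset[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    if (!mask[r, c] || !mask[r2, c2]) next
    i <- levels[r, c] + 1; j <- levels[r2, c2] + 1
    cnt[i, j] <- cnt[i, j] + 1
    cnt[j, i] <- cnt[j, i] + 1
  }
  if (sum(cnt) == 0) return(NULL)
  cnt / sum(cnt)
}

oracle_glcm_features <- function(p) {
  G <- nrow(p)
  asm <- 0; contrast <- 0; entropy <- 0; homog <- 0; dissim <- 0
  for (i in 1:G) for (j in 1:G) {
    v <- p[i, j]
    asm <- asm + v^2
    contrast <- contrast + (i - j)^2 * v
    if (v > 0) entropy <- entropy - v * log2(v)
    homog <- homog + v / (1 + (i - j)^2)
    dissim <- dissim + abs(i - j) * v
  }
  px <- rowSums(p); py <- colSums(p)
  mx <- sum((1:G) * px); my <- sum((1:G) * py)
  sx <- sqrt(sum((1:G - mx)^2 * px)); sy <- sqrt(sum((1:G - my)^2 * py))
  corr <- 0
  if (sx > 1e-12 && sy > 1e-12) {
    for (i in 1:G) for (j in 1:G) corr <- corr + (i - mx) * (j - my) * p[i, j]
    corr <- corr / (sx * sy)
  }
  c(asm = asm, contrast = contrast, correlation = corr, entropy = entropy,
    homogeneity = homog, dissimilarity = dissim)
}

# Mean GLCM features over the four standard angles, via the oracle matrix.
oracle_glcm_4angle <- function(levels, mask, G, distance = 1) {
  offs <- list(c(0, distance), c(-distance, distance), c(-distance, 0),
               c(-distance, -distance))
  fs <- list()
  for (o in offs) {
    p <- oracle_glcm_matrix(levels, mask, G, o)
    if (!is.null(p)) fs[[length(fs) + 1]] <- oracle_glcm_features(p)
  }
  colMeans(do.call(rbind, fs))
}

# Per-displacement difference histogram features by exhaustive enumeration.
oracle_glds <- function(levels, mask, G, displacements) {
  nr <- nrow(levels); nc <- ncol(levels)
  per <- list()
  for (d in displacements) {
    dx <- d[1]; dy <- d[2]
    diffs <- c()
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + dy; c2 <- c + dx
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!mask[r, c] || !mask[r2, c2]) next
      diffs <- c(diffs, abs(levels[r, c] - levels[r2, c2]))
    }
    if (length(diffs) == 0) next
    p <- sapply(0:(G - 1), function(v) mean(diffs == v))
    ent <- -sum(ifelse(p > 0, p * log2(p), 0))
    per[[length(per) + 1]] <- c(mean = sum((0:(G - 1)) * p),
                                contrast = sum((0:(G - 1))^2 * p),
                                asm = sum(p^2), entropy = ent)
  }
  colMeans(do.call(rbind, per))
}

# Joint gray/gradient histogram via per-pixel Sobel kernels and direct binning.
oracle_ggcm_hist <- function(slice, mask, G, Gs) {
  nr <- nrow(slice); nc <- ncol(slice)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  vals <- slice[mask]
  rng <- range(vals)
  qgray <- function(v) {
    if (diff(rng) == 0) return(0)
    min(floor((v - rng[1]) / diff(rng) * G), G - 1)
  }
  pix <- list()
  for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
    if (!all(mask[(r - 1):(r + 1), (c - 1):(c + 1)])) next
    gx <- 0; gy <- 0
    for (a in -1:1) for (b in -1:1) {
      gx <- gx + kx[a + 2, b + 2] * slice[r + a, c + b]
      gy <- gy + ky[a + 2, b + 2] * slice[r + a, c + b]
    }
    pix[[length(pix) + 1]] <- c(gray = qgray(slice[r, c]), grad = sqrt(gx^2 + gy^2))
  }
  if (length(pix) == 0) return(NULL)
  m <- do.call(rbind, pix)
  gmax <- max(m[, "grad"])
  gl <- if (gmax == 0) rep(0, nrow(m)) else pmin(floor(m[, "grad"] / gmax * Gs), Gs - 1)
  h <- matrix(0, G, Gs)
  for (k in seq_len(nrow(m))) {
    h[m[k, "gray"] + 1, gl[k] + 1] <- h[m[k, "gray"] + 1, gl[k] + 1] + 1
  }
  h / sum(h)
}

oracle_ggcm_features <- function(p) {
  G <- nrow(p); Gs <- ncol(p)
  pi_ <- rowSums(p); pj <- colSums(p)
  mui <- sum((0:(G - 1)) * pi_); muj <- sum((0:(Gs - 1)) * pj)
  vari <- sum(((0:(G - 1)) - mui)^2 * pi_); varj <- sum(((0:(Gs - 1)) - muj)^2 * pj)
  sgd <- 0; bgd <- 0; en <- 0; mixed <- 0; inertia <- 0; idm <- 0; corr <- 0
  for (i in 1:G) for (j in 1:Gs) {
    v <- p[i, j]
    sgd <- sgd + v / j^2
    bgd <- bgd + v * (j - 1)^2
    en <- en + v^2
    if (v > 0) mixed <- mixed - v * log2(v)
    inertia <- inertia + ((i - 1) - (j - 1))^2 * v
    idm <- idm + v / (1 + ((i - 1) - (j - 1))^2)
    corr <- corr + ((i - 1) - mui) * ((j - 1) - muj) * v
  }
  corr <- if (vari > 1e-24 && varj > 1e-24) corr / sqrt(vari * varj) else 0
  ent <- function(q) -sum(ifelse(q > 0, q * log2(q), 0))
  c(small_grad_dominance = sgd, big_grad_dominance = bgd,
    gray_asymmetry = sum(pi_^2), grad_asymmetry = sum(pj^2), energy = en,
    gray_mean = mui, grad_mean = muj, gray_variance = vari, grad_variance = varj,
    correlation = corr, gray_entropy = ent(pi_), grad_entropy = ent(pj),
    mixed_entropy = mixed, inertia = inertia, idm = idm)
}

# Convex-hull pixel count by the point-augmentation criterion: an integer
# point lies in the hull iff adding it leaves the hull area unchanged.
oracle_hull_count <- function(pts) {
  poly_area <- function(p) {
    h <- grDevices::chull(p)
    v <- p[h, , drop = FALSE]
    n <- nrow(v)
    if (n < 3) return(0)
    s <- 0
    for (i in 1:n) {
      j <- if (i == n) 1 else i + 1
      s <- s + v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2]
    }
    abs(s) / 2
  }
  a0 <- poly_area(pts)
  cnt <- 0
  for (x in min(pts[, 1]):max(pts[, 1])) for (y in min(pts[, 2]):max(pts[, 2])) {
    if (poly_area(rbind(pts, c(x, y))) <= a0 + 1e-9) cnt <- cnt + 1
  }
  cnt
}

# AUC by exhaustive concordant-pair counting.
oracle_auc <- function(scores, pos) {
  xs <- scores[pos]; ys <- scores[!pos]
  s <- 0
  for (a in xs) for (b in ys) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(xs) * length(ys))
}

# Random connected mask on an n x n grid (random walk fill).
random_connected_mask <- function(n, target = NULL) {
  if (is.null(target)) target <- sample(3:(n * n %/% 2), 1)
  m <- matrix(FALSE, n, n)
  pos <- c(sample(n, 1), sample(n, 1))
  m[pos[1], pos[2]] <- TRUE
  while (sum(m) < target) {
    step <- sample(list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0)), 1)[[1]]
    cand <- pmin(pmax(pos + step, 1), n)
    pos <- cand
    m[pos[1], pos[2]] <- TRUE
  }
  m
}
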