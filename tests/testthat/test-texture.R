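test_that("quantization maps the in-mask range onto G bins", {
  m <- matrix(TRUE, 4, 4)
  const <- quantize_roi(matrix(7, 4, 4), m, 16)
  expect_true(all(const$levels == 0))

  vals <- matrix(0:15, 4, 4)
  q <- quantize_roi(vals, m, 16)
  expect_equal(q$levels, vals)   # {0..15} with G = 16 is the identity

  set.seed(1)
  ramp <- matrix(runif(64, 2, 9), 8, 8)
  q2 <- quantize_roi(ramp, matrix(TRUE, 8, 8), 16)
  # brute-force binning oracle
  rng <- range(ramp)
  expected <- pmin(floor((ramp - rng[1]) / diff(rng) * 16), 15)
  expect_equal(q2$levels, matrix(as.integer(expected), 8, 8))
})

test_that("quantization ignores out-of-mask pixels and is affine-invariant", {
  img <- matrix(c(100, 1, 2, 3, 4, 100, 5, 6, 7), 3, 3)
  mask <- img < 100
  q <- quantize_roi(img, mask, 8)
  expect_true(all(is.na(q$levels[!mask])))
  q_affine <- quantize_roi(3 * img + 11, mask, 8)
  expect_equal(q$levels, q_affine$levels)
})

test_that("grayscale statistics follow the degenerate-region conventions", {
  m <- matrix(TRUE, 3, 3)
  f <- compute_gss(matrix(5, 3, 3), m)
  expect_equal(unname(f[c("sd", "skewness", "kurtosis", "span", "entropy")]),
               c(0, 0, 0, 0, 0))
  expect_equal(unname(f["energy"]), 1)

  two <- matrix(rep(c(0, 10), 8), 4, 4)
  f2 <- compute_gss(two, matrix(TRUE, 4, 4))
  expect_equal(unname(f2["entropy"]), 1)   # two equal-mass levels: 1 bit
  expect_equal(unname(f2["energy"]), 0.5)
  expect_equal(unname(f2["span"]), 10)
})

test_that("central moments match the direct definition on a toy region", {
  x <- c(1.2, 3.4, 2.2, 5.6, 0.1, 4.4, 3.3, 2.8, 1.9, 6.0)
  img <- matrix(c(x, rep(99, 2)), 3, 4)
  mask <- matrix(c(rep(TRUE, 10), FALSE, FALSE), 3, 4)
  f <- compute_gss(img, mask)
  mu <- mean(x)
  expect_equal(unname(f["mean"]), mu)
  expect_equal(unname(f["sd"]), sqrt(sum((x - mu)^2) / 10))
  expect_equal(unname(f["cm5"]), sum((x - mu)^5) / 10)
  expect_equal(unname(f["cm6"]), sum((x - mu)^6) / 10)
  expect_equal(unname(f["skewness"]), (sum((x - mu)^3) / 10) / (sum((x - mu)^2) / 10)^1.5)
  expect_equal(unname(f["kurtosis"]), (sum((x - mu)^4) / 10) / (sum((x - mu)^2) / 10)^2)
})

test_that("the worked 3x3 co-occurrence example reproduces the known matrix", {
  img <- matrix(c(0, 0, 1, 0, 1, 1, 1, 1, 1), 3, 3, byrow = TRUE)
  q <- quantize_roi(img, matrix(TRUE, 3, 3), 2)
  p <- glcm_matrix(q, c(0L, 1L))   # 0 degrees, distance 1
  expect_equal(p, matrix(c(1 / 6, 1 / 6, 1 / 6, 1 / 2), 2, 2), tolerance = 1e-12)
  f <- petradiomics:::glcm_features_one(p)
  expect_equal(unname(f["asm"]), 1 / 3)
  expect_equal(unname(f["contrast"]), 1 / 3)
})

test_that("a constant region gives the degenerate co-occurrence features", {
  q <- quantize_roi(matrix(4, 5, 5), matrix(TRUE, 5, 5), 16)
  f <- compute_glcm_features(q)
  expect_equal(unname(f[c("contrast", "dissimilarity", "entropy", "correlation")]),
               c(0, 0, 0, 0))
  expect_equal(unname(f["homogeneity"]), 1)
  expect_equal(unname(f["asm"]), 1)
})

test_that("the 4-angle mean equals the mean of per-angle features", {
  set.seed(7)
  img <- matrix(sample(0:5, 36, TRUE), 6, 6)
  mask <- matrix(TRUE, 6, 6)
  q <- quantize_roi(img, mask, 6)
  f <- compute_glcm_features(q)
  per <- sapply(petradiomics:::glcm_offsets(1), function(o)
    petradiomics:::glcm_features_one(glcm_matrix(q, o)))
  expect_equal(unname(f), unname(rowMeans(per)))
})

test_that("GLCM/GLDS/GGCM match brute-force oracles on small images", {
  set.seed(99)
  for (i in 1:12) {
    n <- sample(4:8, 1)
    img <- matrix(runif(n * n, 0, 10), n, n)
    mask <- if (i %% 3 == 0) matrix(TRUE, n, n) else random_connected_mask(n, max(6, n))
    if (sum(petradiomics:::erode_mask2(mask)) == 0) mask <- matrix(TRUE, n, n)
    G <- sample(c(4, 8, 16), 1)
    q <- quantize_roi(img, mask, G)

    expect_equal(unname(compute_glcm_features(q)),
                 unname(oracle_glcm_4angle(q$levels, mask, G)), tolerance = 1e-9)

    disp <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
    expect_equal(unname(suppressWarnings(compute_glds_features(q))),
                 unname(oracle_glds(q$levels, mask, G, disp)), tolerance = 1e-9)

    oh <- oracle_ggcm_hist(img, mask, G, 16)
    expect_equal(ggcm_matrix(img, mask, G, 16)$p, oh, tolerance = 1e-9)
    expect_equal(unname(compute_ggcm_features(img, mask, G, 16)),
                 unname(oracle_ggcm_features(oh)), tolerance = 1e-9)
  }
})

test_that("difference statistics behave on the forced patterns", {
  const <- quantize_roi(matrix(2, 4, 4), matrix(TRUE, 4, 4), 16)
  f <- compute_glds_features(const)
  expect_equal(unname(f), c(0, 0, 1, 0))

  # checkerboard, vertical displacement only: all differences are 1
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  qcb <- quantize_roi(cb, matrix(TRUE, 6, 6), 2)
  f2 <- compute_glds_features(qcb, displacements = list(c(0L, 1L)))
  expect_equal(unname(f2["mean"]), 1)
  expect_equal(unname(f2["contrast"]), 1)
  expect_equal(unname(f2["asm"]), 1)
})

test_that("gray-gradient features degenerate correctly on a constant region", {
  f <- compute_ggcm_features(matrix(3, 6, 6), matrix(TRUE, 6, 6))
  expect_equal(unname(f["small_grad_dominance"]), 1)
  expect_equal(unname(f["inertia"]), 0)
  expect_equal(unname(f["mixed_entropy"]), 0)
  expect_error(compute_ggcm_features(matrix(1, 2, 2), matrix(TRUE, 2, 2)), "3x3")
})

test_that("co-occurrence and joint histograms are proper distributions", {
  set.seed(5)
  for (i in 1:6) {
    img <- matrix(runif(49), 7, 7)
    mask <- random_connected_mask(7, 12)
    q <- quantize_roi(img, mask, 8)
    for (o in petradiomics:::glcm_offsets(1)) {
      p <- glcm_matrix(q, o)
      if (!is.null(p)) {
        expect_lt(abs(sum(p) - 1), 1e-9)
        expect_true(all(p >= 0))
      }
    }
    if (sum(petradiomics:::erode_mask2(mask)) > 0)
      expect_lt(abs(sum(ggcm_matrix(img, mask, 8, 8)$p) - 1), 1e-9)
  }
})

test_that("4-angle averaged GLCM features are invariant under 90-degree rotation", {
  set.seed(17)
  img <- matrix(sample(0:7, 64, TRUE), 8, 8)
  mask <- matrix(TRUE, 8, 8)
  rot90 <- function(m) t(m)[, nrow(m):1]
  f1 <- compute_glcm_features(quantize_roi(img, mask, 8))
  f2 <- compute_glcm_features(quantize_roi(rot90(img), rot90(mask) > 0, 8))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("range-relative quantization makes co-occurrence features affine-invariant", {
  set.seed(23)
  img <- matrix(runif(49, 1, 5), 7, 7)
  mask <- matrix(TRUE, 7, 7)
  f1 <- compute_glcm_features(quantize_roi(img, mask, 16))
  f2 <- compute_glcm_features(quantize_roi(100 + 7 * img, mask, 16))
  expect_equal(f1, f2)
  g1 <- compute_glds_features(quantize_roi(img, mask, 16))
  g2 <- compute_glds_features(quantize_roi(100 + 7 * img, mask, 16))
  expect_equal(g1, g2)
})

test_that("texture features respect their analytic ranges", {
  set.seed(31)
  for (i in 1:8) {
    img <- matrix(runif(64), 8, 8)
    q <- quantize_roi(img, matrix(TRUE, 8, 8), 16)
    f <- compute_glcm_features(q)
    expect_gte(unname(f["entropy"]), 0)
    expect_gte(unname(f["contrast"]), 0)
    expect_true(f["asm"] > 0 && f["asm"] <= 1)
    expect_true(f["homogeneity"] > 0 && f["homogeneity"] <= 1)
    d <- compute_glds_features(q)
    expect_gte(unname(d["entropy"]), 0)
    expect_true(d["asm"] > 0 && d["asm"] <= 1)
  }
})

test_that("the assembled vector has exactly 38 features in fixed order", {
  coh <- cached_cohort_features()$cohort
  vp <- coh$volumes[[1]]
  seedv <- as.integer(coh$truth[1, c("seed_x", "seed_y", "seed_z")])
  roi <- segment_isocontour(vp$pet, seedv)
  fpet <- extract_feature_vector(vp, roi, "pet")
  fct <- extract_feature_vector(vp, roi, "ct")
  expect_length(fpet, 38)
  expect_identical(names(fpet), radiomic_feature_names())
  expect_identical(names(fct), radiomic_feature_names())
  # morphology comes from the shared mask, not the intensities
  expect_identical(fpet[1:4], fct[1:4])
  expect_false(isTRUE(all.equal(fpet[5:38], fct[5:38])))
  expect_true(all(is.finite(fpet)) && all(is.finite(fct)))
})

test_that("slice-average mode equals single-slice mode on a z-uniform lesion", {
  dm <- c(16, 16, 9)
  pet <- array(0.1, dm)
  set.seed(8)
  sl <- matrix(0, 16, 16)
  sl[5:12, 5:12] <- runif(64, 4, 9)
  for (z in 3:7) pet[, , z] <- sl
  vp <- volume_pair(pet, array(0, dm) + 40 * (pet > 1), c(2, 2, 2), "zu")
  roi <- segment_isocontour(pet, c(8, 8, 5))
  f1 <- extract_feature_vector(vp, roi, "pet", slice_mode = "largest")
  f2 <- extract_feature_vector(vp, roi, "pet", slice_mode = "average")
  expect_equal(f1, f2)
})
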