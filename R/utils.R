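# Internal array helpers shared by the phantom, segmentation and texture code.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Zero/FALSE-padded shift of a 3-d array by an integer offset.
shift3 <- function(a, d) {
  dm <- dim(a)
  out <- array(vector(typeof(a), 1L), dm)
  idx <- vector("list", 3L)
  src <- vector("list", 3L)
  for (k in 1:3) {
    if (d[k] >= 0) src[[k]] <- seq_len(max(dm[k] - d[k], 0L)) else src[[k]] <- seq.int(1L - d[k], dm[k])
    if (length(src[[k]]) == 0L) return(out)
    idx[[k]] <- src[[k]] + d[k]
  }
  out[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Zero-padded shift of a matrix.
shift2 <- function(m, d) {
  dm <- dim(m)
  out <- matrix(vector(typeof(m), 1L), dm[1], dm[2])
  s1 <- if (d[1] >= 0) seq_len(max(dm[1] - d[1], 0L)) else seq.int(1L - d[1], dm[1])
  s2 <- if (d[2] >= 0) seq_len(max(dm[2] - d[2], 0L)) else seq.int(1L - d[2], dm[2])
  if (length(s1) == 0L || length(s2) == 0L) return(out)
  out[s1 + d[1], s2 + d[2]] <- m[s1, s2]
  out
}

offsets26 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

offsets8 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

dilate_mask3 <- function(mask) {
  out <- mask
  for (r in seq_len(nrow(offsets26))) out <- out | shift3(mask, offsets26[r, ])
  out
}

# Connected component (26-connectivity) of `mask` containing voxel index `seed`
# (length-3 integer). Returns a logical array of the same shape.
connected_component3 <- function(mask, seed) {
  if (!mask[seed[1], seed[2], seed[3]]) stopf("seed voxel is not inside the mask")
  comp <- array(FALSE, dim(mask))
  comp[seed[1], seed[2], seed[3]] <- TRUE
  repeat {
    grown <- dilate_mask3(comp) & mask
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

# Number of 26-connected components in a 3-d logical array.
count_components3 <- function(mask) {
  remaining <- mask
  n <- 0L
  while (any(remaining)) {
    seed <- which(remaining, arr.ind = TRUE)[1, ]
    comp <- connected_component3(remaining, seed)
    remaining <- remaining & !comp
    n <- n + 1L
  }
  n
}

# Smooth standard-normal random field: white noise convolved (circularly, via
# FFT) with a Gaussian kernel of width sigma (in voxels, per axis), then
# restandardized to zero mean / unit variance. sigma ~ 0 returns the raw noise.
gaussian_random_field3 <- function(dm, sigma_vox) {
  noise <- array(stats::rnorm(prod(dm)), dm)
  if (all(sigma_vox < 1e-8)) return(noise)
  axes <- lapply(1:3, function(k) {
    x <- c(0:(dm[k] %/% 2), -rev(seq_len(dm[k] - dm[k] %/% 2 - 1)))
    if (sigma_vox[k] < 1e-8) as.numeric(x == 0) else exp(-x^2 / (2 * sigma_vox[k]^2))
  })
  kern <- outer(outer(axes[[1]], axes[[2]]), axes[[3]])
  f <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) / prod(dm)
  (f - mean(f)) / stats::sd(f)
}

# Erode a 2-d mask by the 3x3 structuring element (pixels whose full 8-neighbourhood
# is in-mask).
erode_mask2 <- function(mask) {
  out <- mask
  for (r in seq_len(nrow(offsets8))) out <- out & shift2(mask, offsets8[r, ])
  out
}
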