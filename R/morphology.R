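#' Morphological features of a 2-d lesion mask
#'
#' Pixel-count based shape descriptors of the analysis slice:
#' \itemize{
#'   \item `area`: number of in-mask pixels.
#'   \item `perimeter`: number of in-mask pixels with at least one out-of-mask
#'     4-neighbour (boundary pixel count).
#'   \item `diameter`: maximum number of pixels on a digital line between any
#'     two boundary pixels, i.e. the maximum pairwise Chebyshev distance + 1.
#'   \item `concavity`: (A - B) / B, where A is the mask area and B the area
#'     (in pixels) of the convex hull of the mask. B is counted as the number
#'     of pixel centres inside the hull polygon, so convex digital shapes give
#'     exactly 0; concave shapes give negative values. Set
#'     `concavity_absolute = TRUE` for |A - B| / B.
#' }
#' All quantities are in pixel units, matching the pixel-count definitions.
#'
#' @param mask Logical matrix (non-empty).
#' @param concavity_absolute Report |A - B| / B instead of (A - B) / B.
#' @return Named numeric vector: `area`, `perimeter`, `diameter`, `concavity`.
#' @export
compute_morphology <- function(mask, concavity_absolute = FALSE) {
  if (!is.matrix(mask)) stopf("mask must be a matrix")
  mask <- mask > 0
  if (!any(mask)) stopf("empty mask")
  area <- sum(mask)

  inner4 <- shift2(mask, c(1L, 0L)) & shift2(mask, c(-1L, 0L)) &
    shift2(mask, c(0L, 1L)) & shift2(mask, c(0L, -1L))
  boundary <- mask & !inner4
  perimeter <- sum(boundary)

  b <- which(boundary, arr.ind = TRUE)
  diameter <- if (nrow(b) == 1L) 1 else {
    max(vapply(seq_len(nrow(b)), function(i) {
      max(pmax(abs(b[, 1] - b[i, 1]), abs(b[, 2] - b[i, 2])))
    }, numeric(1))) + 1
  }

  hull_area <- convex_hull_pixel_count(which(mask, arr.ind = TRUE))
  concavity <- (area - hull_area) / hull_area
  if (concavity_absolute) concavity <- abs(concavity)
  c(area = area, perimeter = perimeter, diameter = diameter, concavity = concavity)
}

# Number of integer pixel centres inside (or on) the convex hull of a set of
# pixel centres. Handles degenerate (collinear / single-point) sets.
convex_hull_pixel_count <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n <= 2L) return(n_points_on_segment(pts))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) <= 2L) return(n_points_on_segment(pts[h, , drop = FALSE], all_pts = pts))
  v <- pts[h, , drop = FALSE]           # chull returns clockwise order
  v <- v[rev(seq_len(nrow(v))), , drop = FALSE]  # counter-clockwise
  cand <- as.matrix(expand.grid(min(pts[, 1]):max(pts[, 1]),
                                min(pts[, 2]):max(pts[, 2])))
  inside <- rep(TRUE, nrow(cand))
  eps <- 1e-9
  m <- nrow(v)
  for (i in seq_len(m)) {
    a <- v[i, ]; bb <- v[if (i == m) 1L else i + 1L, ]
    cross <- (bb[1] - a[1]) * (cand[, 2] - a[2]) - (bb[2] - a[2]) * (cand[, 1] - a[1])
    inside <- inside & (cross >= -eps)
  }
  sum(inside)
}

# Collinear hull: count integer points lying on the segment spanned by the
# extreme points of the set.
n_points_on_segment <- function(pts, all_pts = pts) {
  if (nrow(pts) == 1L) return(1L)
  d2 <- as.matrix(stats::dist(all_pts))^2
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  a <- all_pts[ij[1], ]; b <- all_pts[ij[2], ]
  g <- max(abs(b - a))
  steps <- (a[1] == b[1] || a[2] == b[2] || abs(b[1] - a[1]) == abs(b[2] - a[2]))
  if (steps) return(g + 1L)
  # general collinear rational direction: count lattice points on the segment
  dx <- b[1] - a[1]; dy <- b[2] - a[2]
  gcd <- function(p, q) if (q == 0) abs(p) else gcd(q, p %% q)
  gcd(dx, dy) + 1L
}
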