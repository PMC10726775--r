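# Internal raster and geometry helpers.
#
# Conventions used throughout the package:
#   * rasters are R matrices indexed [row, col], 1-based, origin at the top-left;
#   * on-disk interchange formats (JSON) use 0-based (row, col) coordinates and
#     half-open rectangle extents [r0, c0, r1, c1);
#   * intensities are 0-255 with 0 = black.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Signed doubled area of the triangle spanned by three (row, col) points.
#' @noRd
triangle_area2 <- function(pts) {
  stopifnot(nrow(pts) == 3L)
  (pts[2, 1] - pts[1, 1]) * (pts[3, 2] - pts[1, 2]) -
    (pts[3, 1] - pts[1, 1]) * (pts[2, 2] - pts[1, 2])
}

# Run a block of code under a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage seed from a root seed; kept inside 32-bit integer range.
#' @noRd
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + 1009 * k) %% 2147483647)
}

# --- affine maps -----------------------------------------------------------
# A 2x3 matrix A encodes p_out = A[, 1:2] %*% p_in + A[, 3] on (row, col)
# column vectors.

#' @noRd
affine_identity <- function() cbind(diag(2), c(0, 0))

#' @noRd
affine_apply <- function(A, rows, cols) {
  list(
    row = A[1, 1] * rows + A[1, 2] * cols + A[1, 3],
    col = A[2, 1] * rows + A[2, 2] * cols + A[2, 3]
  )
}

#' @noRd
affine_invert <- function(A) {
  L <- A[, 1:2, drop = FALSE]
  d <- L[1, 1] * L[2, 2] - L[1, 2] * L[2, 1]
  if (abs(d) < 1e-12) stopf("affine transform is singular (det = %g)", d)
  Li <- matrix(c(L[2, 2], -L[2, 1], -L[1, 2], L[1, 1]), 2, 2) / d
  cbind(Li, -Li %*% A[, 3])
}

#' @noRd
affine_compose <- function(A, B) {
  # returns the map x -> A(B(x))
  cbind(A[, 1:2] %*% B[, 1:2], A[, 1:2] %*% B[, 3] + A[, 3])
}

# Solve the affine map sending each src point to the matching dst point.
# Three non-collinear correspondences determine the map exactly.
#' @noRd
affine_from_points <- function(src, dst) {
  stopifnot(nrow(src) == 3L, nrow(dst) == 3L)
  if (abs(triangle_area2(src)) < 1e-9)
    stopf("cannot solve affine map: source points are collinear")
  M <- cbind(src[, 1], src[, 2], 1)
  # one 3x3 solve per output coordinate
  coef_r <- solve(M, dst[, 1])
  coef_c <- solve(M, dst[, 2])
  rbind(coef_r, coef_c)
}

# --- connected components --------------------------------------------------

# Label 8-connected components of a logical matrix. Returns a list with
# integer vectors `pixels` (linear indices) and `label` (component id per
# pixel), plus `n` components. Implemented as a frontier BFS over the true
# pixels only, so cost scales with the number of true pixels, not the raster.
#' @noRd
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  lab <- integer(length(mask))  # 0 = unlabelled
  if (length(idx) == 0L)
    return(list(pixels = integer(0), label = integer(0), n = 0L))
  # 8-neighbour linear offsets; column moves are +-h
  off <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
  n_comp <- 0L
  for (seed in idx) {
    if (lab[seed] != 0L) next
    n_comp <- n_comp + 1L
    lab[seed] <- n_comp
    frontier <- seed
    while (length(frontier) > 0L) {
      rows <- ((frontier - 1L) %% h) + 1L
      nb <- rep(frontier, each = 8L) + off
      nb_row <- rep(rows, each = 8L) + c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
      ok <- nb >= 1L & nb <= length(mask) & nb_row >= 1L & nb_row <= h
      nb <- nb[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      nb <- unique(nb)
      lab[nb] <- n_comp
      frontier <- nb
    }
  }
  list(pixels = idx, label = lab[idx], n = n_comp)
}

# Remove marked pixels that have no marked pixel among their 8 neighbours.
# Isolated single pixels are scanner speckle, not pen strokes.
#' @noRd
despeckle_mask <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  m <- matrix(0L, h + 2L, w + 2L)
  m[2:(h + 1L), 2:(w + 1L)] <- mask * 1L
  nb <- m[1:h, 1:w] + m[1:h, 2:(w + 1L)] + m[1:h, 3:(w + 2L)] +
    m[2:(h + 1L), 1:w] + m[2:(h + 1L), 3:(w + 2L)] +
    m[3:(h + 2L), 1:w] + m[3:(h + 2L), 2:(w + 1L)] + m[3:(h + 2L), 3:(w + 2L)]
  mask & nb > 0L
}

# Interior edge of a mask: true pixels with at least one false 4-neighbour.
#' @noRd
mask_edge <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  inner <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  mask & !inner
}

# Disc mask centred at (r0, c0) with the given radius, on an h x w raster.
#' @noRd
disc_indices <- function(h, w, r0, c0, radius) {
  rr <- max(1L, floor(r0 - radius)):min(h, ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(w, ceiling(c0 + radius))
  if (length(rr) == 0L || length(cc) == 0L) return(integer(0))
  g <- expand.grid(r = rr, c = cc)
  keep <- (g$r - r0)^2 + (g$c - c0)^2 <= radius^2
  (g$c[keep] - 1L) * h + g$r[keep]
}

#' Dice coefficient between two binary rasters
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}, the standard overlap score used here to
#' measure how well scan ingestion recovers the marked pixels of the drawing
#' that generated a render. Both rasters empty gives 1 (perfect agreement on
#' nothing).
#'
#' @param a,b logical matrices of identical shape.
#' @return a number in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
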