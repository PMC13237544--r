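#' @useDynLib aortamap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx aov coef cor.test glm lm median pnorm pt qt
#'   quantile sd setNames t.test var vcov wilcox.test binomial TukeyHSD
#' @importFrom utils head read.csv tail write.csv
NULL

# row-wise Euclidean norms
row_norms <- function(m) sqrt(rowSums(m * m))

# normalize rows to unit length; zero rows left as zero
unit_rows <- function(m) {
  n <- row_norms(m)
  ok <- n > 0
  m[ok, ] <- m[ok, , drop = FALSE] / n[ok]
  m
}

#' k-nearest neighbours between point sets
#'
#' @param query numeric matrix (n x 3) of query points.
#' @param ref numeric matrix (m x 3) of reference points.
#' @param k number of neighbours.
#' @return list with `idx` (n x k, 1-based into `ref`) and `dist` (n x k, mm).
#' @keywords internal
knn_points <- function(query, ref, k = 1L) {
  stopifnot(ncol(query) == 3, ncol(ref) == 3, nrow(ref) >= 1)
  query <- as.matrix(query); ref <- as.matrix(ref)
  if (nrow(ref) < 64) {
    .cpp_knn_brute(query, ref, as.integer(k))
  } else {
    .cpp_grid_knn(query, ref, as.integer(k))
  }
}

#' Trilinear interpolation of a 3D scalar grid at world points
#'
#' Voxel centers sit at 0-based integer grid coordinates times `spacing`.
#' Points outside the grid return `NA`.
#'
#' @param vol 3D numeric array.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @param spacing isotropic voxel size (mm).
#' @return numeric vector of length n.
#' @keywords internal
interp_trilinear <- function(vol, pts, spacing) {
  d <- dim(vol)
  g <- pts / spacing            # continuous 0-based voxel coords
  i0 <- floor(g)
  f <- g - i0
  out <- rep(NA_real_, nrow(pts))
  ok <- i0[, 1] >= 0 & i0[, 1] <= d[1] - 2 &
        i0[, 2] >= 0 & i0[, 2] <= d[2] - 2 &
        i0[, 3] >= 0 & i0[, 3] <= d[3] - 2
  if (!any(ok)) return(out)
  i <- i0[ok, 1]; j <- i0[ok, 2]; k <- i0[ok, 3]
  fx <- f[ok, 1]; fy <- f[ok, 2]; fz <- f[ok, 3]
  at <- function(di, dj, dk) {
    vol[cbind(i + di + 1L, j + dj + 1L, k + dk + 1L)]
  }
  v <- at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
       at(1, 0, 0) * fx       * (1 - fy) * (1 - fz) +
       at(0, 1, 0) * (1 - fx) * fy       * (1 - fz) +
       at(1, 1, 0) * fx       * fy       * (1 - fz) +
       at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
       at(1, 0, 1) * fx       * (1 - fy) * fz +
       at(0, 1, 1) * (1 - fx) * fy       * fz +
       at(1, 1, 1) * fx       * fy       * fz
  out[ok] <- v
  out
}

# nearest-voxel lookup of a logical mask at world points (FALSE outside grid)
mask_at_points <- function(mask, pts, spacing) {
  d <- dim(mask)
  g <- round(pts / spacing)
  ok <- g[, 1] >= 0 & g[, 1] <= d[1] - 1 &
        g[, 2] >= 0 & g[, 2] <= d[2] - 1 &
        g[, 3] >= 0 & g[, 3] <= d[3] - 1
  out <- rep(FALSE, nrow(pts))
  if (any(ok)) {
    out[ok] <- mask[cbind(g[ok, 1] + 1L, g[ok, 2] + 1L, g[ok, 3] + 1L)]
  }
  out
}

# farthest-point subsample of rows; deterministic (starts at row 1)
farthest_points <- function(x, n) {
  m <- nrow(x)
  if (n >= m) return(seq_len(m))
  sel <- integer(n)
  sel[1] <- 1L
  d <- row_norms(sweep(x, 2, x[1, ], "-"))
  for (i in 2:n) {
    sel[i] <- which.max(d)
    d <- pmin(d, row_norms(sweep(x, 2, x[sel[i], ], "-")))
  }
  sel
}
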