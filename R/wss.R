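#' Identify the peak-systolic cardiac phase
#'
#' Peak systole is the phase in which the spatially averaged velocity
#' magnitude within the segmented lumen is highest; ties break to the
#' earliest phase.
#'
#' @param velocity list (one per phase) of 4D arrays `(nx, ny, nz, 3)`
#'   in cm/s.
#' @param lumen_mask 3D logical array on the same grid.
#' @return integer phase index.
#' @export
peak_systole_frame <- function(velocity, lumen_mask) {
  idx <- which(lumen_mask != 0)
  if (length(idx) == 0) stop("empty lumen mask")
  nvox <- prod(dim(lumen_mask))
  means <- vapply(velocity, function(arr) {
    vx <- arr[idx]; vy <- arr[idx + nvox]; vz <- arr[idx + 2 * nvox]
    mean(sqrt(vx^2 + vy^2 + vz^2))
  }, numeric(1))
  which.max(means)
}

#' Local lumen diameter at each mesh vertex
#'
#' Twice the distance from the vertex to the nearest centerline point
#' (no extrapolation beyond the centerline ends).
#'
#' @param mesh an `aorta_mesh`.
#' @param cl an `aorta_centerline`.
#' @return per-vertex diameter, mm.
#' @export
local_lumen_diameter <- function(mesh, cl) {
  nn <- knn_points(mesh$vertices, cl$points, 1L)
  2 * nn$dist[, 1]
}

#' Wall shear stress vectors at peak systole
#'
#' Estimates the wall-normal velocity gradient at each vertex from three
#' sample points along the inward normal spanning half the local lumen
#' diameter: distances 0, D/4 and D/2 from the wall. The wall sample is
#' forced to zero (no-slip); the unique quadratic through the three
#' samples is differentiated at the wall, per velocity component. The
#' wall shear stress vector is the dynamic viscosity times the
#' tangential part of that derivative (the component along the normal is
#' removed); velocities are converted to m/s and distances to m so the
#' result is in Pa.
#'
#' Vertices whose interior sample points leave the lumen mask, or whose
#' interpolated velocities are not finite, are flagged and must be
#' excluded from regional averages.
#'
#' @param velocity_frame 4D array `(nx, ny, nz, 3)`, cm/s, at peak
#'   systole.
#' @param mesh an `aorta_mesh` with outward unit normals.
#' @param cl an `aorta_centerline` (for the local lumen diameter).
#' @param lumen_mask 3D logical array used for the in-lumen check.
#' @param spacing voxel size, mm.
#' @param viscosity dynamic viscosity, Pa s (default 3.2e-3, a standard
#'   value for blood).
#' @return an object of class `aorta_wss`: list with `vectors`
#'   (n x 3, Pa), `magnitude` (n, Pa), `flagged` (n, logical),
#'   `phase_index` (set by the caller or NA), `viscosity`.
#' @export
wss_vectors <- function(velocity_frame, mesh, cl, lumen_mask, spacing,
                        viscosity = 3.2e-3) {
  V <- mesh$vertices
  n_out <- mesh$normals
  D <- local_lumen_diameter(mesh, cl)     # mm
  h <- D / 4                               # mm, sample step
  p1 <- V - n_out * h
  p2 <- V - n_out * 2 * h
  v1 <- sapply(1:3, function(c3) {
    interp_trilinear(velocity_frame[, , , c3], p1, spacing)
  })
  v2 <- sapply(1:3, function(c3) {
    interp_trilinear(velocity_frame[, , , c3], p2, spacing)
  })
  in1 <- mask_at_points(lumen_mask, p1, spacing)
  in2 <- mask_at_points(lumen_mask, p2, spacing)
  flagged <- !in1 | !in2 | !is.finite(rowSums(v1)) | !is.finite(rowSums(v2))
  v1[!is.finite(v1)] <- 0
  v2[!is.finite(v2)] <- 0
  # quadratic through (0, 0), (h, v1), (2h, v2): f'(0) = (4 v1 - v2)/(2 h)
  h_m <- h * 1e-3                          # m
  grad <- (4 * v1 - v2) * 0.01 / (2 * h_m) # 1/s, velocity cm/s -> m/s
  # tangential projection
  gn <- rowSums(grad * n_out)
  grad_t <- grad - n_out * gn
  vectors <- viscosity * grad_t
  structure(list(vectors = vectors, magnitude = row_norms(vectors),
                 flagged = flagged, phase_index = NA_integer_,
                 viscosity = viscosity),
            class = "aorta_wss")
}

#' Per-vertex core velocity magnitude
#'
#' Samples the velocity magnitude at half the local lumen diameter along
#' the inward normal (i.e. near the lumen center), per vertex. Used as
#' the regional velocity parameter.
#'
#' @inheritParams wss_vectors
#' @return list with `values` (cm/s) and `flagged`.
#' @export
core_velocity_map <- function(velocity_frame, mesh, cl, lumen_mask,
                              spacing) {
  D <- local_lumen_diameter(mesh, cl)
  p <- mesh$vertices - mesh$normals * D / 2
  v <- sapply(1:3, function(c3) {
    interp_trilinear(velocity_frame[, , , c3], p, spacing)
  })
  flagged <- !mask_at_points(lumen_mask, p, spacing) |
    !is.finite(rowSums(v))
  v[!is.finite(v)] <- 0
  list(values = sqrt(rowSums(v^2)), flagged = flagged)
}

#' @export
print.aorta_wss <- function(x, ...) {
  cat(sprintf(
    "<aorta_wss> %d vertices, mean %.3f Pa, %d flagged, mu = %.2g Pa s\n",
    length(x$magnitude), mean(x$magnitude[!x$flagged]),
    sum(x$flagged), x$viscosity))
  invisible(x)
}
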