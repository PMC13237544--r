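#' Distance from points to a triangulated surface
#'
#' Nearest-triangle distance using the faces incident to the three
#' nearest vertices of each query point.
#'
#' @param points n x 3 matrix (mm).
#' @param mesh an `aorta_mesh`.
#' @return numeric vector of distances (mm).
#' @export
point_surface_distance <- function(points, mesh) {
  .cpp_point_mesh_dist(as.matrix(points), mesh$vertices, mesh$faces)
}

#' Symmetric mean surface distance between two meshes
#'
#' Average of the two directed mean nearest vertex-to-surface distances.
#'
#' @param mesh_a,mesh_b `aorta_mesh` objects.
#' @return distance in mm.
#' @export
symmetric_surface_distance <- function(mesh_a, mesh_b) {
  d_ab <- mean(point_surface_distance(mesh_a$vertices, mesh_b))
  d_ba <- mean(point_surface_distance(mesh_b$vertices, mesh_a))
  (d_ab + d_ba) / 2
}

#' Select the template geometry of a cohort
#'
#' Returns the index of the mesh with the smallest mean symmetric
#' surface distance to all other meshes; ties break to the lowest index.
#'
#' @param meshes list of at least two `aorta_mesh` objects.
#' @return integer index into `meshes`.
#' @export
select_template <- function(meshes) {
  n <- length(meshes)
  if (n < 2) stop("select_template needs at least two meshes")
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- symmetric_surface_distance(meshes[[i]], meshes[[j]])
    }
  }
  means <- rowSums(D) / (n - 1)
  which.min(means)   # which.min returns the first (lowest-index) minimum
}

#' Non-rigid surface registration (Gaussian-kernel regularized)
#'
#' Registers a source surface onto a target surface with a smooth
#' displacement field of coherent-point-drift type: an affine part plus a
#' Gaussian radial-basis field anchored at farthest-point control nodes,
#' fitted by iteratively matching each (transformed) source vertex to
#' the closest point on the target surface under an annealed ridge
#' penalty on the radial-basis weights. The field is deterministic and
#' smooth; identity input is returned unchanged.
#'
#' @param source,target `aorta_mesh` objects.
#' @param beta Gaussian kernel width (mm). The default (8 mm) matches
#'   the scale over which regional aortic wall motion varies; it is much
#'   smaller than the vessel so neighbouring regions deform
#'   independently, yet large enough to keep the field smooth across
#'   several vertex spacings.
#' @param n_ctrl number of radial-basis control nodes.
#' @param max_iter maximum matching iterations.
#' @param tol mean vertex-motion convergence tolerance (mm).
#' @param residual_tol mean residual (mm) above which the result is
#'   flagged as not converged.
#' @param fit_subsample fit the field on at most this many source/target
#'   vertices (the field is still evaluated at every source vertex).
#' @return an `aorta_deformation`: list with `mapped_vertices`,
#'   `residual` (per-vertex distance to the target surface, mm),
#'   `converged`, `mean_residual`, `source`, `target`.
#' @export
register_nonrigid <- function(source, target, beta = 8, n_ctrl = 250L,
                              max_iter = 30L, tol = 1e-3,
                              residual_tol = 1.5, fit_subsample = 2500L,
                              lam_start = 10, lam_final = 0.05) {
  X <- source$vertices
  Y <- target$vertices
  if (nrow(X) == 0 || nrow(Y) == 0) stop("register_nonrigid: empty mesh")
  fit_idx <- if (nrow(X) > fit_subsample) {
    seq(1, nrow(X), length.out = fit_subsample)
  } else seq_len(nrow(X))
  fit_idx <- unique(round(fit_idx))
  Xf <- X[fit_idx, , drop = FALSE]
  nf <- nrow(Xf)
  ctrl <- Xf[farthest_points(Xf, min(n_ctrl, nf)), , drop = FALSE]
  K <- nrow(ctrl)
  phi_of <- function(P) {
    D2 <- outer(rowSums(P^2), rowSums(ctrl^2), "+") - 2 * P %*% t(ctrl)
    exp(-pmax(D2, 0) / (2 * beta^2))
  }
  Phi_f <- cbind(1, Xf, phi_of(Xf))
  pen <- c(rep(0, 4), rep(1, K))
  G <- crossprod(Phi_f)
  B <- matrix(0, 4 + K, 3)
  Tf <- Xf
  # stage 1: translation-only alignment, so a global shift is explained
  # by the constant term and never leaks into the local field (a full
  # affine here would let regional dilation bleed across regions)
  proj <- function(P) {
    .cpp_project_points(P, Y, target$faces)$points
  }
  move <- Inf
  for (it in 1:8) {
    target_disp <- proj(Tf) - Xf
    shift <- colMeans(target_disp)
    T_new <- Xf + matrix(shift, nf, 3, byrow = TRUE)
    move <- mean(row_norms(T_new - Tf))
    B[1, ] <- shift
    Tf <- T_new
    if (move < tol) break
  }
  # stage 2: release the Gaussian radial-basis field under an annealed
  # ridge penalty
  lam_seq <- exp(seq(log(lam_start), log(lam_final),
                     length.out = max_iter))
  for (it in seq_len(max_iter)) {
    target_disp <- proj(Tf) - Xf
    lam <- lam_seq[it] * nf / K
    B_new <- solve(G + diag(lam * pen), crossprod(Phi_f, target_disp))
    T_new <- Xf + Phi_f %*% B_new
    move <- mean(row_norms(T_new - Tf))
    B <- B_new
    Tf <- T_new
    if (move < tol) break
  }
  Phi_all <- cbind(1, X, phi_of(X))
  mapped <- X + Phi_all %*% B
  residual <- point_surface_distance(mapped, target)
  mres <- mean(residual)
  # converged: the fit settled (small last motion) and the mapped
  # surface lies on the target within tolerance
  converged <- (move < max(0.05, tol)) && mres <= residual_tol
  structure(list(mapped_vertices = mapped, residual = residual,
                 converged = converged,
                 mean_residual = mres, beta = beta, n_ctrl = K),
            class = "aorta_deformation")
}

#' @export
print.aorta_deformation <- function(x, ...) {
  cat(sprintf(
    "<aorta_deformation> %d vertices, mean residual %.3f mm%s\n",
    nrow(x$mapped_vertices), x$mean_residual,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Carry a per-vertex field through a registration onto a target mesh
#'
#' Each target vertex receives the inverse-distance-weighted (power 2)
#' value of the 3 nearest mapped source vertices. Vector fields are
#' interpolated componentwise; set `renormalize = TRUE` when the consumer
#' requires unit vectors.
#'
#' @param values per-vertex numeric vector or n x 3 matrix on the
#'   deformation's source mesh.
#' @param deformation an `aorta_deformation` from the source mesh to the
#'   target's space.
#' @param target target `aorta_mesh`.
#' @param renormalize renormalize interpolated vectors to unit length.
#' @return values on the target mesh (vector or matrix).
#' @export
interpolate_to_mesh <- function(values, deformation, target,
                                renormalize = FALSE) {
  mapped <- deformation$mapped_vertices
  vec <- is.matrix(values)
  nsrc <- if (vec) nrow(values) else length(values)
  if (nsrc == 0) stop("interpolate_to_mesh: empty source field")
  if (nsrc != nrow(mapped)) {
    stop("values are not bound to the deformation's source mesh")
  }
  k <- min(3L, nsrc)
  nn <- knn_points(target$vertices, mapped, k)
  w <- 1 / pmax(nn$dist, 1e-9)^2
  # exact hits dominate by construction of the weight floor
  w <- w / rowSums(w)
  if (vec) {
    out <- matrix(0, nrow(target$vertices), ncol(values))
    for (q in seq_len(k)) {
      out <- out + values[nn$idx[, q], , drop = FALSE] * w[, q]
    }
    if (renormalize) out <- unit_rows(out)
  } else {
    out <- numeric(nrow(target$vertices))
    for (q in seq_len(k)) out <- out + values[nn$idx[, q]] * w[, q]
  }
  out
}

#' Nearest-neighbour transfer of a per-vertex field onto a target mesh
#'
#' Used for binary indicators, where averaging would break integer
#' counts: each target vertex copies the value of the nearest mapped
#' source vertex.
#'
#' @inheritParams interpolate_to_mesh
#' @return values on the target mesh.
#' @export
transfer_nearest <- function(values, deformation, target) {
  nn <- knn_points(target$vertices, deformation$mapped_vertices, 1L)
  if (is.matrix(values)) values[nn$idx[, 1], , drop = FALSE]
  else values[nn$idx[, 1]]
}
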