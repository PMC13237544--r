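#' Triangulated lumen surface
#'
#' A light container for a triangulated surface in world millimetres:
#' vertex positions, triangle indices, outward per-vertex unit normals and
#' per-vertex area weights (one third of the incident triangle areas, so
#' that the vertex areas sum exactly to the total surface area).
#'
#' @param vertices n x 3 numeric matrix of positions (mm).
#' @param faces m x 3 integer matrix of 1-based triangle indices.
#' @param normals optional n x 3 matrix of outward unit normals; computed
#'   from the faces when omitted.
#' @return an object of class `aorta_mesh`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            max(faces) <= nrow(vertices), min(faces) >= 1)
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "aorta_mesh")
  geom <- mesh_geometry(vertices, faces)
  m$normals <- if (is.null(normals)) geom$normals else as.matrix(normals)
  m$vertex_area <- geom$vertex_area
  m
}

#' @export
print.aorta_mesh <- function(x, ...) {
  cat(sprintf("<aorta_mesh> %d vertices, %d faces, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$faces), sum(x$vertex_area)))
  invisible(x)
}

# face normals/areas -> accumulated vertex normals and 1/3-area weights
mesh_geometry <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  f_area <- 0.5 * row_norms(cr)
  n <- nrow(V)
  g <- c(F[, 1], F[, 2], F[, 3])
  s <- rowsum(cbind(rbind(cr, cr, cr), rep(f_area / 3, 3)), g)
  ids <- as.integer(rownames(s))
  acc <- matrix(0, n, 3)
  va <- numeric(n)
  acc[ids, ] <- s[, 1:3]
  va[ids] <- s[, 4]
  list(normals = unit_rows(acc), vertex_area = va, face_area = f_area)
}

# sum values by integer group over 1..n (dense)
rowsum_vec <- function(vals, groups, n) {
  out <- numeric(n)
  s <- rowsum(vals, groups)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Total surface area of a mesh
#' @param mesh an `aorta_mesh`.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) sum(mesh$vertex_area)

# connected components over the vertex graph induced by faces
mesh_components <- function(nv, faces) {
  g <- igraph::graph_from_edgelist(
    rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)]),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nv - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(nv)]
}

# Laplacian smoothing with shrink compensation (Taubin lambda/mu
# scheme); each of the `iters` iterations is one smoothing step plus
# one inflation step, so closed surfaces keep their area
laplacian_smooth <- function(V, F, iters = 5L, lam = 0.5, mu = -0.53) {
  n <- nrow(V)
  ii <- c(F[, 1], F[, 2], F[, 2], F[, 3], F[, 1], F[, 3])
  jj <- c(F[, 2], F[, 1], F[, 3], F[, 2], F[, 3], F[, 1])
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  A <- (A > 0) * 1
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  for (q in seq_len(iters)) {
    V <- V + lam * (as.matrix(A %*% V) / deg - V)
    V <- V + mu * (as.matrix(A %*% V) / deg - V)
  }
  V
}

#' Extract the lumen surface from a binary voxel mask
#'
#' The binary volume is lightly smoothed with a Gaussian kernel
#' (sigma 0.8 voxel), isosurfaced at the 0.5 level by marching
#' tetrahedra, reduced to its largest connected component, and relaxed by
#' five Laplacian iterations. Outward normal orientation is verified
#' against the mask interior. Vertices are in world millimetres with
#' voxel centers at 0-based integer grid points.
#'
#' @param mask 3D logical (or 0/1) array with a single foreground
#'   component.
#' @param spacing isotropic voxel size in mm.
#' @param target_edge optional edge length (mm) for vertex-clustering
#'   decimation of the extracted surface; `NULL` keeps full resolution.
#' @return an `aorta_mesh`.
#' @export
mask_to_surface <- function(mask, spacing, target_edge = NULL) {
  mask <- mask != 0
  if (!any(mask)) stop("mask_to_surface: empty mask")
  # crop to the foreground bounding box (plus smoothing support)
  idx <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 4L, 1L)
  hi <- pmin(apply(idx, 2, max) + 4L, dim(mask))
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  vol <- array(as.double(sub), dim = dim(sub))
  vol <- .cpp_gauss_smooth3(vol, 0.8)
  iso <- .cpp_mt_isosurface(vol, 0.5)
  V <- sweep(iso$vertices, 2, as.double(lo - 1L), "+")
  F <- iso$faces
  if (nrow(V) == 0) stop("mask_to_surface: no isosurface found")
  comp <- mesh_components(nrow(V), F)
  sizes <- tabulate(comp)
  keep_c <- which.max(sizes)
  big <- which(sizes > 0.10 * sizes[keep_c])
  if (length(big) > 1) {
    stop("mask_to_surface: multiple comparable foreground components (",
         length(big), "); segmentation is ambiguous")
  }
  vkeep <- comp == keep_c
  remap <- cumsum(vkeep)
  F <- F[vkeep[F[, 1]] & vkeep[F[, 2]] & vkeep[F[, 3]], , drop = FALSE]
  F <- matrix(remap[F], ncol = 3)
  V <- V[vkeep, , drop = FALSE]
  V <- laplacian_smooth(V, F, iters = 5L, lam = 0.5)
  V <- V * spacing
  mesh <- surface_mesh(V, F)
  # orientation audit: step inward along -normal should land inside
  probe <- mesh$vertices - 0.75 * spacing * mesh$normals
  inside <- mask_at_points(mask, probe, spacing)
  if (mean(inside) < 0.5) {
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
    mesh <- surface_mesh(mesh$vertices, mesh$faces)
  }
  if (!is.null(target_edge)) mesh <- decimate_mesh(mesh, target_edge)
  mesh
}

#' Simplify a mesh by vertex clustering
#'
#' Vertices are pooled on a uniform grid of the given cell size; each
#' cluster collapses to its mean position and degenerate faces are
#' dropped. Intended to bring dense marching-tetrahedra output down to a
#' size where point-set registration is fast; the surface area changes
#' by well under the clustering cell size relative tolerance.
#'
#' @param mesh an `aorta_mesh`.
#' @param cell cell edge length in mm.
#' @return a decimated `aorta_mesh`.
#' @export
decimate_mesh <- function(mesh, cell) {
  V <- mesh$vertices
  F <- mesh$faces
  key <- floor(sweep(V, 2, apply(V, 2, min), "-") / cell)
  kmax <- apply(key, 2, max) + 1
  id <- key[, 1] + kmax[1] * (key[, 2] + kmax[2] * key[, 3])
  fid <- match(id, unique(id))
  nc <- max(fid)
  Vc <- matrix(0, nc, 3)
  for (k in 1:3) Vc[, k] <- rowsum_vec(V[, k], fid, nc) / tabulate(fid, nc)
  Fc <- matrix(fid[F], ncol = 3)
  keep <- Fc[, 1] != Fc[, 2] & Fc[, 2] != Fc[, 3] & Fc[, 1] != Fc[, 3]
  Fc <- Fc[keep, , drop = FALSE]
  # drop duplicated faces (same vertex set)
  lo3 <- pmin(Fc[, 1], Fc[, 2], Fc[, 3])
  hi3 <- pmax(Fc[, 1], Fc[, 2], Fc[, 3])
  mid3 <- Fc[, 1] + Fc[, 2] + Fc[, 3] - lo3 - hi3
  kk <- lo3 + (nc + 1) * (mid3 + (nc + 1) * hi3)
  Fc <- Fc[!duplicated(kk), , drop = FALSE]
  used <- sort(unique(as.vector(Fc)))
  remap <- integer(nc)
  remap[used] <- seq_along(used)
  m2 <- surface_mesh(Vc[used, , drop = FALSE], matrix(remap[Fc], ncol = 3))
  # keep outward orientation consistent with the parent mesh
  nn <- knn_points(m2$vertices, mesh$vertices, 1L)
  agree <- rowSums(m2$normals * mesh$normals[nn$idx[, 1], ])
  if (mean(agree > 0) < 0.5) {
    m2$faces <- m2$faces[, c(1, 3, 2)]
    m2 <- surface_mesh(m2$vertices, m2$faces)
  }
  m2
}
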