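#' Aortic centerline with landmark stations
#'
#' Ordered lumen-axis points with cumulative arclength from the aortic
#' annulus and named landmark stations. Stations are arclengths (mm) for
#' `annulus`, `PA_bifurcation`, `brachiocephalic`, `left_subclavian` and
#' `diaphragm`, and must be ordered along the flow direction. A per-point
#' `side` label (ascending / arch / descending) is derived from the
#' stations: the arch spans brachiocephalic to left subclavian.
#'
#' @param points n x 3 matrix of positions (mm), ordered from the annulus.
#' @param stations named numeric vector of landmark arclengths (mm).
#' @return an object of class `aorta_centerline` with fields `points`,
#'   `arclength`, `stations`, `side`, `tangent`.
#' @export
centerline <- function(points, stations = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 2)
  seg <- diff(points)
  ds <- row_norms(seg)
  if (any(ds <= 0)) stop("centerline: repeated consecutive points")
  s <- c(0, cumsum(ds))
  tg <- rbind(seg, seg[nrow(seg), , drop = FALSE])
  tg <- unit_rows(tg)
  cl <- structure(list(points = points, arclength = s,
                       stations = NULL, side = NULL, tangent = tg),
                  class = "aorta_centerline")
  if (!is.null(stations)) cl <- set_stations(cl, stations)
  cl
}

#' @export
print.aorta_centerline <- function(x, ...) {
  cat(sprintf("<aorta_centerline> %d points, length %.1f mm\n",
              nrow(x$points), max(x$arclength)))
  if (!is.null(x$stations)) {
    cat("  stations:",
        paste(sprintf("%s=%.0f", names(x$stations), x$stations),
              collapse = ", "), "\n")
  }
  invisible(x)
}

station_names <- c("annulus", "PA_bifurcation", "brachiocephalic",
                   "left_subclavian", "diaphragm")

#' Attach landmark stations to a centerline
#'
#' @param cl an `aorta_centerline`.
#' @param stations named arclengths (mm); must contain the five standard
#'   landmarks and be ordered annulus < PA_bifurcation < brachiocephalic
#'   <= left_subclavian < diaphragm.
#' @return the centerline with `stations` and `side` populated.
#' @export
set_stations <- function(cl, stations) {
  miss <- setdiff(station_names, names(stations))
  if (length(miss)) stop("missing station(s): ", paste(miss, collapse = ", "))
  st <- stations[station_names]
  if (!(st["annulus"] < st["PA_bifurcation"] &&
        st["PA_bifurcation"] < st["brachiocephalic"] &&
        st["brachiocephalic"] <= st["left_subclavian"] &&
        st["left_subclavian"] < st["diaphragm"])) {
    stop("stations out of order along the flow direction")
  }
  cl$stations <- st
  s <- cl$arclength
  cl$side <- ifelse(s < st["brachiocephalic"], "ascending",
             ifelse(s < st["left_subclavian"], "arch", "descending"))
  cl
}

# linear interpolation of the centerline position/tangent at arclength s
centerline_at <- function(cl, s) {
  s <- max(min(s, max(cl$arclength)), 0)
  p <- vapply(1:3, function(k) approx(cl$arclength, cl$points[, k], s)$y,
              numeric(1))
  i <- findInterval(s, cl$arclength, all.inside = TRUE)
  tg <- cl$points[i + 1, ] - cl$points[i, ]
  list(point = p, tangent = tg / sqrt(sum(tg^2)))
}

#' Extract a centerline from a lumen mask
#'
#' Distance-transform-weighted shortest path between an inlet and an
#' outlet point: the path cost penalizes proximity to the lumen boundary
#' so the route follows locally maximal distance-to-boundary voxels. The
#' raw voxel path is smoothed with a moving average and resampled at
#' 1 mm arclength steps.
#'
#' @param lumen_mask 3D logical array.
#' @param spacing isotropic voxel size (mm).
#' @param inlet_point,outlet_point world coordinates (mm) inside the mask.
#' @param stations optional named landmark arclengths to attach.
#' @return an `aorta_centerline`.
#' @export
extract_centerline <- function(lumen_mask, spacing, inlet_point,
                               outlet_point, stations = NULL) {
  lumen_mask <- lumen_mask != 0
  d <- dim(lumen_mask)
  vin <- round(inlet_point / spacing) + 1L
  vout <- round(outlet_point / spacing) + 1L
  inside <- function(v) all(v >= 1) && all(v <= d) &&
    lumen_mask[v[1], v[2], v[3]]
  if (!inside(vin)) stop("inlet point outside the lumen mask")
  if (!inside(vout)) stop("outlet point outside the lumen mask")
  dt <- .cpp_edt3(lumen_mask)          # voxel units
  idx <- which(lumen_mask)
  nvox <- length(idx)
  lut <- integer(prod(d)); lut[idx] <- seq_len(nvox)
  co <- arrayInd(idx, d)
  # 26-neighbourhood edges
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & (offs %*% c(1, 10, 100)) > 0, ]
  ee_from <- integer(0); ee_to <- integer(0); ee_w <- numeric(0)
  # inverse-square medial weighting: strongly prefers the lumen axis so
  # curved segments do not cut the inner corner
  invdt <- 1 / (dt[idx] + 0.5)^2
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nbl <- lut[nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
               (nb[ok, 3] - 1L) * d[1] * d[2]]
    src <- which(ok)[nbl > 0]
    dst <- nbl[nbl > 0]
    w <- sqrt(sum(offs[r, ]^2)) * 0.5 * (invdt[src] + invdt[dst])
    ee_from <- c(ee_from, src); ee_to <- c(ee_to, dst); ee_w <- c(ee_w, w)
  }
  g <- igraph::graph_from_edgelist(cbind(ee_from, ee_to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nvox - igraph::vcount(g)))
  a <- lut[vin[1] + (vin[2] - 1L) * d[1] + (vin[3] - 1L) * d[1] * d[2]]
  b <- lut[vout[1] + (vout[2] - 1L) * d[1] + (vout[3] - 1L) * d[1] * d[2]]
  sp <- igraph::shortest_paths(g, from = a, to = b, weights = ee_w,
                               output = "vpath")$vpath[[1]]
  if (length(sp) < 2) stop("lumen mask is disconnected between the points")
  path <- (co[as.integer(sp), , drop = FALSE] - 1) * spacing
  # moving-average smoothing (window ~ 5 voxels), endpoints kept
  w <- 5L
  if (nrow(path) > 2 * w) {
    sm <- path
    for (k in 1:3) {
      sm[, k] <- stats::filter(path[, k], rep(1 / w, w), sides = 2)
    }
    keep <- !is.na(sm[, 1])
    path <- rbind(path[1, ], sm[keep, , drop = FALSE],
                  path[nrow(path), ])
  }
  # resample at 1 mm steps
  ds <- c(0, cumsum(row_norms(diff(path))))
  keep <- c(TRUE, diff(ds) > 1e-9)
  path <- path[keep, , drop = FALSE]; ds <- ds[keep]
  sgrid <- seq(0, max(ds), by = 1)
  rs <- vapply(1:3, function(k) approx(ds, path[, k], sgrid)$y,
               numeric(length(sgrid)))
  centerline(rs, stations)
}

roi_names <- c("pAAo", "dAAo", "pDAo", "dDAo", "excluded")

#' Label mesh vertices with thoracic aortic regions of interest
#'
#' Each vertex is assigned the region of its nearest centerline point:
#' proximal ascending (annulus to pulmonary-artery-bifurcation level),
#' distal ascending (to the brachiocephalic trunk), the arch between the
#' brachiocephalic trunk and left subclavian artery is excluded, proximal
#' descending (left subclavian to the PA-bifurcation level on the
#' descending limb, matched by axial height) and distal descending (down
#' to the diaphragm). Vertices beyond the diaphragm are excluded.
#'
#' @param mesh an `aorta_mesh`.
#' @param cl an `aorta_centerline` with stations.
#' @return factor of length n_vertices with levels
#'   pAAo, dAAo, pDAo, dDAo, excluded.
#' @export
label_rois <- function(mesh, cl) {
  if (is.null(cl$stations)) stop("centerline has no stations")
  st <- cl$stations
  nn <- knn_points(mesh$vertices, cl$points, 1L)
  s <- cl$arclength[nn$idx[, 1]]
  pa_desc <- descending_pa_level(cl)
  lab <- rep("excluded", nrow(mesh$vertices))
  lab[s >= st["annulus"] & s < st["PA_bifurcation"]] <- "pAAo"
  lab[s >= st["PA_bifurcation"] & s < st["brachiocephalic"]] <- "dAAo"
  lab[s >= st["left_subclavian"] & s < pa_desc] <- "pDAo"
  lab[s >= pa_desc & s <= st["diaphragm"]] <- "dDAo"
  factor(lab, levels = roi_names)
}

# Arclength on the descending limb at the axial height of the
# PA-bifurcation station (axial axis = mean descending tangent). When
# no descending point reaches that height (degenerate or straight
# geometries), fall back to the midpoint of the descending region.
descending_pa_level <- function(cl) {
  st <- cl$stations
  desc <- which(cl$arclength >= st["left_subclavian"])
  mid <- (st[["left_subclavian"]] + st[["diaphragm"]]) / 2
  if (length(desc) < 2) return(mid)
  # axial direction from the distal third of the centerline, which is
  # reliably descending (points just past the left subclavian may
  # still curve over the arch)
  smax <- max(cl$arclength)
  distal <- which(cl$arclength >= smax - 0.3 * smax)
  axis <- colMeans(cl$tangent[distal, , drop = FALSE])
  axis <- axis / sqrt(sum(axis^2))
  h <- cl$points %*% axis
  h_pa <- centerline_at(cl, st[["PA_bifurcation"]])$point %*% axis
  i <- desc[which.min(abs(h[desc] - c(h_pa)))]
  if (abs(h[i] - c(h_pa)) > 5) return(mid)
  max(cl$arclength[i], st[["left_subclavian"]])
}

#' Measure the lumen diameter at a centerline station
#'
#' The mesh is sliced by the plane through the centerline point
#' perpendicular to the local tangent. The default reports the
#' area-equivalent diameter 2*sqrt(A/pi) of the cross-section loop
#' nearest the centerline; `mode = "cusp_to_cusp"` reports the maximum
#' point-pair distance in that section, as used at the aortic root.
#'
#' @param mesh an `aorta_mesh`.
#' @param cl an `aorta_centerline`.
#' @param station_arclength arclength (mm) along the centerline.
#' @param mode "area" (default) or "cusp_to_cusp".
#' @return diameter in mm.
#' @export
measure_diameter <- function(mesh, cl, station_arclength,
                             mode = c("area", "cusp_to_cusp")) {
  mode <- match.arg(mode)
  if (station_arclength < 0 || station_arclength > max(cl$arclength)) {
    stop("station outside the centerline range")
  }
  loc <- centerline_at(cl, station_arclength)
  sec <- plane_section(mesh, loc$point, loc$tangent)
  if (is.null(sec)) stop("empty mesh slice at the requested station")
  if (mode == "cusp_to_cusp") {
    P <- sec$points
    max(dist(P))
  } else {
    2 * sqrt(sec$area / pi)
  }
}

# Intersect the mesh with a plane (point c0, unit normal nrm); returns
# the loop nearest c0 as directed segments, its enclosed area and its
# points. NULL if the plane misses the mesh.
plane_section <- function(mesh, c0, nrm) {
  nrm <- nrm / sqrt(sum(nrm^2))
  V <- mesh$vertices
  F <- mesh$faces
  sd <- as.vector((V - matrix(c0, nrow(V), 3, byrow = TRUE)) %*% nrm)
  sd[sd == 0] <- 1e-9        # vertices exactly on the plane
  s1 <- sd[F[, 1]]; s2 <- sd[F[, 2]]; s3 <- sd[F[, 3]]
  cross <- (pmax(s1, s2, s3) > 0) & (pmin(s1, s2, s3) < 0)
  if (!any(cross)) return(NULL)
  Fc <- F[cross, , drop = FALSE]
  seg_a <- matrix(0, nrow(Fc), 3); seg_b <- matrix(0, nrow(Fc), 3)
  for (r in seq_len(nrow(Fc))) {
    vs <- Fc[r, ]
    dv <- sd[vs]
    pts <- list()
    for (e in list(c(1, 2), c(2, 3), c(1, 3))) {
      da <- dv[e[1]]; db <- dv[e[2]]
      if ((da > 0) != (db > 0)) {
        t <- da / (da - db)
        pts[[length(pts) + 1]] <- V[vs[e[1]], ] + t * (V[vs[e[2]], ] - V[vs[e[1]], ])
      }
    }
    if (length(pts) == 2) {
      # direct the segment by triangle winding: t = n_tri x n_plane
      e1 <- V[vs[2], ] - V[vs[1], ]; e2 <- V[vs[3], ] - V[vs[1], ]
      ntri <- c(e1[2] * e2[3] - e1[3] * e2[2],
                e1[3] * e2[1] - e1[1] * e2[3],
                e1[1] * e2[2] - e1[2] * e2[1])
      dir <- c(ntri[2] * nrm[3] - ntri[3] * nrm[2],
               ntri[3] * nrm[1] - ntri[1] * nrm[3],
               ntri[1] * nrm[2] - ntri[2] * nrm[1])
      ab <- pts[[2]] - pts[[1]]
      if (sum(ab * dir) >= 0) {
        seg_a[r, ] <- pts[[1]]; seg_b[r, ] <- pts[[2]]
      } else {
        seg_a[r, ] <- pts[[2]]; seg_b[r, ] <- pts[[1]]
      }
    } else {
      seg_a[r, ] <- NA
    }
  }
  ok <- !is.na(seg_a[, 1])
  seg_a <- seg_a[ok, , drop = FALSE]; seg_b <- seg_b[ok, , drop = FALSE]
  nseg <- nrow(seg_a)
  if (nseg == 0) return(NULL)
  # keep the local cross-section: the plane may also cut the opposite
  # limb of a curved vessel, which lies much farther from c0
  mid <- (seg_a + seg_b) / 2
  d0 <- row_norms(mid - matrix(c0, nseg, 3, byrow = TRUE))
  sel <- d0 < 1.6 * min(d0) + 2
  a <- seg_a[sel, , drop = FALSE] - matrix(c0, sum(sel), 3, byrow = TRUE)
  b <- seg_b[sel, , drop = FALSE] - matrix(c0, sum(sel), 3, byrow = TRUE)
  # closed directed loops sum their edge vectors to zero
  closure <- sqrt(sum(colSums(b - a)^2))
  perim <- sum(row_norms(b - a))
  if (perim <= 0 || closure > 0.05 * perim) {
    stop("mesh slice is open or multi-looped at this station")
  }
  crossab <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                   a[, 3] * b[, 1] - a[, 1] * b[, 3],
                   a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area <- abs(sum(crossab %*% nrm)) / 2
  list(area = area, points = rbind(seg_a[sel, ], seg_b[sel, ]))
}
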