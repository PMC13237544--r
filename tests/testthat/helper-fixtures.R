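# Shared fixtures, built once and cached for the whole test run.

.fx <- new.env()

# binary sphere mask, radius mm, voxel size 1 mm
sphere_mask <- function(radius = 8, pad = 4) {
  d <- 2 * (radius + pad) + 1
  ctr <- radius + pad
  g <- 0:(d - 1)
  P <- as.matrix(expand.grid(g, g, g))
  array(sqrt(rowSums(sweep(P, 2, rep(ctr, 3))^2)) <= radius,
        dim = c(d, d, d))
}

# binary axis-aligned cylinder mask along z
cylinder_mask <- function(radius = 10, len = 60, spacing = 1, pad = 4) {
  nxy <- ceiling(2 * (radius + pad * spacing) / spacing) + 1
  nz <- ceiling((len + 2 * pad * spacing) / spacing) + 1
  cx <- (nxy - 1) / 2 * spacing
  z0 <- pad * spacing
  g <- (0:(nxy - 1)) * spacing
  gz <- (0:(nz - 1)) * spacing
  P <- expand.grid(x = g, y = g, z = gz)
  inside <- (P$x - cx)^2 + (P$y - cx)^2 <= radius^2 &
    P$z >= z0 & P$z <= z0 + len
  list(mask = array(inside, dim = c(nxy, nxy, nz)),
       center = c(cx, cx), z0 = z0, spacing = spacing)
}

# parametric open cylinder mesh along z (analytic, no voxelization);
# optional per-axis radii for elliptic sections
tube_mesh <- function(radius = 10, len = 60, n_theta = 48, n_z = 40,
                      ry = NULL) {
  if (is.null(ry)) ry <- radius
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  z <- seq(0, len, length.out = n_z)
  V <- cbind(rep(radius * cos(th), n_z),
             rep(ry * sin(th), n_z),
             rep(z, each = n_theta))
  f <- list()
  for (iz in 1:(n_z - 1)) {
    for (it in 1:n_theta) {
      a <- (iz - 1) * n_theta + it
      b <- (iz - 1) * n_theta + (it %% n_theta) + 1
      c2 <- iz * n_theta + it
      d2 <- iz * n_theta + (it %% n_theta) + 1
      f[[length(f) + 1]] <- c(a, b, d2)
      f[[length(f) + 1]] <- c(a, d2, c2)
    }
  }
  surface_mesh(V, do.call(rbind, f))
}

# straight centerline along z with stations spanning the full range
straight_centerline <- function(len = 60, x = 0, y = 0,
                                stations = NULL) {
  pts <- cbind(x, y, seq(0, len, by = 1))
  if (is.null(stations)) {
    stations <- c(annulus = 0, PA_bifurcation = 0.25 * len,
                  brachiocephalic = 0.45 * len,
                  left_subclavian = 0.55 * len, diaphragm = len)
  }
  centerline(pts, stations)
}

# cached Poiseuille tube subject (the analytic WSS oracle geometry)
poiseuille_tube <- function() {
  if (is.null(.fx$tube)) {
    .fx$tube <- synthetic_tube(radius = 10, length = 100, v_max = 100,
                               spacing = 1, viscosity = 3.2e-3)
  }
  .fx$tube
}

poiseuille_mesh <- function() {
  if (is.null(.fx$tube_mesh)) {
    .fx$tube_mesh <- mask_to_surface(poiseuille_tube()$lumen_mask, 1)
  }
  .fx$tube_mesh
}

# small decimated cylinder mesh for registration/atlas tests
small_cyl <- function() {
  if (is.null(.fx$small_cyl)) {
    cm <- cylinder_mask(radius = 10, len = 60, spacing = 1.5)
    .fx$small_cyl <- mask_to_surface(cm$mask, 1.5, target_edge = 2.5)
  }
  .fx$small_cyl
}
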