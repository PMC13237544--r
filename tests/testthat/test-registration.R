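test_that("identity registration returns the source unchanged", {
  m <- small_cyl()
  def <- register_nonrigid(m, m)
  expect_lt(mean(aortamap:::row_norms(def$mapped_vertices - m$vertices)),
            1e-3)
  expect_lt(def$mean_residual, 1e-6)
  expect_true(def$converged)
})

test_that("a rigid 5 mm translation is recovered", {
  m <- small_cyl()
  m2 <- surface_mesh(sweep(m$vertices, 2, c(5, 0, 0), "+"), m$faces)
  def <- register_nonrigid(m, m2)
  d <- aortamap:::row_norms(def$mapped_vertices - m$vertices)
  expect_equal(mean(d), 5, tolerance = 0.2 / 5)
  expect_true(def$converged)
})

test_that("a 1 mm radial inflation is recovered", {
  m <- small_cyl()
  ctr <- colMeans(m$vertices)
  rad <- m$vertices
  rad[, 1] <- rad[, 1] - ctr[1]; rad[, 2] <- rad[, 2] - ctr[2]
  rad[, 3] <- 0
  rad <- rad / pmax(sqrt(rowSums(rad^2)), 1e-9)
  m2 <- surface_mesh(m$vertices + rad, m$faces)
  def <- register_nonrigid(m, m2)
  d <- aortamap:::row_norms(def$mapped_vertices - m$vertices)
  expect_equal(mean(d), 1, tolerance = 0.15)
})

test_that("registration residual does not exceed the pre-registration
           surface distance", {
  m <- small_cyl()
  specs <- subject_spec(spacing = 2.5, n_phases = 2, perturb_scale = 0.5,
                        seed = 5)
  s <- make_subject(specs, with_velocity = FALSE)
  m2 <- mask_to_surface(s$lumen_mask, 2.5, target_edge = 2.5)
  pre <- symmetric_surface_distance(m, m2)
  def <- register_nonrigid(m, m2)
  expect_lte(def$mean_residual, pre)
})

test_that("the smoothness of the deformation bounds neighbour differences", {
  m <- small_cyl()
  m2 <- surface_mesh(sweep(m$vertices, 2, c(3, 2, 0), "+"), m$faces)
  def <- register_nonrigid(m, m2)
  disp <- def$mapped_vertices - m$vertices
  F <- m$faces
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(1, 3)])
  dd <- aortamap:::row_norms(disp[e[, 1], ] - disp[e[, 2], ])
  expect_lt(max(dd), 1)   # mm between adjacent vertices
})

test_that("template selection picks the central geometry", {
  m <- small_cyl()
  expect_equal(select_template(list(m, m, m)), 1L)  # tie -> lowest index
  big <- surface_mesh(m$vertices * 1.5, m$faces)
  expect_equal(select_template(list(m, big, m)) %in% c(1L, 3L), TRUE)
  # two identical + one inflated: one of the identical pair wins
  infl <- surface_mesh(m$vertices +
                         5 * m$normals, m$faces)
  expect_true(select_template(list(m, infl, m)) %in% c(1L, 3L))
})

test_that("template selection is permutation-equivariant and
           translation-invariant", {
  m <- small_cyl()
  a <- m
  b <- surface_mesh(m$vertices + 2 * m$normals, m$faces)
  c2 <- surface_mesh(m$vertices + 4 * m$normals, m$faces)
  i1 <- select_template(list(a, b, c2))
  perm <- c(3, 1, 2)
  i2 <- select_template(list(a, b, c2)[perm])
  expect_equal(perm[i2], i1)
  sh <- function(mm) surface_mesh(sweep(mm$vertices, 2, c(7, -3, 2), "+"),
                                  mm$faces)
  expect_equal(select_template(list(sh(a), sh(b), sh(c2))), i1)
})

test_that("interpolation reproduces constant, exact and linear fields", {
  m <- small_cyl()
  def <- register_nonrigid(m, m)
  cst <- interpolate_to_mesh(rep(3.5, nrow(m$vertices)), def, m)
  expect_equal(cst, rep(3.5, nrow(m$vertices)), tolerance = 1e-9)
  vals <- seq_len(nrow(m$vertices)) * 1.0
  expect_equal(interpolate_to_mesh(vals, def, m), vals, tolerance = 1e-6)
  # linear field across a registration to a denser mesh
  dense <- mask_to_surface(poiseuille_tube()$lumen_mask, 1)
  lin <- dense$vertices[, 1]
  def2 <- register_nonrigid(dense, dense)
  m_lin <- interpolate_to_mesh(lin, def2, dense)
  expect_lt(max(abs(m_lin - lin)), 0.1)
})

test_that("vector interpolation can renormalize", {
  m <- small_cyl()
  def <- register_nonrigid(m, m)
  out <- interpolate_to_mesh(m$normals, def, m, renormalize = TRUE)
  expect_equal(sqrt(rowSums(out^2)), rep(1, nrow(out)), tolerance = 1e-9)
})

test_that("empty inputs are rejected", {
  m <- small_cyl()
  expect_error(select_template(list(m)), "two")
  def <- register_nonrigid(m, m)
  expect_error(interpolate_to_mesh(numeric(0), def, m), "empty|bound")
})
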