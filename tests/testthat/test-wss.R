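test_that("peak systole is the phase of highest mean lumen speed", {
  spec <- subject_spec(shape = "straight", desc_length = 50, radius = 8,
                       radius_distal = 8, perturb_scale = 0,
                       n_phases = 10, spacing = 2,
                       displacement_amplitude = c(pAAo = 0, dAAo = 0,
                                                  pDAo = 0, dDAo = 0),
                       seed = 2)
  s <- make_subject(spec)
  pk <- peak_systole_frame(s$velocity, s$lumen_mask)
  # brute-force oracle over phases
  idx <- which(s$lumen_mask)
  nv <- prod(dim(s$lumen_mask))
  means <- sapply(s$velocity, function(a) {
    mean(sqrt(a[idx]^2 + a[idx + nv]^2 + a[idx + 2 * nv]^2))
  })
  expect_equal(pk, which.max(means))
  expect_equal(pk, s$ground_truth$peak_phase)
  # all-zero field: earliest phase wins the tie
  zeros <- lapply(s$velocity, function(a) a * 0)
  expect_equal(peak_systole_frame(zeros, s$lumen_mask), 1L)
  expect_error(peak_systole_frame(zeros, s$lumen_mask & FALSE), "empty")
})

test_that("Poiseuille flow yields the analytic WSS 2 mu v_max / r", {
  s <- poiseuille_tube()
  m <- poiseuille_mesh()
  cl <- s$ground_truth$centerline
  w <- wss_vectors(s$velocity[[1]], m, cl, s$lumen_mask, s$spacing)
  lab <- label_rois(m, cl)
  sel <- lab != "excluded" & !w$flagged
  expect_equal(mean(w$magnitude[sel]), 0.64, tolerance = 0.05)
  expect_gt(mean(abs(w$magnitude[sel] - 0.64) <= 0.1 * 0.64), 0.9)
})

test_that("WSS vectors are tangential and magnitude-consistent", {
  s <- poiseuille_tube()
  m <- poiseuille_mesh()
  w <- wss_vectors(s$velocity[[1]], m, s$ground_truth$centerline,
                   s$lumen_mask, s$spacing)
  dot <- abs(rowSums(w$vectors * m$normals))
  expect_true(all(dot <= 1e-6 * w$magnitude + 1e-9))
  expect_equal(w$magnitude, sqrt(rowSums(w$vectors^2)), tolerance = 1e-12)
})

test_that("WSS is linear in velocity and viscosity", {
  s <- poiseuille_tube()
  m <- decimate_mesh(poiseuille_mesh(), 3)
  cl <- s$ground_truth$centerline
  w1 <- wss_vectors(s$velocity[[1]], m, cl, s$lumen_mask, s$spacing)
  w2 <- wss_vectors(s$velocity[[1]] * 2.5, m, cl, s$lumen_mask, s$spacing)
  expect_equal(w2$magnitude, 2.5 * w1$magnitude, tolerance = 1e-9)
  w3 <- wss_vectors(s$velocity[[1]], m, cl, s$lumen_mask, s$spacing,
                    viscosity = 6.4e-3)
  expect_equal(w3$magnitude, 2 * w1$magnitude, tolerance = 1e-12)
})

test_that("zero velocity gives a zero WSS map", {
  s <- poiseuille_tube()
  m <- decimate_mesh(poiseuille_mesh(), 3)
  w <- wss_vectors(s$velocity[[1]] * 0, m, s$ground_truth$centerline,
                   s$lumen_mask, s$spacing)
  expect_true(all(w$magnitude == 0))
})

test_that("the three-point quadratic matches an independent symbolic fit", {
  # uniform wall-parallel velocity field: samples (0, v, v) after the
  # no-slip override; oracle = derivative of the lm-fitted quadratic
  v <- 80  # cm/s
  D <- 20  # mm
  h <- D / 4
  fit <- lm(y ~ x + I(x^2),
            data = data.frame(x = c(0, h, 2 * h) * 1e-3,
                              y = c(0, v, v) * 0.01))
  dydx0 <- coef(fit)[["x"]]
  expect_equal(dydx0, (4 * v - v) * 0.01 / (2 * h * 1e-3),
               tolerance = 1e-9)
  # package path on a synthetic uniform field
  s <- poiseuille_tube()
  m <- decimate_mesh(poiseuille_mesh(), 3)
  cl <- s$ground_truth$centerline
  vf <- s$velocity[[1]]
  vf[, , , 1] <- 0; vf[, , , 2] <- 0
  vf[, , , 3] <- array(as.double(s$lumen_mask) * v, dim = dim(s$lumen_mask))
  w <- wss_vectors(vf, m, cl, s$lumen_mask, s$spacing)
  lab <- label_rois(m, cl)
  sel <- lab != "excluded" & !w$flagged
  Dv <- local_lumen_diameter(m, cl)[sel]
  pred <- 3.2e-3 * 3 * (v * 0.01) / (2 * (Dv / 4) * 1e-3)
  # interpolation near the wall smears the discontinuous plug profile;
  # check order-of-magnitude agreement of the median ratio
  expect_equal(median(w$magnitude[sel] / pred), 1, tolerance = 0.35)
})

test_that("local lumen diameter tracks the tube radius", {
  s <- poiseuille_tube()
  m <- poiseuille_mesh()
  cl <- s$ground_truth$centerline
  lab <- label_rois(m, cl)
  D <- local_lumen_diameter(m, cl)
  expect_equal(median(D[lab != "excluded"]), 20, tolerance = 0.025)
  expect_true(all(abs(D[lab != "excluded"] - 20) < 2))
  # tapered tube: D follows 2 r(s) within 5%
  spec <- subject_spec(shape = "straight", desc_length = 100, radius = 15,
                       radius_distal = 10, perturb_scale = 0,
                       n_phases = 2, spacing = 1.5, steady = TRUE,
                       displacement_amplitude = c(pAAo = 0, dAAo = 0,
                                                  pDAo = 0, dDAo = 0),
                       seed = 1)
  st <- make_subject(spec, with_velocity = FALSE)
  mt <- mask_to_surface(st$lumen_mask, 1.5)
  clt <- st$ground_truth$centerline
  labt <- label_rois(mt, clt)
  Dt <- local_lumen_diameter(mt, clt)
  nn <- aortamap:::knn_points(mt$vertices, clt$points, 1L)
  rtrue <- approx(st$ground_truth$radius_profile$s,
                  st$ground_truth$radius_profile$r_avg,
                  clt$arclength[nn$idx[, 1]])$y
  sel <- labt != "excluded"
  expect_lt(median(abs(Dt[sel] / (2 * rtrue[sel]) - 1)), 0.05)
})

test_that("regional WSS recovers the generator ground truth", {
  spec <- subject_spec(spacing = 2, n_phases = 6, perturb_scale = 0.3,
                       seed = 31)
  s <- make_subject(spec)
  m <- mask_to_surface(s$lumen_mask, 2, target_edge = 2)
  cl <- s$ground_truth$centerline
  pk <- peak_systole_frame(s$velocity, s$lumen_mask)
  w <- wss_vectors(s$velocity[[pk]], m, cl, s$lumen_mask, 2)
  lab <- label_rois(m, cl)
  est <- roi_means(w$magnitude, lab, m$vertex_area, w$flagged)
  gt <- s$ground_truth$table
  expect_lt(max(abs(est[gt$region] / gt$wss_pa - 1)), 0.15)
})
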