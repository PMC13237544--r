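test_that("voxelized tube volume matches the analytic volume", {
  s <- poiseuille_tube()
  vol <- sum(s$lumen_mask) * s$spacing^3
  expect_lt(abs(vol / (pi * 10^2 * 100) - 1), 0.05)
})

test_that("zero displacement amplitude gives identical phase masks", {
  spec <- subject_spec(shape = "straight", desc_length = 50, radius = 8,
                       radius_distal = 8, perturb_scale = 0,
                       n_phases = 4, spacing = 2,
                       displacement_amplitude = c(pAAo = 0, dAAo = 0,
                                                  pDAo = 0, dDAo = 0),
                       seed = 2)
  s <- make_subject(spec, with_velocity = FALSE)
  for (k in 2:4) expect_identical(s$phase_masks[[k]], s$phase_masks[[1]])
})

test_that("no wave speed means a synchronous pulse at all planes", {
  spec <- subject_spec(shape = "straight", desc_length = 80, radius = 8,
                       radius_distal = 8, perturb_scale = 0,
                       n_phases = 10, spacing = 2, wave_speed = NULL,
                       displacement_amplitude = c(pAAo = 0, dAAo = 0,
                                                  pDAo = 0, dDAo = 0),
                       seed = 2)
  s <- make_subject(spec)
  cl <- s$ground_truth$centerline
  wfs <- plane_flow_waveforms(s$velocity, s$lumen_mask, cl, 2,
                              n_planes = 4, phase_times = s$phase_times)
  peaks <- apply(wfs$waveforms, 1, which.max)
  expect_true(all(peaks == peaks[1]))
})

test_that("ground-truth WSS is the Poiseuille value 2 mu v_max / r", {
  # oracle: d/drho [v_max (1 - rho^2/r^2)] at rho = r gives 2 v_max / r;
  # with r = 10 mm, v_max = 100 cm/s, mu = 3.2e-3 Pa s -> 0.64 Pa
  s <- poiseuille_tube()
  expect_equal(s$ground_truth$table$wss_pa,
               rep(2 * 3.2e-3 * 1 / 0.01, 4), tolerance = 1e-10)
})

test_that("velocity is zero outside the lumen and maximal on the axis", {
  s <- poiseuille_tube()
  v <- s$velocity[[1]]
  vmag <- sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
  expect_true(all(vmag[!s$lumen_mask] == 0))
  imax <- which(vmag == max(vmag), arr.ind = TRUE)[1, ]
  # axis of the straight tube runs through the grid at the centerline x/y
  cl <- s$ground_truth$centerline
  axis_xy <- cl$points[1, 1:2]
  expect_lt(max(abs((imax[1:2] - 1) * s$spacing - axis_xy)), s$spacing + 1e-9)
  expect_equal(max(vmag), 100, tolerance = 0.02)
})

test_that("traveling-wave peak lag between planes equals distance over c", {
  c_mps <- 4
  spec <- subject_spec(shape = "straight", desc_length = 160, radius = 10,
                       radius_distal = 10, perturb_scale = 0,
                       n_phases = 40, spacing = 2, wave_speed = c_mps,
                       displacement_amplitude = c(pAAo = 0, dAAo = 0,
                                                  pDAo = 0, dDAo = 0),
                       seed = 2)
  s <- make_subject(spec)
  cl <- s$ground_truth$centerline
  wfs <- plane_flow_waveforms(s$velocity, s$lumen_mask, cl, 2,
                              n_planes = 3, phase_times = s$phase_times,
                              dt_ms = 5)
  t1 <- wfs$times[which.max(wfs$waveforms[1, ])]
  t3 <- wfs$times[which.max(wfs$waveforms[3, ])]
  ds <- wfs$arclengths[3] - wfs$arclengths[1]
  dt_sample <- diff(s$phase_times)[1]
  expect_lt(abs((t3 - t1) - ds / c_mps), dt_sample + 1e-9)
})

test_that("cohorts are reproducible and Bernoulli assignment is in range", {
  a <- draw_cohort_params(c(control = 3, native = 2, ars = 2), seed = 42)
  b <- draw_cohort_params(c(control = 3, native = 2, ars = 2), seed = 42)
  expect_identical(a$regional, b$regional)
  expect_identical(a$manifest, b$manifest)

  ab <- list(region = "pDAo", kind = "increase", multiplier = 2,
             parameter = "displacement")
  d <- draw_cohort_params(c(control = 0, native = 40, ars = 0),
                          prevalence = 0.5, abnormality = ab, seed = 9)
  k <- sum(d$manifest$abnormal)
  # binomial 95% central range for n = 40, p = 0.5
  expect_gte(k, qbinom(0.025, 40, 0.5))
  expect_lte(k, qbinom(0.975, 40, 0.5))
})

test_that("controls never receive abnormality patches", {
  ab <- list(region = "pAAo", kind = "decrease", multiplier = 0.5,
             parameter = "displacement")
  d <- draw_cohort_params(c(control = 5, native = 0, ars = 0),
                          prevalence = 1, abnormality = ab, seed = 3)
  expect_false(any(d$manifest$abnormal))
})

test_that("degenerate geometry and bad prevalence are rejected", {
  expect_error(subject_spec(radius = 3, radius_distal = 3, spacing = 2),
               "degenerate")
  expect_error(draw_cohort_params(c(control = 2), prevalence = 1.5),
               "prevalence")
  expect_error(subject_spec(n_phases = 1), "n_phases")
})
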