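#' Reference regional values for the synthetic cohort
#'
#' Typical peak wall displacement (mm), peak intraluminal velocity (cm/s)
#' and pulse wave velocity (m/s) for healthy adults and for Marfan
#' patients without ("native") and with ("ars") aortic root surgery, per
#' thoracic region: proximal/distal ascending (pAAo, dAAo) and
#' proximal/distal descending (pDAo, dDAo) aorta. Between-subject
#' standard deviations are included; these define the population the
#' cohort generator draws from.
#'
#' @return a list with `displacement`, `velocity` (4 x 3 mean matrices
#'   plus matching `*_sd`), and `pwv` (per-group mean/sd, m/s).
#' @export
cohort_reference <- function() {
  rn <- c("pAAo", "dAAo", "pDAo", "dDAo")
  gn <- c("control", "native", "ars")
  disp <- matrix(c(9.8, 9.0, 5.8,
                   4.5, 4.6, 4.3,
                   1.5, 1.4, 1.6,
                   1.8, 1.7, 1.3), 4, 3, byrow = TRUE,
                 dimnames = list(rn, gn))
  disp_sd <- matrix(c(1.2, 1.9, 1.5,
                      1.0, 1.2, 1.2,
                      0.4, 0.4, 0.5,
                      0.4, 0.5, 0.4), 4, 3, byrow = TRUE,
                    dimnames = list(rn, gn))
  vel <- matrix(c(73.2, 65.1, 78.4,
                  62.0, 62.7, 69.0,
                  76.9, 69.6, 66.5,
                  82.6, 76.3, 74.2), 4, 3, byrow = TRUE,
                dimnames = list(rn, gn))
  vel_sd <- matrix(c(9.5, 9.4, 12.1,
                     12.2, 11.2, 10.7,
                     9.2, 12.9, 13.5,
                     11.9, 13.3, 14.3), 4, 3, byrow = TRUE,
                   dimnames = list(rn, gn))
  pwv <- c(control = 6.6, native = 9.0, ars = 10.0)
  pwv_sd <- c(control = 1.4, native = 3.5, ars = 2.7)
  list(displacement = disp, displacement_sd = disp_sd,
       velocity = vel, velocity_sd = vel_sd,
       pwv = pwv, pwv_sd = pwv_sd)
}

#' Specification of one synthetic aortic subject
#'
#' Defines a candy-cane aortic geometry (half-torus arch joined to a
#' straight descending limb) or a straight tube, its cyclic wall motion,
#' the intraluminal velocity field and any injected localized
#' abnormalities. Wall radius follows r(s,t) = r0(s) + amp(s) * w(t)
#' with w a raised-cosine systolic pulse over the first 40 percent of
#' the cycle; velocity is a near-parabolic profile along the local
#' tangent, optionally delayed by s/c for a traveling wave of speed c.
#'
#' @param group one of "control", "native", "ars".
#' @param shape "candy_cane" or "straight".
#' @param arch_radius arch (half-torus) radius, mm.
#' @param desc_length descending limb length, mm (also the tube length
#'   for `shape = "straight"`).
#' @param radius root lumen radius, mm (tapers linearly to
#'   `radius_distal` at the distal end).
#' @param radius_distal distal lumen radius, mm.
#' @param perturb_scale scale (mm) of smooth low-frequency random radial
#'   perturbations emulating between-subject shape variability.
#' @param n_phases cardiac phases per cycle (>= 2).
#' @param cycle_ms cardiac cycle duration, ms.
#' @param spacing isotropic voxel size, mm.
#' @param displacement_amplitude named per-region peak wall excursion,
#'   mm (pAAo, dAAo, pDAo, dDAo).
#' @param velocity_peak named per-region peak centerline velocity, cm/s.
#' @param wave_speed pulse wave speed c in m/s, or `NULL` for a
#'   synchronous pulse (zero delay everywhere).
#' @param viscosity dynamic viscosity used for the analytic wall shear
#'   stress ground truth, Pa s.
#' @param abnormalities list of abnormality patches; each a list with
#'   `region`, `kind` ("increase"/"decrease"), `multiplier`,
#'   `parameter` ("displacement" or "velocity"), optional `angle_deg`
#'   (half-width of an angular sector centered on the outer curvature,
#'   `NULL` = full circumference) and `s_frac` (span within the region).
#' @param steady if `TRUE`, w(t) is held at 1 (static geometry, steady
#'   flow); used for analytic flow oracles.
#' @param seed integer seed controlling the shape perturbation.
#' @return an object of class `aorta_subject_spec`.
#' @export
subject_spec <- function(group = "control",
                         shape = c("candy_cane", "straight"),
                         arch_radius = 35, desc_length = 120,
                         radius = 15, radius_distal = 10,
                         perturb_scale = 0.5,
                         n_phases = 30L, cycle_ms = 1000,
                         spacing = 1.0,
                         displacement_amplitude = NULL,
                         velocity_peak = NULL,
                         wave_speed = NULL,
                         viscosity = 3.2e-3,
                         abnormalities = list(),
                         steady = FALSE,
                         seed = 1L) {
  shape <- match.arg(shape)
  ref <- cohort_reference()
  if (is.null(displacement_amplitude)) {
    displacement_amplitude <- ref$displacement[, group]
  }
  if (is.null(velocity_peak)) velocity_peak <- ref$velocity[, group]
  if (n_phases < 2) stop("n_phases must be >= 2")
  if (spacing <= 0) stop("spacing must be positive")
  if (any(displacement_amplitude < 0)) stop("amplitudes must be >= 0")
  if (min(radius, radius_distal) <= 2 * spacing) {
    stop("degenerate geometry: lumen radius must exceed 2 * spacing")
  }
  structure(list(group = group, shape = shape, arch_radius = arch_radius,
                 desc_length = desc_length, radius = radius,
                 radius_distal = radius_distal,
                 perturb_scale = perturb_scale,
                 n_phases = as.integer(n_phases), cycle_ms = cycle_ms,
                 spacing = spacing,
                 displacement_amplitude = displacement_amplitude,
                 velocity_peak = velocity_peak,
                 wave_speed = wave_speed, viscosity = viscosity,
                 abnormalities = abnormalities, steady = steady,
                 seed = as.integer(seed)),
            class = "aorta_subject_spec")
}

# raised-cosine systolic pulse: bump over the first 40% of the cycle
pulse_wave <- function(t_ms, cycle_ms) {
  t <- t_ms %% cycle_ms
  sys <- 0.4 * cycle_ms
  ifelse(t < sys, 0.5 * (1 - cos(2 * pi * t / sys)), 0)
}

# analytic centerline for a spec (1 mm steps), with stations and the
# outward-curvature direction per point
spec_centerline <- function(spec) {
  if (spec$shape == "candy_cane") {
    R <- spec$arch_radius
    L <- spec$desc_length
    s_arch <- seq(0, pi * R, by = 1)
    th <- s_arch / R
    arch <- cbind(R * cos(th), 0, R * sin(th))
    s_desc <- seq(1, L, by = 1)
    desc <- cbind(-R, 0, -s_desc)
    pts <- rbind(arch, desc)
    total <- pi * R + L
    stations <- c(annulus = 5,
                  PA_bifurcation = 0.20 * pi * R,
                  brachiocephalic = 0.40 * pi * R,
                  left_subclavian = 0.60 * pi * R,
                  diaphragm = total - 5)
    # outward direction: radially away from the arch center on the
    # arch, -x (outer curvature side) on the descending limb
    e_out <- rbind(cbind(cos(th), 0, sin(th)),
                   matrix(rep(c(-1, 0, 0), length(s_desc)),
                          ncol = 3, byrow = TRUE))
  } else {
    L <- spec$desc_length
    s <- seq(0, L, by = 1)
    pts <- cbind(0, 0, s)
    stations <- c(annulus = 5, PA_bifurcation = 0.25 * L,
                  brachiocephalic = 0.45 * L,
                  left_subclavian = 0.55 * L, diaphragm = L - 5)
    e_out <- matrix(rep(c(1, 0, 0), length(s)), ncol = 3, byrow = TRUE)
  }
  cl <- centerline(pts, stations)
  cl$e_out <- e_out[seq_len(nrow(cl$points)), , drop = FALSE]
  cl
}

# per-region arclength intervals, including the descending split at the
# PA-bifurcation axial level
roi_intervals <- function(cl) {
  st <- cl$stations
  s_pd <- descending_pa_level(cl)
  data.frame(region = c("pAAo", "dAAo", "arch", "pDAo", "dDAo"),
             s0 = c(st[["annulus"]], st[["PA_bifurcation"]],
                    st[["brachiocephalic"]], st[["left_subclavian"]], s_pd),
             s1 = c(st[["PA_bifurcation"]], st[["brachiocephalic"]],
                    st[["left_subclavian"]], s_pd, st[["diaphragm"]]))
}

# piecewise-regional profile over the centerline arclength grid,
# linearly blended across the (excluded) arch and lightly smoothed
regional_profile <- function(cl, values) {
  iv <- roi_intervals(cl)
  s <- cl$arclength
  out <- numeric(length(s))
  get <- function(r) values[[r]]
  for (r in c("pAAo", "dAAo", "pDAo", "dDAo")) {
    row <- iv[iv$region == r, ]
    out[s >= row$s0 & s < row$s1] <- get(r)
  }
  arch <- iv[iv$region == "arch", ]
  in_arch <- s >= arch$s0 & s < arch$s1
  if (any(in_arch)) {
    u <- (s[in_arch] - arch$s0) / max(arch$s1 - arch$s0, 1e-9)
    out[in_arch] <- (1 - u) * get("dAAo") + u * get("pDAo")
  }
  out[s < iv$s0[1]] <- get("pAAo")
  out[s >= iv$s1[nrow(iv)]] <- get("dDAo")
  # moving-average smoothing, 5 mm window: enough to avoid step
  # discontinuities at region boundaries while keeping cross-region
  # contamination of the band means small
  k <- rep(1 / 5, 5)
  sm <- stats::filter(out, k, sides = 2)
  out[!is.na(sm)] <- sm[!is.na(sm)]
  out
}

# angular patch multiplier field over (centerline index, angle) pairs
# returns multiplicative factor per sample given its s and unit radial
# direction u (rows), for one abnormality entry
patch_factor <- function(ab, s, u, cl) {
  iv <- roi_intervals(cl)
  row <- iv[iv$region == ab$region, ]
  sf <- if (is.null(ab$s_frac)) c(0, 1) else ab$s_frac
  s0 <- row$s0 + sf[1] * (row$s1 - row$s0)
  s1 <- row$s0 + sf[2] * (row$s1 - row$s0)
  inside <- s >= s0 & s < s1
  if (!is.null(ab$angle_deg)) {
    i <- pmin(pmax(round(s) + 1L, 1L), nrow(cl$e_out))
    cosang <- rowSums(u * cl$e_out[i, , drop = FALSE])
    inside <- inside & cosang >= cos(ab$angle_deg * pi / 180)
  }
  f <- rep(1, length(s))
  f[inside] <- ab$multiplier
  f
}

#' Does each point fall inside an injected abnormality patch?
#'
#' Used to check that detected abnormality hot-spots are localized
#' within the ground-truth patch.
#'
#' @param points n x 3 world coordinates (mm).
#' @param subject an `aorta_subject` (or its ground truth).
#' @param ab one abnormality entry from the subject's spec.
#' @return logical vector of length n.
#' @export
patch_indicator <- function(points, subject, ab) {
  gt <- if (inherits(subject, "aorta_subject")) subject$ground_truth else subject
  cl <- gt$centerline
  nn <- knn_points(points, cl$points, 1L)
  s <- cl$arclength[nn$idx[, 1]]
  u <- unit_rows(points - cl$points[nn$idx[, 1], , drop = FALSE])
  patch_factor(ab, s, u, cl) != 1
}

#' Generate one synthetic aortic subject
#'
#' Voxelizes the subject geometry of a [subject_spec()] into
#' time-resolved binary phase masks, a time-averaged lumen mask and a
#' per-phase 3-component velocity field (cm/s), together with landmark
#' stations and an analytic ground-truth table (per-region wall
#' excursion, peak velocity, Poiseuille wall shear stress
#' 2 mu v_max / r, and wave speed). Voxel centers sit at 0-based integer
#' grid coordinates times `spacing`.
#'
#' @param spec an `aorta_subject_spec`.
#' @param with_velocity generate the velocity field (can be disabled for
#'   displacement-only studies to save memory).
#' @return an object of class `aorta_subject` with fields `phase_masks`,
#'   `phase_times`, `lumen_mask`, `velocity`, `spacing`, `landmarks`,
#'   `ground_truth`, `group`, `spec`.
#' @export
make_subject <- function(spec, with_velocity = TRUE) {
  set.seed(spec$seed)
  sp <- spec$spacing
  cl <- spec_centerline(spec)
  s <- cl$arclength
  total <- max(s)
  # tapering base radius + smooth low-frequency perturbation
  r0 <- spec$radius + (spec$radius_distal - spec$radius) * s / total
  if (spec$perturb_scale > 0) {
    z <- stats::rnorm(3); ph <- stats::runif(3, 0, 2 * pi)
    pert <- spec$perturb_scale *
      Reduce(`+`, lapply(1:3, function(k) {
        z[k] * sin(k * pi * s / total + ph[k]) / k
      }))
    r0 <- r0 + pert
  }
  if (any(r0 <= 2 * sp)) {
    stop("degenerate geometry: lumen radius must exceed 2 * spacing")
  }
  amp_vals <- as.list(spec$displacement_amplitude)
  vel_vals <- as.list(spec$velocity_peak)
  amp <- regional_profile(cl, amp_vals)
  vpk <- regional_profile(cl, vel_vals)

  # pulse samples
  tms <- (seq_len(spec$n_phases) - 1) * spec$cycle_ms / spec$n_phases
  w <- if (spec$steady) rep(1, spec$n_phases) else pulse_wave(tms, spec$cycle_ms)
  w_max <- max(w)
  w_mean <- mean(w)

  # grid: shift the centerline into positive world coordinates
  margin <- max(r0) + max(amp) * w_max + 4 * sp
  lo <- apply(cl$points, 2, min) - margin
  hi <- apply(cl$points, 2, max) + margin
  shift <- -lo
  cl$points <- unname(sweep(cl$points, 2, shift, "+"))
  dims <- unname(pmax(ceiling((hi - lo) / sp) + 1L, 2L))
  # voxel world coordinates
  gx <- (seq_len(dims[1]) - 1) * sp
  gy <- (seq_len(dims[2]) - 1) * sp
  gz <- (seq_len(dims[3]) - 1) * sp
  P <- cbind(rep(gx, times = dims[2] * dims[3]),
             rep(rep(gy, each = dims[1]), times = dims[3]),
             rep(gz, each = dims[1] * dims[2]))
  nn <- knn_points(P, cl$points, 1L)
  ci <- nn$idx[, 1]
  rho <- nn$dist[, 1]
  svox <- s[ci]
  # candidate voxels near the wall or inside; trim flat end caps by
  # dropping voxels that overshoot the first/last centerline point
  cand <- which(rho <= r0[ci] + max(amp) * w_max + 2 * sp)
  nlast <- nrow(cl$points)
  at_end <- ci[cand] == 1L | ci[cand] == nlast
  if (any(at_end)) {
    pe <- cand[at_end]
    over <- rowSums((P[pe, , drop = FALSE] -
                       cl$points[ci[pe], , drop = FALSE]) *
                      cl$tangent[ci[pe], , drop = FALSE])
    drop <- (ci[pe] == 1L & over < 0) | (ci[pe] == nlast & over > 0)
    cand <- setdiff(cand, pe[drop])
  }
  u_cand <- unit_rows(P[cand, , drop = FALSE] -
                        cl$points[ci[cand], , drop = FALSE])
  # abnormality patches modulate the local amplitude / velocity
  amp_fac <- rep(1, length(cand))
  vel_fac <- rep(1, length(cand))
  for (ab in spec$abnormalities) {
    f <- patch_factor(ab, svox[cand], u_cand, cl)
    par <- if (is.null(ab$parameter)) "displacement" else ab$parameter
    if (par == "displacement") amp_fac <- amp_fac * f else vel_fac <- vel_fac * f
  }
  amp_vox <- amp[ci[cand]] * amp_fac
  r0_vox <- r0[ci[cand]]
  rho_c <- rho[cand]

  empty <- array(FALSE, dim = dims)
  phase_masks <- vector("list", spec$n_phases)
  for (k in seq_len(spec$n_phases)) {
    m <- empty
    m[cand[rho_c <= r0_vox + amp_vox * w[k]]] <- TRUE
    phase_masks[[k]] <- m
  }
  lumen <- empty
  r_avg_vox <- r0_vox + amp_vox * w_mean
  lumen[cand[rho_c <= r_avg_vox]] <- TRUE

  velocity <- NULL
  if (with_velocity) {
    inl <- rho_c <= r_avg_vox
    iv <- cand[inl]
    tang <- cl$tangent[ci[iv], , drop = FALSE]
    prof <- pmax(0, 1 - (rho_c[inl] / r_avg_vox[inl])^2)
    vmag0 <- vpk[ci[iv]] * vel_fac[inl] * prof    # cm/s at w = 1
    delay <- if (is.null(spec$wave_speed)) 0 else svox[iv] / spec$wave_speed
    velocity <- vector("list", spec$n_phases)
    for (k in seq_len(spec$n_phases)) {
      wk <- if (spec$steady) rep(1, length(iv)) else
        pulse_wave(tms[k] - delay, spec$cycle_ms)
      arr <- array(0, dim = c(dims, 3))
      v <- vmag0 * wk
      for (c3 in 1:3) {
        comp <- array(0, dim = dims)
        comp[iv] <- v * tang[, c3]
        arr[, , , c3] <- comp
      }
      velocity[[k]] <- arr
    }
  }

  # per-region analytic ground truth
  iv4 <- roi_intervals(cl)
  iv4 <- iv4[iv4$region != "arch", ]
  gt_tab <- do.call(rbind, lapply(seq_len(nrow(iv4)), function(r) {
    selr <- s >= iv4$s0[r] & s < iv4$s1[r]
    r_avg <- mean(r0[selr]) + mean(amp[selr]) * w_mean
    v_pk <- mean(vpk[selr]) * w_max          # cm/s realized at peak
    data.frame(region = iv4$region[r],
               displacement_mm = mean(amp[selr]) * w_max,
               velocity_peak_cms = v_pk,
               wss_pa = 2 * spec$viscosity * (v_pk * 0.01) / (r_avg * 1e-3))
  }))
  landmarks <- cl$stations
  gt <- list(table = gt_tab, wave_speed = spec$wave_speed,
             ed_phase = 1L, peak_phase = which.max(w),
             systole_peak_w = w_max, viscosity = spec$viscosity,
             centerline = cl,
             radius_profile = data.frame(s = s, r0 = r0,
                                         r_avg = r0 + amp * w_mean),
             amplitude_profile = data.frame(s = s, amp = amp),
             abnormalities = spec$abnormalities)
  structure(list(phase_masks = phase_masks, phase_times = tms,
                 lumen_mask = lumen, velocity = velocity, spacing = sp,
                 landmarks = landmarks, ground_truth = gt,
                 group = spec$group, spec = spec),
            class = "aorta_subject")
}

#' @export
print.aorta_subject <- function(x, ...) {
  cat(sprintf(
    "<aorta_subject> group %s, %d phases, grid %s, spacing %.2g mm\n",
    x$group, length(x$phase_masks),
    paste(dim(x$lumen_mask), collapse = "x"), x$spacing))
  invisible(x)
}

#' Straight-tube subject with Poiseuille flow
#'
#' Convenience wrapper around [make_subject()] for analytic oracles: a
#' straight cylinder of constant radius with steady parabolic flow.
#'
#' @param radius lumen radius, mm.
#' @param length tube length, mm.
#' @param v_max centerline velocity, cm/s.
#' @param spacing voxel size, mm.
#' @param viscosity Pa s.
#' @param n_phases number of (identical) phases.
#' @return an `aorta_subject`.
#' @export
synthetic_tube <- function(radius = 10, length = 100, v_max = 100,
                           spacing = 1.0, viscosity = 3.2e-3,
                           n_phases = 2L) {
  spec <- subject_spec(shape = "straight", desc_length = length,
                       radius = radius, radius_distal = radius,
                       perturb_scale = 0, n_phases = n_phases,
                       spacing = spacing,
                       displacement_amplitude = c(pAAo = 0, dAAo = 0,
                                                  pDAo = 0, dDAo = 0),
                       velocity_peak = c(pAAo = v_max, dAAo = v_max,
                                         pDAo = v_max, dDAo = v_max),
                       viscosity = viscosity, steady = TRUE, seed = 1L)
  make_subject(spec)
}

#' Generate a synthetic cohort
#'
#' Draws subjects for the three study groups with independent
#' per-subject shape and amplitude jitter around the group reference
#' values of [cohort_reference()] (normal jitter, truncated at
#' physiologic floors). Abnormality patches are assigned to patients
#' (non-control subjects) by independent Bernoulli draws at the given
#' prevalence, and the assignment is recorded in the manifest. Fully
#' reproducible for a given seed.
#'
#' @param n_per_group named counts, e.g. `c(control = 5, native = 0,
#'   ars = 0)`.
#' @param group_effects optional list overriding per-group per-region
#'   mean displacement multipliers, e.g.
#'   `list(ars = c(pAAo = 0.6, dAAo = 1, pDAo = 1, dDAo = 1))`.
#' @param prevalence fraction of patients receiving each abnormality in
#'   `abnormality`.
#' @param abnormality an abnormality entry (see [subject_spec()])
#'   injected at the given prevalence, or `NULL`.
#' @param spacing,n_phases,perturb_scale forwarded to [subject_spec()].
#' @param wave_speed `NA` (default) draws per-subject group-specific wave
#'   speeds; `NULL` disables the traveling delay; a number fixes it.
#' @param with_velocity generate velocity fields.
#' @param seed master seed.
#' @return list with `subjects` (list of `aorta_subject`) and `manifest`
#'   (data.frame: id, group, seed, abnormal).
#' @export
make_cohort <- function(n_per_group = c(control = 5, native = 0, ars = 0),
                        group_effects = NULL, prevalence = 0,
                        abnormality = NULL,
                        spacing = 2.0, n_phases = 30L,
                        perturb_scale = 0.5, wave_speed = NA,
                        with_velocity = TRUE, seed = 1L) {
  par <- draw_cohort_params(n_per_group, group_effects, prevalence,
                            abnormality = abnormality,
                            wave_speed = wave_speed, seed = seed)
  n <- nrow(par$manifest)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    p <- par$params[[i]]
    spec <- subject_spec(group = p$group,
                         arch_radius = p$arch_radius,
                         desc_length = p$desc_length,
                         radius = p$radius,
                         radius_distal = p$radius_distal,
                         perturb_scale = perturb_scale,
                         n_phases = n_phases, spacing = spacing,
                         displacement_amplitude = p$displacement,
                         velocity_peak = p$velocity,
                         wave_speed = p$wave_speed,
                         abnormalities = p$abnormalities,
                         seed = p$seed)
    subjects[[i]] <- make_subject(spec, with_velocity = with_velocity)
  }
  list(subjects = subjects, manifest = par$manifest)
}

#' Draw per-subject cohort parameters without voxelization
#'
#' The population layer of [make_cohort()]: per-subject geometry jitter,
#' per-region displacement amplitudes and peak velocities (normal
#' between-subject variation around the group reference values,
#' truncated at physiologic floors), wave speeds, and Bernoulli
#' abnormality assignment. [make_cohort()] voxelizes exactly these
#' draws; using them directly gives measurement-level cohorts (the
#' generator's ground truth) for statistical studies that do not need
#' the imaging stage.
#'
#' @inheritParams make_cohort
#' @return list with `manifest` (id, group, seed, abnormal), `params`
#'   (per-subject list), and `regional` (data.frame: id, group, per-ROI
#'   true peak displacement mm, velocity cm/s, wave speed m/s).
#' @export
draw_cohort_params <- function(n_per_group, group_effects = NULL,
                               prevalence = 0, abnormality = NULL,
                               wave_speed = NA, seed = 1L) {
  if (prevalence < 0 || prevalence > 1) stop("prevalence outside [0, 1]")
  ref <- cohort_reference()
  groups <- rep(names(n_per_group), times = n_per_group)
  n <- length(groups)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  abn_draw <- stats::runif(n)
  jitter <- list(
    arch_radius = stats::rnorm(n, 35, 2),
    desc_length = stats::rnorm(n, 120, 8),
    radius = stats::rnorm(n, 15, 1),
    radius_distal = stats::rnorm(n, 10, 0.7),
    disp = matrix(stats::rnorm(4 * n), 4, n),
    vel = matrix(stats::rnorm(4 * n), 4, n),
    pwv = stats::rnorm(n))
  rn <- c("pAAo", "dAAo", "pDAo", "dDAo")
  params <- vector("list", n)
  abnormal <- logical(n)
  for (i in seq_len(n)) {
    g <- groups[i]
    dm <- ref$displacement[, g]
    if (!is.null(group_effects) && !is.null(group_effects[[g]])) {
      dm <- ref$displacement[, "control"] * group_effects[[g]][rn]
    }
    disp <- pmax(dm + ref$displacement_sd[, g] * jitter$disp[, i], 0.1)
    vel <- pmax(ref$velocity[, g] + ref$velocity_sd[, g] * jitter$vel[, i], 5)
    ws <- if (is.null(wave_speed)) NULL
          else if (is.na(wave_speed)) {
            max(ref$pwv[g] + ref$pwv_sd[g] * jitter$pwv[i], 1)
          } else wave_speed
    abs_i <- list()
    if (!is.null(abnormality) && g != "control" &&
        abn_draw[i] < prevalence) {
      abs_i <- list(abnormality)
      abnormal[i] <- TRUE
    }
    params[[i]] <- list(group = g, seed = sub_seeds[i],
                        arch_radius = jitter$arch_radius[i],
                        desc_length = jitter$desc_length[i],
                        radius = jitter$radius[i],
                        radius_distal = jitter$radius_distal[i],
                        displacement = setNames(disp, rn),
                        velocity = setNames(vel, rn),
                        wave_speed = ws,
                        abnormalities = abs_i)
  }
  manifest <- data.frame(id = sprintf("S%03d", seq_len(n)),
                         group = groups, seed = sub_seeds,
                         abnormal = abnormal, stringsAsFactors = FALSE)
  regional <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- params[[i]]
    data.frame(id = manifest$id[i], group = p$group,
               region = rn, displacement_mm = unname(p$displacement),
               velocity_cms = unname(p$velocity),
               wave_speed = if (is.null(p$wave_speed)) NA_real_
                            else p$wave_speed)
  }))
  list(manifest = manifest, params = params, regional = regional)
}
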