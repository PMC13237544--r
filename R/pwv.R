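#' Plane-wise flow waveforms along the centerline
#'
#' Places planes perpendicular to the centerline at equal arclength
#' spacing, integrates the through-plane velocity over the lumen
#' cross-section per cardiac phase (flow in mL/s), and linearly
#' resamples every waveform to a fixed temporal resolution (default
#' 20 ms).
#'
#' @param velocity list (one per phase) of 4D arrays, cm/s.
#' @param lumen_mask 3D logical array.
#' @param cl an `aorta_centerline`.
#' @param spacing voxel size, mm.
#' @param n_planes number of planes (>= 3).
#' @param phase_times acquisition times, ms from the R-wave.
#' @param cycle_ms cardiac cycle duration; defaults to the phase grid
#'   extended by one step.
#' @param dt_ms target temporal resolution after resampling (ms).
#' @param margin arclength (mm) excluded at both centerline ends.
#' @return an `aorta_waveforms` object: `arclengths` (mm per plane),
#'   `waveforms` (planes x samples, mL/s), `dt` (ms), `times` (ms).
#' @export
plane_flow_waveforms <- function(velocity, lumen_mask, cl, spacing,
                                 n_planes = 8L, phase_times,
                                 cycle_ms = NULL, dt_ms = 20,
                                 margin = 10) {
  if (n_planes < 3) stop("need at least 3 planes")
  smax <- max(cl$arclength)
  ss <- seq(margin, smax - margin, length.out = n_planes)
  if (is.null(cycle_ms)) {
    cycle_ms <- max(phase_times) + stats::median(diff(phase_times))
  }
  nph <- length(velocity)
  raw <- matrix(0, n_planes, nph)
  keep <- rep(TRUE, n_planes)
  for (p in seq_len(n_planes)) {
    loc <- centerline_at(cl, ss[p])
    nrm <- loc$tangent
    # in-plane sample lattice at voxel resolution
    e1 <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * nrm) * nrm
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
            nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    rmax <- 30
    g <- seq(-rmax, rmax, by = spacing)
    uv <- as.matrix(expand.grid(g, g))
    pts <- matrix(loc$point, nrow(uv), 3, byrow = TRUE) +
      uv[, 1] %o% e1 + uv[, 2] %o% e2
    inl <- mask_at_points(lumen_mask, pts, spacing)
    if (!any(inl)) { keep[p] <- FALSE; next }
    pts <- pts[inl, , drop = FALSE]
    dA <- spacing^2                       # mm^2
    for (k in seq_len(nph)) {
      vn <- interp_trilinear(velocity[[k]][, , , 1], pts, spacing) * nrm[1] +
            interp_trilinear(velocity[[k]][, , , 2], pts, spacing) * nrm[2] +
            interp_trilinear(velocity[[k]][, , , 3], pts, spacing) * nrm[3]
      vn[!is.finite(vn)] <- 0
      # cm/s * mm^2 = 10 mm^3/s; mL/s = mm^3/s / 1000
      raw[p, k] <- sum(vn) * dA / 100
    }
  }
  if (any(!keep)) {
    warning(sum(!keep), " plane(s) with no lumen samples dropped")
    raw <- raw[keep, , drop = FALSE]
    ss <- ss[keep]
  }
  tgrid <- seq(0, cycle_ms - dt_ms, by = dt_ms)
  wf <- t(apply(raw, 1, function(y) {
    approx(phase_times, y, xout = tgrid, rule = 2)$y
  }))
  structure(list(arclengths = ss, waveforms = wf, dt = dt_ms,
                 times = tgrid), class = "aorta_waveforms")
}

# arrival time (ms) of the systolic upstroke foot: intersection of the
# regression through the 20-80% upslope with the pre-upstroke baseline
foot_arrival <- function(y, t, dt) {
  ipk <- which.max(y)
  if (ipk < 3) return(NA_real_)
  base <- min(y[1:ipk])
  amp <- y[ipk] - base
  if (amp <= 0) return(NA_real_)
  up <- which(y[1:ipk] >= base + 0.2 * amp & y[1:ipk] <= base + 0.8 * amp)
  if (length(up) < 2) {
    # coarse sampling: interpolate the 50% crossing instead
    lvl <- base + 0.5 * amp
    i <- max(which(y[1:ipk] <= lvl))
    if (i >= ipk) return(t[ipk])
    return(t[i] + dt * (lvl - y[i]) / (y[i + 1] - y[i]))
  }
  fit <- lm(yy ~ tt, data = data.frame(yy = y[up], tt = t[up]))
  b <- coef(fit)
  if (b[2] <= 0) return(NA_real_)
  unname((base - b[1]) / b[2])
}

# lag (ms) of y relative to ref maximizing the cross-correlation, with
# parabolic sub-sample refinement around the integer-lag peak
xcorr_lag <- function(ref, y, dt, max_lag_frac = 0.25) {
  n <- length(ref)
  maxl <- max(2L, floor(n * max_lag_frac))
  lags <- -maxl:maxl
  cc <- vapply(lags, function(L) {
    if (L >= 0) sum(ref[1:(n - L)] * y[(1 + L):n])
    else sum(ref[(1 - L):n] * y[1:(n + L)])
  }, numeric(1))
  i <- which.max(cc)
  lag <- lags[i]
  if (i > 1 && i < length(lags)) {
    a <- cc[i - 1]; b <- cc[i]; c <- cc[i + 1]
    den <- a - 2 * b + c
    if (abs(den) > 1e-12) lag <- lag + 0.5 * (a - c) / den
  }
  lag * dt
}

#' Transit-time pulse wave velocity
#'
#' Estimates the global aortic pulse wave velocity from plane-wise flow
#' waveforms: an arrival time per plane (systolic-upstroke foot, or lag
#' of maximal cross-correlation against the most proximal plane with
#' parabolic sub-sample refinement), then a least-squares fit of arrival
#' time against arclength; PWV is the inverse slope in m/s.
#'
#' @param wfs an `aorta_waveforms` object.
#' @param method "xcorr" (default) or "foot".
#' @return list with `pwv` (m/s, `NA` when flagged), `arrival_times`
#'   (ms), `arclengths`, `method`, `ok` (FALSE for non-positive or
#'   non-finite slope).
#' @export
estimate_pwv <- function(wfs, method = c("xcorr", "foot")) {
  method <- match.arg(method)
  W <- wfs$waveforms
  if (nrow(W) < 3) stop("need at least 3 usable planes")
  at <- if (method == "foot") {
    apply(W, 1, foot_arrival, t = wfs$times, dt = wfs$dt)
  } else {
    apply(W, 1, function(y) xcorr_lag(W[1, ], y, wfs$dt))
  }
  ok_pts <- is.finite(at)
  res <- list(pwv = NA_real_, arrival_times = at,
              arclengths = wfs$arclengths, method = method, ok = FALSE)
  if (sum(ok_pts) < 3) return(res)
  fit <- lm(at ~ s, data = data.frame(at = at[ok_pts],
                                      s = wfs$arclengths[ok_pts]))
  slope <- coef(fit)[["s"]]               # ms per mm
  if (!is.finite(slope) || slope <= 1e-9) return(res)
  res$pwv <- 1 / slope                    # mm/ms = m/s
  res$ok <- TRUE
  res
}
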