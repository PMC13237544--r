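#' Pipeline configuration
#'
#' Collects every tunable constant of the subject- and cohort-level
#' pipelines. The defaults reproduce the standard analysis: viscosity
#' 3.2e-3 Pa s, 95% confidence maps (1.96 SD), a 120-degree
#' vector-direction threshold, cross-correlation PWV after 20 ms
#' resampling, and the ROI-to-diameter-station pairing pAAo-root,
#' dAAo-ascending, pDAo-proximal descending, dDAo-diaphragm.
#'
#' @param viscosity dynamic viscosity, Pa s.
#' @param ci_multiplier SD multiplier of the normal interval.
#' @param direction_threshold_deg abnormal-direction angle threshold.
#' @param pwv_method "xcorr" or "foot".
#' @param pwv_planes number of flow planes.
#' @param pwv_dt_ms temporal resolution after resampling, ms.
#' @param mesh_edge vertex-clustering cell (mm) applied to extracted
#'   surfaces before registration; `NULL` keeps full resolution.
#' @param anova_threshold omnibus significance threshold.
#' @param incidence_classes abnormality classes mapped across patients.
#' @param seed seed for any stochastic stage.
#' @return a `aorta_run_config` list.
#' @export
run_config <- function(viscosity = 3.2e-3, ci_multiplier = 1.96,
                       direction_threshold_deg = 120,
                       pwv_method = "xcorr", pwv_planes = 8L,
                       pwv_dt_ms = 20, mesh_edge = 2.0,
                       anova_threshold = 0.0125,
                       incidence_classes = c("increased", "decreased"),
                       seed = 1L) {
  structure(list(viscosity = viscosity, ci_multiplier = ci_multiplier,
                 direction_threshold_deg = direction_threshold_deg,
                 pwv_method = pwv_method, pwv_planes = pwv_planes,
                 pwv_dt_ms = pwv_dt_ms, mesh_edge = mesh_edge,
                 anova_threshold = anova_threshold,
                 incidence_classes = incidence_classes, seed = seed),
            class = "aorta_run_config")
}

# every default the standard description leaves open, for the run log
config_decisions <- function(config) {
  list(viscosity_pa_s = config$viscosity,
       sd_convention = "sample (n-1)",
       ci_multiplier = config$ci_multiplier,
       direction_threshold_deg = config$direction_threshold_deg,
       direction_boundary = "angle exactly at threshold is normal",
       pwv_method = config$pwv_method,
       pwv_resample_ms = config$pwv_dt_ms,
       peak_frame_tiebreak = "earliest phase",
       template_tiebreak = "lowest index",
       roi_diameter_stations = c(pAAo = "root", dAAo = "ascending",
                                 pDAo = "desc_proximal",
                                 dDAo = "diaphragm"),
       rank_test = "rank-sum (Mann-Whitney) for independent groups",
       incidence_transfer = "nearest-neighbour (integer counts)")
}

#' Process one subject end to end
#'
#' Extracts surfaces and the centerline, computes the displacement
#' series and its peak frame, peak-systolic WSS vectors and core
#' velocities, the transit-time PWV, station diameters and
#' diameter-adjusted regional values. Stages fail independently: an
#' error in one stage is recorded and the remaining stages still run
#' (e.g. a missing velocity field yields a displacement-only report).
#'
#' @param subject an `aorta_subject` (or compatible list).
#' @param config an `aorta_run_config`.
#' @return an `aorta_subject_report` list.
#' @export
run_subject <- function(subject, config = run_config()) {
  errors <- list()
  note <- function(stage, e) errors[[stage]] <<- conditionMessage(e)
  sp <- subject$spacing
  cl <- subject$ground_truth$centerline
  lumen_mesh <- mask_to_surface(subject$lumen_mask, sp,
                                target_edge = config$mesh_edge)
  lumen_labels <- label_rois(lumen_mesh, cl)

  # displacement on the end-diastolic surface
  ed <- subject$ground_truth$ed_phase
  disp <- tryCatch({
    # full-resolution targets; decimated end-diastolic source carries
    # the map (decimating the targets would quantize the matches)
    phase_meshes <- lapply(subject$phase_masks, mask_to_surface,
                           spacing = sp)
    ed_mesh <- if (is.null(config$mesh_edge)) phase_meshes[[ed]] else
      decimate_mesh(phase_meshes[[ed]], config$mesh_edge)
    series <- displacement_series(phase_meshes, ed, ed_mesh = ed_mesh)
    peak <- peak_displacement(series)
    labels <- label_rois(ed_mesh, cl)
    list(ed_mesh = ed_mesh, labels = labels, peak = peak,
         map = peak$map$values,
         roi = roi_means(peak$map$values, labels, ed_mesh$vertex_area))
  }, error = function(e) { note("displacement", e); NULL })

  wss <- NULL; velo <- NULL; pwv <- NULL
  if (!is.null(subject$velocity)) {
    wss <- tryCatch({
      pk <- peak_systole_frame(subject$velocity, subject$lumen_mask)
      w <- wss_vectors(subject$velocity[[pk]], lumen_mesh, cl,
                       subject$lumen_mask, sp,
                       viscosity = config$viscosity)
      w$phase_index <- pk
      list(map = w, phase = pk,
           roi = roi_means(w$magnitude, lumen_labels,
                           lumen_mesh$vertex_area, w$flagged))
    }, error = function(e) { note("wss", e); NULL })
    velo <- tryCatch({
      pk <- if (!is.null(wss)) wss$phase else
        peak_systole_frame(subject$velocity, subject$lumen_mask)
      cv <- core_velocity_map(subject$velocity[[pk]], lumen_mesh, cl,
                              subject$lumen_mask, sp)
      list(map = cv,
           roi = roi_means(cv$values, lumen_labels,
                           lumen_mesh$vertex_area, cv$flagged))
    }, error = function(e) { note("velocity", e); NULL })
    pwv <- tryCatch({
      wfs <- plane_flow_waveforms(subject$velocity, subject$lumen_mask,
                                  cl, sp, n_planes = config$pwv_planes,
                                  phase_times = subject$phase_times,
                                  dt_ms = config$pwv_dt_ms)
      estimate_pwv(wfs, method = config$pwv_method)
    }, error = function(e) { note("pwv", e); NULL })
  } else {
    errors$velocity <- "no velocity field; displacement-only report"
  }

  diameters <- tryCatch({
    st <- cl$stations
    iv <- roi_intervals(cl)
    mid <- function(r) mean(unlist(iv[iv$region == r, c("s0", "s1")]))
    c(root = measure_diameter(lumen_mesh, cl, st[["annulus"]] + 3),
      ascending = measure_diameter(lumen_mesh, cl, mid("dAAo")),
      desc_proximal = measure_diameter(lumen_mesh, cl, mid("pDAo")),
      diaphragm = measure_diameter(lumen_mesh, cl,
                                   st[["diaphragm"]] - 3))
  }, error = function(e) { note("diameters", e); NULL })

  regional <- list(displacement = if (!is.null(disp)) disp$roi,
                   velocity = if (!is.null(velo)) velo$roi,
                   wss = if (!is.null(wss)) wss$roi)
  adjusted <- if (!is.null(diameters)) {
    diameter_adjust(regional, diameters)
  }
  structure(list(group = subject$group, lumen_mesh = lumen_mesh,
                 lumen_labels = lumen_labels, centerline = cl,
                 displacement = disp, wss = wss, velocity = velo,
                 pwv = pwv, diameters = diameters, regional = regional,
                 adjusted = adjusted, errors = errors,
                 config = config),
            class = "aorta_subject_report")
}

#' @export
print.aorta_subject_report <- function(x, ...) {
  cat("<aorta_subject_report>", x$group, "\n")
  for (p in names(x$regional)) {
    if (!is.null(x$regional[[p]])) {
      cat(sprintf("  %-12s %s\n", p,
                  paste(sprintf("%s=%.2f", names(x$regional[[p]]),
                                x$regional[[p]]), collapse = " ")))
    }
  }
  if (!is.null(x$pwv) && isTRUE(x$pwv$ok)) {
    cat(sprintf("  pwv          %.2f m/s\n", x$pwv$pwv))
  }
  if (length(x$errors)) {
    cat("  stage notes:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Process a cohort end to end
#'
#' Runs every subject, builds the control displacement / WSS atlases on
#' the control template, projects them onto each patient to produce
#' abnormality heatmaps, maps abnormal indicators across patients into
#' incidence maps on the patient template, quantifies abnormal surface
#' areas, audits pre/post-registration agreement, and assembles the
#' group statistics tables.
#'
#' @param subjects list of `aorta_subject`.
#' @param groups optional character vector of group labels (defaults to
#'   each subject's own `group`).
#' @param config an `aorta_run_config`.
#' @param verbose print progress.
#' @return an `aorta_cohort_report`.
#' @export
run_cohort <- function(subjects, groups = NULL, config = run_config(),
                       verbose = FALSE) {
  n <- length(subjects)
  if (is.null(groups)) {
    groups <- vapply(subjects, function(s) s$group, character(1))
  }
  reports <- vector("list", n)
  for (i in seq_len(n)) {
    if (verbose) message("subject ", i, "/", n, " (", groups[i], ")")
    reports[[i]] <- run_subject(subjects[[i]], config)
  }
  ctrl <- which(groups == "control")
  pats <- which(groups != "control")
  notes <- character(0)

  atlases <- NULL; heatmaps <- NULL; incidence <- NULL; audit <- NULL
  area_summaries <- NULL
  have_disp <- vapply(reports, function(r) !is.null(r$displacement),
                      logical(1))
  have_wss <- vapply(reports, function(r) !is.null(r$wss), logical(1))
  if (length(ctrl) >= 2 && all(have_disp[ctrl])) {
    ctrl_meshes <- lapply(reports[ctrl], function(r) r$displacement$ed_mesh)
    ctrl_maps <- lapply(reports[ctrl], function(r) r$displacement$map)
    disp_atlas <- build_scalar_atlas(ctrl_meshes, ctrl_maps,
                                     ci_multiplier = config$ci_multiplier)
    wss_atlas <- NULL; dir_atlas <- NULL
    if (all(have_wss[ctrl])) {
      wm <- lapply(reports[ctrl], function(r) r$lumen_mesh)
      wss_atlas <- build_scalar_atlas(
        wm, lapply(reports[ctrl], function(r) r$wss$map$magnitude),
        ci_multiplier = config$ci_multiplier)
      dir_atlas <- build_vector_atlas(
        wm, lapply(reports[ctrl], function(r) r$wss$map$vectors),
        template = wss_atlas$template_index)
    }
    atlases <- list(displacement = disp_atlas, wss = wss_atlas,
                    wss_direction = dir_atlas)
    # pre/post-registration audit on the controls
    tmpl_rep <- reports[ctrl][[disp_atlas$template_index]]
    audit <- tryCatch({
      pre <- unlist(lapply(reports[ctrl], function(r) r$displacement$roi))
      post <- unlist(lapply(seq_along(ctrl), function(j) {
        r <- reports[ctrl][[j]]
        if (j == disp_atlas$template_index) return(r$displacement$roi)
        def <- register_nonrigid(r$displacement$ed_mesh,
                                 disp_atlas$template)
        m <- interpolate_to_mesh(r$displacement$map, def,
                                 disp_atlas$template)
        roi_means(m, label_rois(disp_atlas$template,
                                tmpl_rep$centerline),
                  disp_atlas$template$vertex_area)
      }))
      registration_audit(pre, post)
    }, error = function(e) { notes <<- c(notes, conditionMessage(e)); NULL })

    if (length(pats)) {
      heatmaps <- lapply(pats, function(i) {
        r <- reports[[i]]
        hm <- list()
        if (!is.null(r$displacement)) {
          pr <- project_atlas(disp_atlas, r$displacement$ed_mesh)
          hm$displacement <- classify_scalar(r$displacement$map, pr)
        }
        if (!is.null(r$wss) && !is.null(wss_atlas)) {
          prw <- project_atlas(wss_atlas, r$lumen_mesh)
          hm$wss <- classify_scalar(r$wss$map$magnitude, prw)
          prd <- project_atlas(dir_atlas, r$lumen_mesh)
          hm$wss_direction <- classify_direction(
            r$wss$map$vectors, prd,
            threshold_deg = config$direction_threshold_deg)
        }
        hm
      })
      names(heatmaps) <- paste0("patient_", pats)
      area_summaries <- lapply(seq_along(pats), function(j) {
        r <- reports[[pats[j]]]
        hm <- heatmaps[[j]]
        out <- list()
        if (!is.null(hm$displacement)) {
          out$displacement <- abnormal_area_percent(
            hm$displacement, r$displacement$labels,
            r$displacement$ed_mesh$vertex_area)
        }
        if (!is.null(hm$wss)) {
          out$wss <- abnormal_area_percent(hm$wss, r$lumen_labels,
                                           r$lumen_mesh$vertex_area)
          out$wss_direction <- abnormal_area_percent(
            hm$wss_direction, r$lumen_labels, r$lumen_mesh$vertex_area)
        }
        out
      })
      if (length(pats) >= 1 && all(have_disp[pats])) {
        pat_meshes <- lapply(reports[pats],
                             function(r) r$displacement$ed_mesh)
        pat_hm <- lapply(heatmaps, function(h) h$displacement)
        incidence <- lapply(config$incidence_classes, function(cls) {
          build_incidence_map(pat_hm, pat_meshes, class = cls)
        })
        names(incidence) <- config$incidence_classes
      }
    }
  } else {
    notes <- c(notes,
               "insufficient controls with displacement; atlas stages skipped")
  }

  tables <- cohort_tables(reports, groups, area_summaries,
                          if (length(pats)) groups[pats], config)
  structure(list(reports = reports, groups = groups, atlases = atlases,
                 heatmaps = heatmaps, area_summaries = area_summaries,
                 incidence = incidence, audit = audit, tables = tables,
                 notes = notes, decisions = config_decisions(config),
                 config = config),
            class = "aorta_cohort_report")
}

# group-level summary and test tables (regional means, abnormal areas,
# correlations)
cohort_tables <- function(reports, groups, area_summaries, pat_groups,
                          config) {
  params <- c("displacement", "velocity", "wss")
  rows <- list()
  for (p in params) {
    for (r in quant_rois) {
      vals <- vapply(reports, function(rep) {
        v <- rep$regional[[p]]
        if (is.null(v)) NA_real_ else v[[r]]
      }, numeric(1))
      ok <- is.finite(vals)
      if (sum(ok) < 4 || length(unique(groups[ok])) < 2) next
      cmp <- tryCatch(
        compare_groups(vals[ok], groups[ok],
                       threshold = config$anova_threshold),
        error = function(e) NULL)
      if (is.null(cmp)) next
      rows[[paste(p, r)]] <- data.frame(parameter = p, roi = r,
                                        anova_p = cmp$anova_p)
    }
  }
  regional_tests <- if (length(rows)) do.call(rbind, c(rows,
                                                       make.row.names = FALSE))
  # PWV comparison
  pwv_vals <- vapply(reports, function(r) {
    if (!is.null(r$pwv) && isTRUE(r$pwv$ok)) r$pwv$pwv else NA_real_
  }, numeric(1))
  pwv_test <- tryCatch({
    ok <- is.finite(pwv_vals)
    if (sum(ok) >= 4) compare_groups(pwv_vals[ok], groups[ok],
                                     threshold = config$anova_threshold)
  }, error = function(e) NULL)
  # abnormal-area rank tests between the two patient groups
  area_tests <- NULL
  if (!is.null(area_summaries) && length(unique(pat_groups)) == 2) {
    pieces <- list()
    for (p in c("displacement", "wss", "wss_direction")) {
      per_pat <- lapply(area_summaries, function(s) s[[p]])
      if (any(vapply(per_pat, is.null, logical(1)))) next
      key <- per_pat[[1]][, c("roi", "class")]
      for (i in seq_len(nrow(key))) {
        vals <- vapply(per_pat, function(s) s$area_percent[i], numeric(1))
        g1 <- vals[pat_groups == "native"]
        g2 <- vals[pat_groups == "ars"]
        if (!length(g1) || !length(g2)) next
        ct <- compare_abnormal_areas(g1[is.finite(g1)], g2[is.finite(g2)])
        pieces[[paste(p, i)]] <- data.frame(
          parameter = p, roi = key$roi[i], class = key$class[i],
          native = ct$iqr_strings[["native"]],
          ars = ct$iqr_strings[["ars"]], p = ct$p)
      }
    }
    if (length(pieces)) {
      area_tests <- do.call(rbind, c(pieces, make.row.names = FALSE))
    }
  }
  # per-ROI displacement vs WSS correlations
  correlations <- NULL
  cors <- list()
  for (r in quant_rois) {
    d <- vapply(reports, function(rep) {
      v <- rep$regional$displacement
      if (is.null(v)) NA_real_ else v[[r]]
    }, numeric(1))
    w <- vapply(reports, function(rep) {
      v <- rep$regional$wss
      if (is.null(v)) NA_real_ else v[[r]]
    }, numeric(1))
    ok <- is.finite(d) & is.finite(w)
    if (sum(ok) >= 4) {
      cr <- tryCatch(correlate(d[ok], w[ok]), error = function(e) NULL)
      if (!is.null(cr)) {
        cors[[r]] <- data.frame(roi = r, r = cr$r, ci_lo = cr$ci[1],
                                ci_hi = cr$ci[2], p = cr$p, n = cr$n)
      }
    }
  }
  if (length(cors)) {
    correlations <- do.call(rbind, c(cors, make.row.names = FALSE))
  }
  list(regional_tests = regional_tests, pwv_test = pwv_test,
       area_tests = area_tests, correlations = correlations)
}

#' @export
print.aorta_cohort_report <- function(x, ...) {
  cat(sprintf("<aorta_cohort_report> %d subjects (%s)\n",
              length(x$reports),
              paste(names(table(x$groups)), table(x$groups),
                    sep = "=", collapse = ", ")))
  if (!is.null(x$tables$regional_tests)) {
    cat("regional ANOVA:\n"); print(x$tables$regional_tests)
  }
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Write the cohort report tables and maps to a directory
#'
#' @param report an `aorta_cohort_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tb <- report$tables
  if (!is.null(tb$regional_tests)) {
    write.csv(tb$regional_tests, file.path(dir, "regional_tests.csv"),
              row.names = FALSE)
  }
  if (!is.null(tb$area_tests)) {
    write.csv(tb$area_tests, file.path(dir, "abnormal_area_tests.csv"),
              row.names = FALSE)
  }
  if (!is.null(tb$correlations)) {
    write.csv(tb$correlations, file.path(dir, "correlations.csv"),
              row.names = FALSE)
  }
  meta <- list(decisions = report$decisions, notes = report$notes,
               audit = report$audit)
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$incidence)) {
    for (cls in names(report$incidence)) {
      im <- report$incidence[[cls]]
      write_vtk_polydata(im$template,
                         file.path(dir, sprintf("incidence_%s.vtk", cls)),
                         point_data = list(proportion = im$proportion))
    }
  }
  invisible(dir)
}
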