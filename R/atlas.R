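#' Control-cohort scalar atlas (mean, SD and 95% CI maps)
#'
#' Builds per-vertex normal-value statistics on a control geometry
#' template: every control surface is registered non-rigidly to the
#' template (chosen by [select_template()] unless given) and its map is
#' interpolated there; the per-vertex mean and sample standard deviation
#' are computed, and confidence bounds are the mean plus/minus
#' `ci_multiplier` times the SD (default 1.96, the 95% normal interval).
#'
#' @param control_meshes list of `aorta_mesh`.
#' @param control_maps list of per-vertex numeric vectors bound to the
#'   corresponding meshes.
#' @param template index of the template mesh, or `NULL` for automatic
#'   selection.
#' @param ci_multiplier width of the normal interval in SD units.
#' @param ... passed to [register_nonrigid()].
#' @return an `aorta_atlas`: list with `template_index`, `template`
#'   (mesh), `mean`, `sd`, `ci_lower`, `ci_upper`, `n_controls`,
#'   `ci_multiplier`, `excluded` (indices of controls that failed
#'   registration).
#' @export
build_scalar_atlas <- function(control_meshes, control_maps,
                               template = NULL, ci_multiplier = 1.96,
                               ...) {
  n <- length(control_meshes)
  if (n < 2) stop("need at least 2 controls")
  stopifnot(length(control_maps) == n)
  ti <- if (is.null(template)) select_template(control_meshes) else template
  tmpl <- control_meshes[[ti]]
  nv <- nrow(tmpl$vertices)
  vals <- matrix(NA_real_, nv, n)
  excluded <- integer(0)
  for (i in seq_len(n)) {
    if (i == ti) {
      vals[, i] <- control_maps[[i]]
      next
    }
    def <- register_nonrigid(control_meshes[[i]], tmpl, ...)
    if (!def$converged) {
      excluded <- c(excluded, i)
      warning("control ", i, " failed registration (mean residual ",
              round(def$mean_residual, 2), " mm); excluded")
      next
    }
    vals[, i] <- interpolate_to_mesh(control_maps[[i]], def, tmpl)
  }
  use <- setdiff(seq_len(n), excluded)
  if (length(use) < 2) {
    stop("fewer than 2 controls registered successfully; no atlas")
  }
  mu <- rowMeans(vals[, use, drop = FALSE])
  sdv <- apply(vals[, use, drop = FALSE], 1, sd)
  structure(list(template_index = ti, template = tmpl, mean = mu,
                 sd = sdv, ci_lower = mu - ci_multiplier * sdv,
                 ci_upper = mu + ci_multiplier * sdv,
                 n_controls = length(use), ci_multiplier = ci_multiplier,
                 excluded = excluded),
            class = "aorta_atlas")
}

#' @export
print.aorta_atlas <- function(x, ...) {
  cat(sprintf(
    "<aorta_atlas> %d template vertices, %d controls, mean %.2f, CI x%.2f\n",
    length(x$mean), x$n_controls, mean(x$mean), x$ci_multiplier))
  invisible(x)
}

#' Control-cohort vector-direction atlas
#'
#' Per template vertex, the average control vector direction: control
#' vectors are unit-normalized on their own meshes (zero vectors are
#' excluded), carried to the template through the registration, averaged
#' and renormalized. The resultant length (norm of the mean of unit
#' vectors, in [0, 1]) measures directional coherence; vertices with
#' resultant length below `eps` carry an undefined direction flag.
#'
#' @param control_meshes list of `aorta_mesh`.
#' @param control_vector_maps list of n x 3 matrices bound to the meshes.
#' @param template template index or `NULL` for automatic selection.
#' @param eps resultant-length threshold below which the mean direction
#'   is undefined.
#' @param ... passed to [register_nonrigid()].
#' @return an `aorta_vector_atlas`: `template_index`, `template`,
#'   `mean_direction` (unit rows; zero rows where undefined),
#'   `resultant_length`, `undefined` (logical), `n_controls`.
#' @export
build_vector_atlas <- function(control_meshes, control_vector_maps,
                               template = NULL, eps = 1e-6, ...) {
  n <- length(control_meshes)
  if (n < 2) stop("need at least 2 controls")
  ti <- if (is.null(template)) select_template(control_meshes) else template
  tmpl <- control_meshes[[ti]]
  nv <- nrow(tmpl$vertices)
  acc <- matrix(0, nv, 3)
  cnt <- numeric(nv)
  excluded <- integer(0)
  for (i in seq_len(n)) {
    u <- unit_rows(control_vector_maps[[i]])
    if (i == ti) {
      ui <- u
    } else {
      def <- register_nonrigid(control_meshes[[i]], tmpl, ...)
      if (!def$converged) { excluded <- c(excluded, i); next }
      ui <- interpolate_to_mesh(u, def, tmpl, renormalize = TRUE)
    }
    nz <- row_norms(ui) > 0
    acc[nz, ] <- acc[nz, ] + ui[nz, , drop = FALSE]
    cnt[nz] <- cnt[nz] + 1
  }
  used <- n - length(excluded)
  mean_vec <- acc / pmax(cnt, 1)
  rl <- row_norms(mean_vec)
  undefined <- rl < eps | cnt == 0
  dir <- mean_vec
  dir[!undefined, ] <- dir[!undefined, , drop = FALSE] / rl[!undefined]
  dir[undefined, ] <- 0
  structure(list(template_index = ti, template = tmpl,
                 mean_direction = dir, resultant_length = rl,
                 undefined = undefined, n_controls = used,
                 excluded = excluded),
            class = "aorta_vector_atlas")
}

#' Project an atlas onto a patient geometry
#'
#' Registers the control template to the patient surface and carries the
#' atlas fields over by inverse-distance interpolation (directions are
#' renormalized).
#'
#' @param atlas an `aorta_atlas` or `aorta_vector_atlas`.
#' @param patient_mesh target `aorta_mesh`.
#' @param ... passed to [register_nonrigid()].
#' @return for a scalar atlas: list with `mean`, `sd`, `ci_lower`,
#'   `ci_upper`, `ci_multiplier`, `flagged_subject`; for a vector atlas:
#'   list with `mean_direction`, `undefined`, `flagged_subject`. All
#'   fields are bound to the patient mesh.
#' @export
project_atlas <- function(atlas, patient_mesh, ...) {
  def <- register_nonrigid(atlas$template, patient_mesh, ...)
  flagged <- !def$converged
  if (inherits(atlas, "aorta_vector_atlas")) {
    dir <- interpolate_to_mesh(atlas$mean_direction, def, patient_mesh,
                               renormalize = TRUE)
    undef <- transfer_nearest(atlas$undefined, def, patient_mesh)
    list(mean_direction = dir, undefined = undef,
         flagged_subject = flagged)
  } else {
    list(mean = interpolate_to_mesh(atlas$mean, def, patient_mesh),
         sd = interpolate_to_mesh(atlas$sd, def, patient_mesh),
         ci_lower = interpolate_to_mesh(atlas$ci_lower, def, patient_mesh),
         ci_upper = interpolate_to_mesh(atlas$ci_upper, def, patient_mesh),
         ci_multiplier = atlas$ci_multiplier,
         flagged_subject = flagged)
  }
}

#' Classify vertices against projected normal bounds
#'
#' A vertex is `increased` strictly above the upper confidence bound,
#' `decreased` strictly below the lower bound, and `normal` otherwise
#' (boundary values are normal). Vertices where the projected SD is zero
#' are classified against exact equality with the mean and flagged.
#'
#' @param patient_map per-vertex values on the patient mesh.
#' @param bounds projection of a scalar atlas (see [project_atlas()]).
#' @return an `aorta_heatmap`: list with `labels` (factor: normal /
#'   increased / decreased), `flagged` (logical; degenerate-SD vertices).
#' @export
classify_scalar <- function(patient_map, bounds) {
  stopifnot(length(patient_map) == length(bounds$ci_lower))
  lab <- rep("normal", length(patient_map))
  lab[patient_map > bounds$ci_upper] <- "increased"
  lab[patient_map < bounds$ci_lower] <- "decreased"
  structure(list(labels = factor(lab, levels = c("normal", "increased",
                                                 "decreased")),
                 flagged = !is.finite(bounds$sd) | bounds$sd == 0),
            class = "aorta_heatmap")
}

#' Classify vector directions against the atlas mean direction
#'
#' A vertex is abnormal when the angle between the patient vector and
#' the projected mean control direction strictly exceeds the threshold
#' (default 120 degrees). Zero patient vectors and vertices with an
#' undefined atlas direction are normal-with-flag.
#'
#' @param patient_vectors n x 3 matrix on the patient mesh.
#' @param projection vector-atlas projection (see [project_atlas()]).
#' @param threshold_deg angular threshold in degrees.
#' @return an `aorta_heatmap` with labels normal / abnormal_direction
#'   and a `flagged` vector.
#' @export
classify_direction <- function(patient_vectors, projection,
                               threshold_deg = 120) {
  u <- unit_rows(patient_vectors)
  zero <- row_norms(patient_vectors) == 0
  dots <- rowSums(u * projection$mean_direction)
  # strict inequality with a guard so vectors at exactly the threshold
  # angle stay normal despite floating-point round-off
  cth <- cos(threshold_deg * pi / 180)
  abn <- dots < cth - 1e-9
  abn[zero | projection$undefined] <- FALSE
  lab <- ifelse(abn, "abnormal_direction", "normal")
  structure(list(labels = factor(lab, levels = c("normal",
                                                 "abnormal_direction")),
                 flagged = zero | projection$undefined),
            class = "aorta_heatmap")
}

#' @export
print.aorta_heatmap <- function(x, ...) {
  tb <- table(x$labels)
  cat("<aorta_heatmap>", paste(names(tb), tb, collapse = ", "),
      sprintf("(%d flagged)\n", sum(x$flagged)))
  invisible(x)
}

#' Cross-patient incidence map of abnormal vertices
#'
#' Registers every patient surface to a patient template (chosen by
#' [select_template()] unless given), carries each patient's binary
#' abnormality indicator over by nearest-neighbour transfer (so counts
#' stay integer), and reports the per-vertex proportion of patients with
#' the given abnormality class.
#'
#' @param patient_heatmaps list of `aorta_heatmap`.
#' @param patient_meshes list of `aorta_mesh` the heatmaps are bound to.
#' @param class abnormality class counted ("increased", "decreased" or
#'   "abnormal_direction").
#' @param template template index or `NULL` for automatic selection.
#' @param ... passed to [register_nonrigid()].
#' @return an `aorta_incidence`: `template_index`, `template`,
#'   `proportion` (per-vertex, in [0, 1]), `n_patients`, `class`.
#' @export
build_incidence_map <- function(patient_heatmaps, patient_meshes,
                                class = "increased", template = NULL,
                                ...) {
  n <- length(patient_meshes)
  if (n < 1) stop("need at least 1 patient")
  ti <- if (is.null(template)) {
    if (n >= 2) select_template(patient_meshes) else 1L
  } else template
  tmpl <- patient_meshes[[ti]]
  nv <- nrow(tmpl$vertices)
  counts <- numeric(nv)
  used <- 0L
  for (i in seq_len(n)) {
    ind <- as.numeric(patient_heatmaps[[i]]$labels == class)
    if (i == ti) {
      ind_t <- ind
    } else {
      def <- register_nonrigid(patient_meshes[[i]], tmpl, ...)
      if (!def$converged) {
        warning("patient ", i, " failed registration; excluded")
        next
      }
      ind_t <- transfer_nearest(ind, def, tmpl)
    }
    counts <- counts + ind_t
    used <- used + 1L
  }
  structure(list(template_index = ti, template = tmpl,
                 proportion = counts / max(used, 1), n_patients = used,
                 class = class),
            class = "aorta_incidence")
}

#' @export
print.aorta_incidence <- function(x, ...) {
  cat(sprintf(
    "<aorta_incidence> class %s, %d patients, peak proportion %.2f\n",
    x$class, x$n_patients, max(x$proportion)))
  invisible(x)
}
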