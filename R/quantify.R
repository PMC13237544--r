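quant_rois <- c("pAAo", "dAAo", "pDAo", "dDAo")

#' Area-weighted regional means of a per-vertex map
#'
#' Means are taken over unflagged vertices only; an empty region yields
#' `NA` with a warning, never zero.
#'
#' @param values per-vertex numeric vector.
#' @param labeling per-vertex ROI factor from [label_rois()].
#' @param vertex_area per-vertex areas, mm^2.
#' @param flagged optional logical vector of vertices to exclude.
#' @return named numeric vector (pAAo, dAAo, pDAo, dDAo).
#' @export
roi_means <- function(values, labeling, vertex_area, flagged = NULL) {
  if (is.null(flagged)) flagged <- rep(FALSE, length(values))
  stopifnot(length(values) == length(labeling),
            length(values) == length(vertex_area))
  out <- setNames(rep(NA_real_, 4), quant_rois)
  for (r in quant_rois) {
    sel <- labeling == r & !flagged
    if (!any(sel)) {
      warning("ROI ", r, " has no usable vertices; mean is NA")
      next
    }
    out[r] <- sum(values[sel] * vertex_area[sel]) / sum(vertex_area[sel])
  }
  out
}

#' Abnormal surface-area percentages per region
#'
#' For each ROI and abnormality class, the percentage of the ROI surface
#' area carrying that label (area-weighted, not vertex-counted), plus a
#' flag for whether any abnormal vertex is present.
#'
#' @param heatmap an `aorta_heatmap`.
#' @param labeling per-vertex ROI factor.
#' @param vertex_area per-vertex areas, mm^2.
#' @param exclude_flagged drop heatmap-flagged vertices from the
#'   denominators.
#' @return data.frame with columns `roi`, `class`, `area_percent`,
#'   `any_abnormal_vertex`.
#' @export
abnormal_area_percent <- function(heatmap, labeling, vertex_area,
                                  exclude_flagged = TRUE) {
  classes <- setdiff(levels(heatmap$labels), "normal")
  use <- if (exclude_flagged) !heatmap$flagged else
    rep(TRUE, length(vertex_area))
  res <- expand.grid(roi = quant_rois, class = classes,
                     stringsAsFactors = FALSE)
  res$area_percent <- NA_real_
  res$any_abnormal_vertex <- NA
  for (i in seq_len(nrow(res))) {
    sel <- labeling == res$roi[i] & use
    if (!any(sel)) next
    denom <- sum(vertex_area[sel])
    num <- sum(vertex_area[sel & heatmap$labels == res$class[i]])
    res$area_percent[i] <- 100 * num / denom
    res$any_abnormal_vertex[i] <- num > 0
  }
  res
}

#' Diameter-adjusted regional parameters
#'
#' Adjusts regional values by the diameter at the matched measurement
#' station: displacement as displacement / diameter * 100 (mm * 100/mm),
#' velocity as velocity / diameter (cm/s per mm), WSS as
#' WSS * 1000 / diameter (mPa per mm). The station pairing is pAAo-root,
#' dAAo-ascending, pDAo-proximal descending, dDAo-diaphragm.
#'
#' @param regional named list with per-ROI `displacement` (mm),
#'   `velocity` (cm/s), `wss` (Pa) vectors (names pAAo, dAAo, pDAo,
#'   dDAo; any may be missing).
#' @param diameters named per-station diameters (mm): root, ascending,
#'   desc_proximal, diaphragm.
#' @return list of adjusted vectors (`displacement_adj`, `velocity_adj`,
#'   `wss_adj`); entries with zero or missing diameters are `NA`.
#' @export
diameter_adjust <- function(regional, diameters) {
  station_of <- c(pAAo = "root", dAAo = "ascending",
                  pDAo = "desc_proximal", dDAo = "diaphragm")
  dia <- diameters[station_of[quant_rois]]
  dia[!is.finite(dia) | dia <= 0] <- NA_real_
  dia <- setNames(as.numeric(dia), quant_rois)
  out <- list()
  if (!is.null(regional$displacement)) {
    out$displacement_adj <- regional$displacement[quant_rois] / dia * 100
  }
  if (!is.null(regional$velocity)) {
    out$velocity_adj <- regional$velocity[quant_rois] / dia
  }
  if (!is.null(regional$wss)) {
    out$wss_adj <- regional$wss[quant_rois] * 1000 / dia
  }
  out
}

#' Pre/post-registration agreement audit
#'
#' Paired comparison of per-subject regional means before registration
#' (on the native geometry) and after projection to the template: mean
#' difference (post minus pre), t-based 95% confidence interval and
#' two-sided p-value. Zero-variance differences are flagged and yield a
#' degenerate CI.
#'
#' @param pre_values,post_values paired numeric vectors (subjects x ROIs
#'   combined).
#' @return list with `mean_difference`, `ci` (length 2), `p`, `n`,
#'   `degenerate`.
#' @export
registration_audit <- function(pre_values, post_values) {
  stopifnot(length(pre_values) == length(post_values))
  ok <- is.finite(pre_values) & is.finite(post_values)
  d <- post_values[ok] - pre_values[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 paired values")
  md <- mean(d)
  if (var(d) <= (1e-10 * (abs(md) + 1))^2) {
    return(list(mean_difference = md, ci = c(md, md), p = NA_real_,
                n = n, degenerate = TRUE))
  }
  tt <- t.test(d)
  list(mean_difference = md, ci = unname(tt$conf.int),
       p = tt$p.value, n = n, degenerate = FALSE)
}
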