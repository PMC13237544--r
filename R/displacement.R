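#' Per-vertex wall displacement across the cardiac cycle
#'
#' Registers the end-diastolic surface to the surface of every other
#' cardiac phase (non-rigid, see [register_nonrigid()]) and records, per
#' end-diastolic vertex, the Euclidean distance to its mapped position.
#' The end-diastolic phase itself yields the zero map.
#'
#' @param phase_meshes list of `aorta_mesh`, one per cardiac phase
#'   (used as registration targets; keep these at full resolution).
#' @param ed_index index of the end-diastolic reference phase.
#' @param ed_mesh optional replacement for the end-diastolic source
#'   mesh, e.g. a decimated copy of `phase_meshes[[ed_index]]` — the
#'   displacement map is bound to this mesh.
#' @param ... passed to [register_nonrigid()].
#' @return list of displacement maps; each a list with `values`
#'   (per-vertex mm, bound to the ED mesh), `phase_index`, and `flagged`
#'   (TRUE when the registration did not converge).
#' @export
displacement_series <- function(phase_meshes, ed_index, ed_mesh = NULL,
                                ...) {
  n <- length(phase_meshes)
  if (n < 2) stop("need at least 2 phases")
  if (ed_index < 1 || ed_index > n) stop("invalid ed_index")
  ed <- if (is.null(ed_mesh)) phase_meshes[[ed_index]] else ed_mesh
  lapply(seq_len(n), function(t) {
    if (t == ed_index) {
      return(list(values = numeric(nrow(ed$vertices)), phase_index = t,
                  flagged = FALSE))
    }
    def <- register_nonrigid(ed, phase_meshes[[t]], ...)
    list(values = row_norms(def$mapped_vertices - ed$vertices),
         phase_index = t, flagged = !def$converged)
  })
}

#' Peak-displacement frame selection
#'
#' Returns the map whose unweighted vertex-mean displacement is largest;
#' ties break to the earliest phase.
#'
#' @param series output of [displacement_series()].
#' @param vertex_area optional per-vertex areas for an area-weighted
#'   mean (the default is the plain vertex mean).
#' @return list with `phase_index`, `map` (the chosen displacement map),
#'   and `mean_per_phase`.
#' @export
peak_displacement <- function(series, vertex_area = NULL) {
  if (length(series) == 0) stop("empty displacement series")
  means <- vapply(series, function(m) {
    if (is.null(vertex_area)) mean(m$values)
    else sum(m$values * vertex_area) / sum(vertex_area)
  }, numeric(1))
  i <- which.max(means)   # first maximum = earliest phase on ties
  list(phase_index = series[[i]]$phase_index, map = series[[i]],
       mean_per_phase = means)
}
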