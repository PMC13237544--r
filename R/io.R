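#' Write a mesh with per-vertex arrays as legacy VTK ASCII polydata
#'
#' @param mesh an `aorta_mesh`.
#' @param path output file.
#' @param point_data named list of per-vertex numeric vectors (scalars)
#'   or n x 3 matrices (vectors).
#' @return `path`, invisibly.
#' @export
write_vtk_polydata <- function(mesh, path, point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- mesh$vertices
  F <- mesh$faces
  writeLines(c("# vtk DataFile Version 3.0",
               "aortamap surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(V))), con)
  write(t(V), con, ncolumns = 3)
  writeLines(sprintf("POLYGONS %d %d", nrow(F), 4 * nrow(F)), con)
  write(t(cbind(3L, F - 1L)), con, ncolumns = 4)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(V)), con)
    for (nm in names(point_data)) {
      x <- point_data[[nm]]
      if (is.matrix(x)) {
        writeLines(sprintf("VECTORS %s float", nm), con)
        write(t(x), con, ncolumns = 3)
      } else {
        writeLines(c(sprintf("SCALARS %s float 1", nm),
                     "LOOKUP_TABLE default"), con)
        write(as.numeric(x), con, ncolumns = 9)
      }
    }
  }
  invisible(path)
}

#' Read legacy VTK ASCII polydata written by [write_vtk_polydata()]
#'
#' @param path VTK file path.
#' @return list with `mesh` (an `aorta_mesh`) and `point_data`.
#' @export
read_vtk_polydata <- function(path) {
  toks <- scan(path, what = "character", quiet = TRUE, skip = 4)
  cur <- 1L
  take <- function(n) {
    out <- toks[cur:(cur + n - 1L)]
    cur <<- cur + n
    out
  }
  expect_kw <- function(kw) {
    while (cur <= length(toks) && toks[cur] != kw) cur <<- cur + 1L
    if (cur > length(toks)) stop("VTK parse error: missing ", kw)
    cur <<- cur + 1L
  }
  expect_kw("POINTS")
  np <- as.integer(take(1))
  take(1)                               # data type
  V <- matrix(as.numeric(take(3L * np)), ncol = 3, byrow = TRUE)
  expect_kw("POLYGONS")
  nf <- as.integer(take(1))
  sz <- as.integer(take(1))
  F <- matrix(as.integer(take(sz)), ncol = 4, byrow = TRUE)[, 2:4,
                                                            drop = FALSE] + 1L
  pd <- list()
  if (any(toks == "POINT_DATA")) {
    expect_kw("POINT_DATA")
    take(1)
    while (cur <= length(toks)) {
      kw <- toks[cur]
      if (kw == "SCALARS") {
        cur <- cur + 1L
        nm <- take(1); take(2)          # type, ncomp
        take(2)                         # LOOKUP_TABLE default
        pd[[nm]] <- as.numeric(take(np))
      } else if (kw == "VECTORS") {
        cur <- cur + 1L
        nm <- take(1); take(1)          # type
        pd[[nm]] <- matrix(as.numeric(take(3L * np)), ncol = 3,
                           byrow = TRUE)
      } else break
    }
  }
  list(mesh = surface_mesh(V, F), point_data = pd)
}

#' Write a centerline as CSV (x, y, z, arclength, side)
#' @param cl an `aorta_centerline`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_centerline_csv <- function(cl, path) {
  df <- data.frame(x = cl$points[, 1], y = cl$points[, 2],
                   z = cl$points[, 3], arclength = cl$arclength,
                   side = if (is.null(cl$side)) NA else cl$side)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic subject to disk
#'
#' Phase masks as one 4D NIfTI, the lumen mask as 3D NIfTI, the velocity
#' field as three 4D NIfTI component files (cm/s), and landmarks plus
#' ground truth as JSON.
#'
#' @param subject an `aorta_subject`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- subject$spacing
  d <- dim(subject$lumen_mask)
  nph <- length(subject$phase_masks)
  arr4 <- array(0L, dim = c(d, nph))
  for (k in seq_len(nph)) arr4[, , , k] <- subject$phase_masks[[k]] * 1L
  RNifti::writeNifti(RNifti::asNifti(arr4, pixdim = c(sp, sp, sp, 1)),
                     file.path(dir, "phase_masks.nii.gz"))
  RNifti::writeNifti(
    RNifti::asNifti(subject$lumen_mask * 1L, pixdim = rep(sp, 3)),
    file.path(dir, "lumen_mask.nii.gz"))
  if (!is.null(subject$velocity)) {
    for (c3 in 1:3) {
      vc <- array(0, dim = c(d, nph))
      for (k in seq_len(nph)) vc[, , , k] <- subject$velocity[[k]][, , , c3]
      RNifti::writeNifti(RNifti::asNifti(vc, pixdim = c(sp, sp, sp, 1)),
                         file.path(dir, sprintf("velocity_%s.nii.gz",
                                                c("x", "y", "z")[c3])))
    }
  }
  meta <- list(spacing = sp, phase_times = subject$phase_times,
               group = subject$group,
               landmarks = as.list(subject$landmarks),
               ground_truth_table = subject$ground_truth$table,
               ed_phase = subject$ground_truth$ed_phase,
               viscosity = subject$ground_truth$viscosity)
  jsonlite::write_json(meta, file.path(dir, "subject.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_centerline_csv(subject$ground_truth$centerline,
                       file.path(dir, "centerline.csv"))
  invisible(dir)
}

#' Read a subject written by [write_subject()]
#' @param dir subject directory.
#' @return an `aorta_subject` (without the analytic ground-truth
#'   profiles; the regional table and centerline are restored).
#' @export
read_subject <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "subject.json"),
                              simplifyVector = TRUE)
  pm4 <- RNifti::readNifti(file.path(dir, "phase_masks.nii.gz"))
  nph <- dim(pm4)[4]
  phase_masks <- lapply(seq_len(nph), function(k) pm4[, , , k] != 0)
  lumen <- RNifti::readNifti(file.path(dir, "lumen_mask.nii.gz")) != 0
  velocity <- NULL
  vf <- file.path(dir, sprintf("velocity_%s.nii.gz", c("x", "y", "z")))
  if (all(file.exists(vf))) {
    comps <- lapply(vf, RNifti::readNifti)
    velocity <- lapply(seq_len(nph), function(k) {
      arr <- array(0, dim = c(dim(lumen), 3))
      for (c3 in 1:3) arr[, , , c3] <- comps[[c3]][, , , k]
      arr
    })
  }
  cldf <- read.csv(file.path(dir, "centerline.csv"))
  cl <- centerline(unname(as.matrix(cldf[, c("x", "y", "z")])),
                   unlist(meta$landmarks))
  structure(list(phase_masks = phase_masks,
                 phase_times = meta$phase_times,
                 lumen_mask = lumen, velocity = velocity,
                 spacing = meta$spacing,
                 landmarks = unlist(meta$landmarks),
                 ground_truth = list(table = meta$ground_truth_table,
                                     ed_phase = meta$ed_phase,
                                     viscosity = meta$viscosity,
                                     centerline = cl),
                 group = meta$group),
            class = "aorta_subject")
}
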