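# Plain-text interchange: VTK legacy ASCII unstructured grids for meshes,
# CSV sidecars for demographics, landmarks and Hounsfield fields.

#' Write a tetrahedral mesh as a VTK legacy ASCII unstructured grid
#'
#' @param mesh list with `nodes` (n x 3) and `tets` (m x 4, 1-based).
#' @param path output file.
#' @param title dataset title line.
#' @export
write_vtk_mesh <- function(mesh, path, title = "osteotrial mesh") {
  con <- file(path, "w"); on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(mesh$nodes, 1, function(p)
    sprintf("%.10g %.10g %.10g", p[1], p[2], p[3])), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(apply(mesh$tets - 1L, 1, function(t)
    paste(4, t[1], t[2], t[3], t[4])), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)   # VTK_TETRA
  invisible(path)
}

#' Read a VTK legacy ASCII unstructured grid of tetrahedra
#'
#' @param path file written by [write_vtk_mesh()] (or compatible).
#' @return list with `nodes` and `tets` (1-based).
#' @export
read_vtk_mesh <- function(path) {
  if (!file.exists(path)) stop("parse error: file not found: ", path)
  lines <- readLines(path)
  perr <- function(i, msg) stop(sprintf("parse error in %s line %d: %s",
                                        path, i, msg))
  ip <- grep("^POINTS", lines)
  if (!length(ip)) perr(1, "no POINTS section")
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE)
  if (length(pts) != 3 * n) perr(ip, "POINTS count mismatch")
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)
  if (!length(ic)) perr(1, "no CELLS section")
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cl <- scan(text = lines[(ic + 1):(ic + m)], quiet = TRUE)
  cl <- matrix(cl, ncol = 5, byrow = TRUE)
  if (any(cl[, 1] != 4)) perr(ic, "non-tetrahedral cell")
  list(nodes = nodes, tets = cl[, 2:5, drop = FALSE] + 1L)
}

#' Write a cohort to disk
#'
#' Emits `cohort.csv` plus, per patient, `<id>_mesh.vtk`,
#' `<id>_landmarks.csv` and `<id>_hu.csv` under `path`.
#'
#' @param cohort list with `patients` (data.frame) and `tibias`
#'   (list of `tibia_geometry`), as produced by [generate_cohort()].
#' @param path output directory (created if missing).
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$patients, file.path(path, "cohort.csv"),
            row.names = FALSE)
  for (tb in cohort$tibias) {
    id <- tb$patient_id
    write_vtk_mesh(tb, file.path(path, paste0(id, "_mesh.vtk")), id)
    lm <- data.frame(name = rownames(tb$landmarks),
                     x = tb$landmarks[, 1], y = tb$landmarks[, 2],
                     z = tb$landmarks[, 3])
    write.csv(lm, file.path(path, paste0(id, "_landmarks.csv")),
              row.names = FALSE)
    write.csv(data.frame(element_id = seq_along(tb$hu), HU = tb$hu),
              file.path(path, paste0(id, "_hu.csv")), row.names = FALSE)
  }
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path cohort directory.
#' @return list with `patients` and `tibias` (meshes, HU, landmarks;
#'   derived fields such as the section function are not round-tripped).
#' @export
read_cohort <- function(path) {
  cf <- file.path(path, "cohort.csv")
  if (!file.exists(cf)) stop("parse error: missing ", cf)
  patients <- read.csv(cf, stringsAsFactors = FALSE,
                       colClasses = c(sex = "character",
                                      side = "character"))
  if (nrow(patients) == 0) {
    warning("cohort.csv has a header but no rows: returning empty cohort")
    return(list(patients = patients, tibias = list()))
  }
  tibias <- lapply(patients$id, function(id) {
    mf <- file.path(path, paste0(id, "_mesh.vtk"))
    hf <- file.path(path, paste0(id, "_hu.csv"))
    lf <- file.path(path, paste0(id, "_landmarks.csv"))
    mesh <- read_vtk_mesh(mf)
    if (!file.exists(hf))
      stop("parse error: missing HU sidecar for patient ", id, ": ", hf)
    hu <- read.csv(hf)
    if (!all(c("element_id", "HU") %in% names(hu)))
      stop("parse error in ", hf, " line 1: need element_id,HU columns")
    if (!file.exists(lf))
      stop("parse error: missing landmark sidecar for patient ", id)
    lm <- read.csv(lf)
    lms <- landmark_set(
      hip_center = unlist(lm[lm$name == "hip_center", c("x", "y", "z")]),
      knee_center = unlist(lm[lm$name == "knee_center", c("x", "y", "z")]),
      plateau_medial = unlist(lm[lm$name == "plateau_medial",
                                 c("x", "y", "z")]),
      plateau_lateral = unlist(lm[lm$name == "plateau_lateral",
                                  c("x", "y", "z")]),
      ankle_center = unlist(lm[lm$name == "ankle_center", c("x", "y", "z")]))
    structure(list(nodes = mesh$nodes, tets = mesh$tets,
                   hu = hu$HU[order(hu$element_id)], landmarks = lms,
                   joint_line_z = lms["knee_center", 3],
                   patient_id = id),
              class = "tibia_geometry")
  })
  list(patients = patients, tibias = tibias)
}

#' Generate a full cohort (demographics + geometries)
#'
#' @param spec a [cohort_spec()].
#' @return list with `patients` data.frame and `tibias` list.
#' @export
generate_cohort <- function(spec) {
  patients <- sample_demographics(spec)
  tibias <- lapply(seq_len(nrow(patients)),
                   function(i) build_tibia(patients[i, ], spec))
  list(patients = patients, tibias = tibias, spec = spec)
}
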