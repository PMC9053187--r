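# Structured tetrahedral meshing for the parametric proximal tibia and for
# the rectangular verification blocks used by the solver checks.
#
# Every hexahedral cell of a structured (i, j, k) grid is split into six
# tetrahedra sharing the 0-6 diagonal; this split is translation-invariant,
# so shared faces between neighbouring hexes carry matching diagonals and
# the mesh is conforming and watertight by construction.

hex_to_tets <- function(h) {
  # h: integer vector of the 8 hex corner node ids (VTK corner order)
  rbind(c(h[1], h[2], h[3], h[7]),
        c(h[1], h[3], h[4], h[7]),
        c(h[1], h[4], h[8], h[7]),
        c(h[1], h[8], h[5], h[7]),
        c(h[1], h[5], h[6], h[7]),
        c(h[1], h[6], h[2], h[7]))
}

structured_tet_mesh <- function(nu, nv, nz, map) {
  # map(u, v, w) with u, v in [-1, 1], w in [0, 1] -> n x 3 coordinates
  us <- seq(-1, 1, length.out = nu + 1)
  vs <- seq(-1, 1, length.out = nv + 1)
  ws <- seq(0, 1, length.out = nz + 1)
  g <- expand.grid(u = us, v = vs, w = ws, KEEP.OUT.ATTRS = FALSE)
  nodes <- map(g$u, g$v, g$w)
  nid <- function(i, j, k) i + (nu + 1) * (j - 1) + (nu + 1) * (nv + 1) * (k - 1)
  cells <- expand.grid(i = seq_len(nu), j = seq_len(nv), k = seq_len(nz))
  tets <- do.call(rbind, lapply(seq_len(nrow(cells)), function(r) {
    i <- cells$i[r]; j <- cells$j[r]; k <- cells$k[r]
    h <- c(nid(i, j, k),     nid(i + 1, j, k),
           nid(i + 1, j + 1, k), nid(i, j + 1, k),
           nid(i, j, k + 1), nid(i + 1, j, k + 1),
           nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
    hex_to_tets(h)
  }))
  m <- list(nodes = as.matrix(nodes), tets = tets)
  orient_tets(m)
}

#' Signed tetrahedron volumes
#'
#' @param nodes n x 3 node coordinates (mm).
#' @param tets m x 4 node indices.
#' @return numeric vector of signed volumes (mm^3).
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
     b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
     b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

orient_tets <- function(mesh) {
  v <- tet_volumes(mesh$nodes, mesh$tets)
  flip <- which(v < 0)
  if (length(flip)) {
    tmp <- mesh$tets[flip, 3]
    mesh$tets[flip, 3] <- mesh$tets[flip, 4]
    mesh$tets[flip, 4] <- tmp
  }
  mesh
}

tet_faces_key <- function(tets) {
  # the four faces of each tet, as sorted node triples
  f <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
             tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  f <- t(apply(f, 1, sort))
  list(faces = f, key = paste(f[, 1], f[, 2], f[, 3]))
}

#' Mesh validity checks
#'
#' A mesh is accepted when every tetrahedron has positive volume and the
#' triangular face complex is watertight: each face is shared by exactly
#' one or two tetrahedra and every boundary edge borders exactly two
#' boundary faces (closed 2-manifold surface).
#'
#' @param mesh list with `nodes` and `tets`.
#' @return list with logical `watertight`, `positive_volumes`,
#'   the boundary face matrix, and the minimum volume.
#' @export
check_mesh <- function(mesh) {
  v <- tet_volumes(mesh$nodes, mesh$tets)
  fk <- tet_faces_key(mesh$tets)
  cnt <- table(fk$key)
  ok_faces <- all(cnt <= 2)
  boundary <- fk$faces[fk$key %in% names(cnt)[cnt == 1], , drop = FALSE]
  e <- rbind(boundary[, 1:2], boundary[, 2:3], boundary[, c(1, 3)])
  e <- t(apply(e, 1, sort))
  ecnt <- table(paste(e[, 1], e[, 2]))
  closed <- all(ecnt == 2)
  list(watertight = ok_faces && closed,
       positive_volumes = all(v > 0),
       boundary_faces = boundary,
       min_volume = min(v))
}

# Squircle map: bijection [-1,1]^2 -> ellipse with semi-axes a (x) and b (y)
squircle <- function(u, v, a, b) {
  cbind(a * u * sqrt(pmax(0, 1 - v^2 / 2)),
        b * v * sqrt(pmax(0, 1 - u^2 / 2)))
}

#' Build a parametric proximal tibia for one virtual patient
#'
#' The meshed segment is a tapered elliptical column of length
#' `segment_length_frac * height` ending at the joint line (z = L, +z
#' proximal, +x medial-to-lateral, units mm).  The plateau ML width is a
#' configured fraction of patient height with multiplicative noise; the
#' shaft narrows to `shaft_ratio` of the plateau with a cubic metaphyseal
#' flare.  Per-element Hounsfield units are drawn compartment-wise:
#' cortical shell ~ N(1400, 100^2), trabecular core ~ N(300, 80^2) by
#' default.  Hip and ankle centers are synthesized on the limb axis; a
#' truncated-normal varus offset displaces the ankle center medially so
#' the mechanical axis crosses the plateau below its midpoint.
#'
#' @param patient one row of [sample_demographics()].
#' @param spec the [cohort_spec()] that produced it.
#' @return object of class `tibia_geometry`: nodes, tets, hu, landmarks,
#'   joint_line_z, section function, and provenance fields.
#' @export
build_tibia <- function(patient, spec) {
  g <- spec$geometry
  height_mm <- patient$height_cm * 10
  idx <- as.integer(sub("P", "", patient$id))
  with_seed(derive_seed(spec$seed, idx, salt = 23L), {
    width <- g$plateau_width_frac * height_mm *
      (1 + rnorm(1, 0, g$plateau_width_noise_sd))
    varus <- rtruncnorm(1, g$varus_offset_mean, g$varus_offset_sd,
                        g$varus_offset_min, Inf)
    L <- g$segment_length_frac * height_mm
    a_top <- width / 2
    b_top <- g$ap_ratio * a_top
    if (!is.finite(L) || L <= 0 || a_top <= 0)
      stop("geometry error: degenerate scale parameters")
    # ML/AP semi-axes along the segment; w = 0 distal, w = 1 joint line
    sect <- function(w) {
      s <- g$shaft_ratio + (1 - g$shaft_ratio) * w^3
      list(a = a_top * s, b = b_top * s)
    }
    map <- function(u, v, w) {
      s <- sect(w)
      xy <- squircle(u, v, s$a, s$b)
      cbind(xy, w * L)
    }
    mesh <- structured_tet_mesh(g$nu, g$nv, g$nz, map)
    # compartment classification by normalised elliptical radius at the
    # element centroid
    cent <- tet_centroids(mesh$nodes, mesh$tets)
    s <- sect(pmin(1, pmax(0, cent[, 3] / L)))
    rn <- sqrt((cent[, 1] / s$a)^2 + (cent[, 2] / s$b)^2)
    cortical <- rn >= g$cortical_radius_frac
    hu <- numeric(nrow(mesh$tets))
    hu[cortical] <- rnorm(sum(cortical), g$hu_cortical_mean, g$hu_cortical_sd)
    hu[!cortical] <- rnorm(sum(!cortical), g$hu_trabecular_mean,
                           g$hu_trabecular_sd)
    tibia_len <- g$tibia_length_frac * height_mm
    femur_len <- g$femur_length_frac * height_mm
    landmarks <- landmark_set(
      hip_center = c(0, 0, L + femur_len),
      knee_center = c(0, 0, L),
      plateau_medial = c(-a_top, 0, L),
      plateau_lateral = c(a_top, 0, L),
      ankle_center = c(-varus, 0, L - tibia_len))
    structure(list(nodes = mesh$nodes, tets = mesh$tets, hu = hu,
                   landmarks = landmarks, joint_line_z = L,
                   section = sect, plateau_width = width,
                   varus_offset = varus, cortical = cortical,
                   patient_id = patient$id),
              class = "tibia_geometry")
  })
}

#' Five-landmark set for lower-limb alignment
#'
#' @param hip_center,knee_center,plateau_medial,plateau_lateral,ankle_center
#'   3-D points (mm, global frame, +z proximal).
#' @return object of class `landmark_set` (5 x 3 matrix with row names).
#' @export
landmark_set <- function(hip_center, knee_center, plateau_medial,
                         plateau_lateral, ankle_center) {
  m <- rbind(hip_center = as.numeric(hip_center),
             knee_center = as.numeric(knee_center),
             plateau_medial = as.numeric(plateau_medial),
             plateau_lateral = as.numeric(plateau_lateral),
             ankle_center = as.numeric(ankle_center))
  colnames(m) <- NULL
  if (sum((m["plateau_medial", ] - m["plateau_lateral", ])^2) < 1e-12)
    stop("geometry error: plateau landmarks coincide")
  if (m["hip_center", 3] <= m["ankle_center", 3])
    stop("geometry error: hip center must be proximal to ankle center")
  structure(m, class = "landmark_set")
}

# barycentric point-in-tetrahedron membership (any tet of the subset)
points_in_tets <- function(pts, nodes, tets) {
  out <- rep(FALSE, nrow(pts))
  for (r in seq_len(nrow(tets))) {
    a <- nodes[tets[r, 1], ]
    M <- cbind(nodes[tets[r, 2], ] - a, nodes[tets[r, 3], ] - a,
               nodes[tets[r, 4], ] - a)
    Minv <- tryCatch(solve(M), error = function(e) NULL)
    if (is.null(Minv)) next
    todo <- which(!out)
    if (!length(todo)) break
    lam <- Minv %*% (t(pts[todo, , drop = FALSE]) - a)
    inside <- colSums(lam < -1e-9) == 0 & colSums(lam) <= 1 + 1e-9
    out[todo[inside]] <- TRUE
  }
  out
}

tet_centroids <- function(nodes, tets) {
  (nodes[tets[, 1], , drop = FALSE] + nodes[tets[, 2], , drop = FALSE] +
     nodes[tets[, 3], , drop = FALSE] + nodes[tets[, 4], , drop = FALSE]) / 4
}

#' Rectangular block mesh for solver verification
#'
#' @param lx,ly,lz block dimensions (mm).
#' @param nx,ny,nz cells per direction.
#' @return list with nodes and tets.
#' @export
box_mesh <- function(lx, ly, lz, nx, ny, nz) {
  map <- function(u, v, w) cbind((u + 1) / 2 * lx, (v + 1) / 2 * ly, w * lz)
  structured_tet_mesh(nx, ny, nz, map)
}
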