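# Opening-wedge osteotomy planning in the frontal (x-z) plane.
# Alignment is quantified by where the mechanical axis (hip center ->
# ankle center) crosses the tibial plateau chord between its medial and
# lateral edges; the correction rotates the distal fragment about a
# lateral cortical hinge until that crossing sits at the target fraction
# (0.625 by default, the Fujisawa-type rule).

#' Mechanical-axis plateau crossing fraction
#'
#' Projects the hip-to-ankle line onto the frontal plane and intersects it
#' with the plateau level; returns the fractional position of the crossing
#' between the medial (0) and lateral (1) plateau edges.
#'
#' @param landmarks a [landmark_set()].
#' @return unitless fraction (may fall outside `[0, 1]` for severe
#'   malalignment).
#' @export
mechanical_axis_fraction <- function(landmarks) {
  lm <- unclass(landmarks)
  hip <- lm["hip_center", ]; ank <- lm["ankle_center", ]
  med <- lm["plateau_medial", ]; lat <- lm["plateau_lateral", ]
  zp <- (med[3] + lat[3]) / 2
  dz <- hip[3] - ank[3]
  if (abs(dz) < 1e-9)
    stop("geometry error: mechanical axis parallel to the plateau level")
  width <- lat[1] - med[1]
  if (abs(width) < 1e-9)
    stop("geometry error: zero-length plateau segment in the frontal plane")
  t <- (zp - ank[3]) / dz
  x_cross <- ank[1] + t * (hip[1] - ank[1])
  as.numeric((x_cross - med[1]) / width)
}

#' Plan the opening-wedge correction angle
#'
#' Finds the rotation angle theta (degrees, positive = medial opening
#' wedge / varus correction) about the anterior-posterior hinge axis such
#' that, after rotating the distal fragment (and with it the ankle
#' center), the mechanical axis crosses the plateau at `target_fraction`.
#' Solved by bisection on theta in [-30, 30] degrees to 0.001 degrees,
#' well inside the 0.01-degree planning tolerance.
#'
#' @param landmarks a [landmark_set()].
#' @param target_fraction plateau crossing target, default 0.625.
#' @param hinge hinge point (mm); default lateral plateau edge dropped
#'   `hinge_depth` below the joint line.
#' @param hinge_depth hinge depth below the joint line (mm, >= 10).
#' @return correction angle in degrees.
#' @export
correction_angle <- function(landmarks, target_fraction = 0.625,
                             hinge = NULL, hinge_depth = 10) {
  if (hinge_depth < 10)
    stop("planning error: hinge must be at least 10 mm below the joint line")
  lm <- unclass(landmarks)
  if (is.null(hinge))
    hinge <- lm["plateau_lateral", ] - c(0, 0, hinge_depth)
  f <- function(theta) {
    ank <- rotate_points(matrix(lm["ankle_center", ], 1, 3),
                         hinge, c(0, 1, 0), -theta)
    lm2 <- lm; lm2["ankle_center", ] <- ank
    mechanical_axis_fraction(structure(lm2, class = "landmark_set")) -
      target_fraction
  }
  lo <- -30; hi <- 30
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop("planning error: no correction in [-30, 30] degrees reaches the ",
         "target fraction; patient flagged for exclusion")
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (flo * f(mid) <= 0) hi <- mid else { lo <- mid; flo <- f(lo) }
  }
  (lo + hi) / 2
}

#' Assemble a correction plan for one tibia
#'
#' @param tibia a `tibia_geometry`.
#' @param target_fraction plateau target, default 0.625.
#' @param wedge_plane_tilt cut-plane tilt to the plateau (degrees,
#'   default 15).
#' @param hinge_depth hinge depth below the joint line (mm, default 10).
#' @return object of class `correction_plan`.
#' @export
plan_correction <- function(tibia, target_fraction = 0.625,
                            wedge_plane_tilt = 15, hinge_depth = 10) {
  stopifnot(target_fraction >= 0, target_fraction <= 1)
  lm <- unclass(tibia$landmarks)
  hinge <- lm["plateau_lateral", ] - c(0, 0, hinge_depth)
  theta <- correction_angle(tibia$landmarks, target_fraction, hinge,
                            hinge_depth)
  structure(list(correction_angle = theta,
                 target_fraction = target_fraction,
                 hinge_point = hinge, hinge_axis = c(0, 1, 0),
                 wedge_plane_tilt = wedge_plane_tilt,
                 hinge_depth = hinge_depth,
                 valgus_flagged = theta < 0),
            class = "correction_plan")
}

cut_plane <- function(plan) {
  # plane through the hinge, dipping medially at the configured tilt:
  # g(p) = (z - hz) - tan(tilt) * (x - hx); g > 0 proximal
  tilt <- plan$wedge_plane_tilt * pi / 180
  h <- plan$hinge_point
  function(pts) (pts[, 3] - h[3]) - tan(tilt) * (pts[, 1] - h[1])
}

#' Perform the virtual opening-wedge osteotomy
#'
#' Nodes below the tilted cut plane form the distal fragment and are
#' rigidly rotated by the correction angle about the hinge axis; nodes
#' above remain fixed.  Tetrahedra with nodes on both sides become the
#' gap layer, which deforms to fill the opened wedge (the mesh stays
#' conforming, so no remeshing is needed); gap elements within
#' `hinge_radius` of the hinge point are labelled `cortical_hinge` and
#' retain bone material.  When the correction angle is (numerically)
#' zero the geometry is returned unchanged with an empty gap set.
#'
#' @param tibia a `tibia_geometry`.
#' @param plan a `correction_plan`.
#' @param hinge_radius radius of the intact lateral hinge (mm).
#' @return object of class `osteotomized_tibia`: nodes (post-rotation),
#'   reference nodes, tets, element labels, HU, plan, updated landmarks.
#' @export
build_osteotomy <- function(tibia, plan, hinge_radius = 10) {
  g <- cut_plane(plan)(tibia$nodes)
  if (all(g > 0) || all(g < 0))
    stop("geometry error: cut plane misses the meshed segment")
  distal_node <- g < 0
  theta <- plan$correction_angle
  labels <- rep("proximal", nrow(tibia$tets))
  nd <- matrix(distal_node[tibia$tets], ncol = 4)
  ns <- rowSums(nd)
  labels[ns == 4] <- "distal"
  if (abs(theta) > 1e-9) labels[ns > 0 & ns < 4] <- "gap"
  else labels[ns > 0 & ns < 4] <- "proximal"
  cent <- tet_centroids(tibia$nodes, tibia$tets)
  near_hinge <- sqrt(rowSums(sweep(cent, 2, plan$hinge_point)^2)) <=
    hinge_radius
  labels[labels == "gap" & near_hinge] <- "cortical_hinge"
  nodes <- tibia$nodes
  if (abs(theta) > 1e-9)
    nodes[distal_node, ] <- rotate_points(tibia$nodes[distal_node, ,
                                                      drop = FALSE],
                                          plan$hinge_point,
                                          plan$hinge_axis, -theta)
  v <- tet_volumes(nodes, tibia$tets)
  if (any(v <= 0))
    stop("geometry error: osteotomy rotation inverted ",
         sum(v <= 0), " elements")
  lm <- unclass(tibia$landmarks)
  lm["ankle_center", ] <- rotate_points(matrix(lm["ankle_center", ], 1, 3),
                                        plan$hinge_point, plan$hinge_axis,
                                        -theta)
  structure(list(nodes = nodes, ref_nodes = tibia$nodes,
                 tets = tibia$tets, labels = labels, hu = tibia$hu,
                 distal_node = distal_node, plan = plan,
                 landmarks = structure(lm, class = "landmark_set"),
                 joint_line_z = tibia$joint_line_z,
                 section = tibia$section,
                 patient_id = tibia$patient_id),
            class = "osteotomized_tibia")
}

#' Measured wedge dihedral angle of an osteotomy
#'
#' Fits a plane (total least squares) to the distal-side nodes of the gap
#' layer in the reference and the rotated configuration and returns the
#' angle between the fitted normals.  For a rigid rotation this equals
#' the correction angle.
#'
#' @param ost an `osteotomized_tibia`.
#' @return dihedral angle in degrees (0 when there is no gap).
#' @export
gap_dihedral_angle <- function(ost) {
  gap <- ost$labels %in% c("gap", "cortical_hinge")
  if (!any(gap)) return(0)
  nid <- unique(as.vector(ost$tets[gap, ]))
  nid <- nid[ost$distal_node[nid]]
  if (length(nid) < 3) return(0)
  fitn <- function(pts) {
    c_ <- sweep(pts, 2, colMeans(pts))
    svd(c_)$v[, 3]
  }
  n1 <- fitn(ost$ref_nodes[nid, , drop = FALSE])
  n2 <- fitn(ost$nodes[nid, , drop = FALSE])
  acos(min(1, abs(sum(n1 * n2)))) * 180 / pi
}
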