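# Parametric plate + screw constructs on the osteotomized tibia.
#
# The Generic arm is a flat, fixed-dimension T-style locking plate with
# patient-invariant shape and screw layout (a parametric stand-in for a
# standard commercial HTO plate); only its rigid placement adapts to the
# patient, so its standoff from the curved medial cortex varies with
# anatomy.  The Personalised arm conforms its inner surface to the
# post-osteotomy bone surface (standoff <= 0.5 mm), sizes itself with
# patient mass, adapts screw lengths to a bicortical-purchase rule and
# tilts screw axes away from the osteotomy plane.

#' Default plate and screw configuration
#'
#' Lengths in mm.  `zeta_cut` is the distance from the distal plate end
#' at which the osteotomy crosses the plate; screw positions are given in
#' the same plate-local axial coordinate.
#'
#' @param generic_length,generic_width,generic_thickness generic plate
#'   dimensions (default 115 x 16 x 3).
#' @param personalised_length personalised plate length.
#' @param screw_diameter screw diameter (mm).
#' @param generic_screw_length_prox,generic_screw_length_dist fixed
#'   generic screw lengths.
#' @param plate_E,plate_nu titanium alloy elastic constants (MPa, -).
#' @param clearance_personalised inner-surface clearance of the
#'   conforming plate (mm).
#' @param screw_plane_clearance minimum distance between a personalised
#'   screw axis and the osteotomy plane (mm).
#' @param ref_mass_kg,size_exponent personalised sizing law: width and
#'   thickness scale with `(mass / ref_mass_kg)^size_exponent`.
#' @param n_length,n_width,n_thickness plate mesh resolution.
#' @return named list.
#' @export
default_plate_params <- function(generic_length = 115, generic_width = 16,
                                 generic_thickness = 3,
                                 personalised_length = 95,
                                 screw_diameter = 5,
                                 generic_screw_length_prox = 60,
                                 generic_screw_length_dist = 34,
                                 plate_E = 110e3, plate_nu = 0.3,
                                 clearance_personalised = 0.1,
                                 screw_plane_clearance = 2,
                                 ref_mass_kg = 90.1, size_exponent = 1 / 3,
                                 n_length = 20, n_width = 3,
                                 n_thickness = 2) {
  as.list(environment())
}

# inverse-distance interpolant x = f(y, z) of the medial bone surface,
# built from boundary nodes of the (post-osteotomy) mesh with x < 0
medial_surface_interp <- function(ost, k = 8) {
  bf <- check_mesh(list(nodes = ost$nodes, tets = ost$tets))$boundary_faces
  nid <- unique(as.vector(bf))
  pts <- ost$nodes[nid, , drop = FALSE]
  pts <- pts[pts[, 1] < 0, , drop = FALSE]
  function(y, z) {
    vapply(seq_along(y), function(i) {
      d2 <- (pts[, 2] - y[i])^2 + (pts[, 3] - z[i])^2
      o <- order(d2)[seq_len(min(k, nrow(pts)))]
      w <- 1 / (d2[o] + 1e-6)
      sum(w * pts[o, 1]) / sum(w)
    }, numeric(1))
  }
}

cut_z_at_medial_surface <- function(ost) {
  tilt <- ost$plan$wedge_plane_tilt * pi / 180
  h <- ost$plan$hinge_point
  x_med <- min(ost$nodes[, 1])
  h[3] - tan(tilt) * (h[1] - x_med)
}

plate_axial_frame <- function(ost, length, top_margin = 3) {
  # map plate-local zeta in [0, length] (distal -> proximal) to global z;
  # the plate head is anchored just below the joint line
  z_cut <- cut_z_at_medial_surface(ost)
  zmin <- min(ost$nodes[, 3]); zmax <- max(ost$nodes[, 3])
  z_top <- zmax - top_margin
  z_bot <- z_top - length
  if (z_bot < zmin - 1e-9)
    stop("placement error: plate footprint exceeds meshed bone extent (",
         sprintf("plate z %.1f..%.1f, bone z %.1f..%.1f", z_bot, z_top,
                 zmin, zmax), ")")
  list(z_of_zeta = function(zeta) z_bot + zeta, z_bot = z_bot,
       z_top = z_top, z_cut = z_cut)
}

generic_screw_layout <- function(length) {
  data.frame(
    label = c(paste0("proximal_", 1:4), paste0("distal_", 1:4)),
    side = rep(c("proximal", "distal"), each = 4),
    zeta = c(length - c(5, 11, 17, 23), c(6, 20, 34, 48)),
    stringsAsFactors = FALSE)
}

new_plate_model <- function(arm, mesh, centerline, dims, standoff, screws,
                            params, frame) {
  structure(list(arm = arm, nodes = mesh$nodes, tets = mesh$tets,
                 centerline = centerline, dims = dims,
                 standoff = standoff, screws = screws,
                 active = rep(TRUE, nrow(screws)),
                 config = "SC1", E = params$plate_E, nu = params$plate_nu,
                 params = params, frame = frame),
            class = "plate_model")
}

plate_mesh_from_inner <- function(inner_x, ys, zetas, z_of_zeta, thickness,
                                  n_thickness) {
  # inner_x: matrix [length(zetas) x length(ys)] of inner-face x values
  nL <- length(zetas) - 1; nW <- length(ys) - 1
  map <- function(u, v, w) {
    zi <- (u + 1) / 2 * nL + 1
    yi <- (v + 1) / 2 * nW + 1
    xin <- inner_x[cbind(round(zi), round(yi))]
    cbind(xin - w * thickness, ys[round(yi)], z_of_zeta(zetas[round(zi)]))
  }
  structured_tet_mesh(nL, nW, n_thickness, map)
}

#' Build the generic (patient-invariant) plate
#'
#' @param ost an `osteotomized_tibia`.
#' @param params a [default_plate_params()] list.
#' @return a `plate_model`.
#' @export
build_generic_plate <- function(ost, params = default_plate_params()) {
  len <- params$generic_length
  fr <- plate_axial_frame(ost, len)
  surf <- medial_surface_interp(ost)
  zetas <- seq(0, len, length.out = params$n_length + 1)
  ys <- seq(-params$generic_width / 2, params$generic_width / 2,
            length.out = params$n_width + 1)
  gz <- fr$z_of_zeta(rep(zetas, times = length(ys)))
  gy <- rep(ys, each = length(zetas))
  sx <- matrix(surf(gy, gz), length(zetas), length(ys))
  x_plane <- min(sx)            # flat plate touches the most medial point
  standoff <- as.vector(sx - x_plane)
  inner <- matrix(x_plane, length(zetas), length(ys))
  mesh <- plate_mesh_from_inner(inner, ys, zetas, fr$z_of_zeta,
                                params$generic_thickness, params$n_thickness)
  lay <- generic_screw_layout(len)
  screws <- data.frame(lay,
                       x = x_plane, y = 0, z = fr$z_of_zeta(lay$zeta),
                       ax = 1, ay = 0, az = 0,
                       length = ifelse(lay$side == "proximal",
                                       params$generic_screw_length_prox,
                                       params$generic_screw_length_dist),
                       diameter = params$screw_diameter,
                       stringsAsFactors = FALSE)
  screws$dist_to_gap <- screw_gap_distances(screws, ost)
  centerline <- cbind(x = inner[, (length(ys) + 1) %/% 2], y = 0,
                      z = fr$z_of_zeta(zetas))
  new_plate_model("Generic", mesh, centerline,
                  c(length = len, width = params$generic_width,
                    thickness = params$generic_thickness),
                  standoff, screws, params, fr)
}

#' Build the personalised (surface-conforming) plate
#'
#' @param ost an `osteotomized_tibia`.
#' @param mass_kg patient body mass, drives the sizing law.
#' @param params a [default_plate_params()] list.
#' @return a `plate_model`.
#' @export
build_personalised_plate <- function(ost, mass_kg = 90.1,
                                     params = default_plate_params()) {
  stopifnot(mass_kg > 0)
  scale <- (mass_kg / params$ref_mass_kg)^params$size_exponent
  len <- params$personalised_length
  width <- params$generic_width * scale
  thick <- params$generic_thickness * scale
  fr <- plate_axial_frame(ost, len)
  surf <- medial_surface_interp(ost)
  zetas <- seq(0, len, length.out = params$n_length + 1)
  ys <- seq(-width / 2, width / 2, length.out = params$n_width + 1)
  gz <- fr$z_of_zeta(rep(zetas, times = length(ys)))
  gy <- rep(ys, each = length(zetas))
  sx <- matrix(surf(gy, gz), length(zetas), length(ys))
  inner <- sx - params$clearance_personalised
  standoff <- rep(params$clearance_personalised,
                  length(zetas) * length(ys))
  mesh <- plate_mesh_from_inner(inner, ys, zetas, fr$z_of_zeta, thick,
                                params$n_thickness)
  lay <- generic_screw_layout(len)
  entry_x <- surf(rep(0, nrow(lay)), fr$z_of_zeta(lay$zeta))
  screws <- data.frame(lay, x = entry_x, y = 0,
                       z = fr$z_of_zeta(lay$zeta),
                       ax = 1, ay = 0, az = 0,
                       length = 30, diameter = params$screw_diameter,
                       stringsAsFactors = FALSE)
  screws <- personalise_screws(screws, ost, params, surf, fr$z_bot,
                               fr$z_top)
  screws$dist_to_gap <- screw_gap_distances(screws, ost)
  centerline <- cbind(x = inner[, (length(ys) + 1) %/% 2], y = 0,
                      z = fr$z_of_zeta(zetas))
  new_plate_model("Personalised", mesh, centerline,
                  c(length = len, width = width, thickness = thick),
                  standoff, screws, params, fr)
}

# adapt screw axes and entries so every screw clears the osteotomy:
# tilt in the frontal plane away from the cut (up to 45 degrees), then
# shift the entry along the plate away from the cut if tilting alone is
# not enough; lengths follow the bicortical-purchase rule (entry to
# far-cortex exit).  Clearance is checked both against the cut plane
# (>= configured clearance) and against the meshed gap layer itself.
personalise_screws <- function(screws, ost, params, surf, z_bot, z_top) {
  g <- cut_plane(ost$plan)
  grad_norm <- sqrt(1 + tan(ost$plan$wedge_plane_tilt * pi / 180)^2)
  hx <- ost$plan$hinge_point[1]
  gap_tets <- ost$tets[ost$labels == "gap", , drop = FALSE]
  for (i in seq_len(nrow(screws))) {
    sgn <- if (screws$side[i] == "proximal") 1 else -1
    placed <- FALSE
    for (shift in seq(0, 20, by = 5)) {
      z0 <- screws$z[i] + sgn * shift
      if (z0 > z_top - 2 || z0 < z_bot + 2) break
      entry <- c(surf(0, z0), 0, z0)
      for (tilt in seq(0, 45, by = 5)) {
        ax <- c(cos(tilt * pi / 180), 0, sgn * sin(tilt * pi / 180))
        ln <- bicortical_length(entry, ax, ost)
        s <- seq(0.05, 1, length.out = 40) * ln
        pts <- matrix(entry, length(s), 3, byrow = TRUE) + outer(s, ax)
        inplane <- pts[, 1] < hx
        dmin <- if (any(inplane))
          min(abs(g(pts[inplane, , drop = FALSE])) / grad_norm) else Inf
        hits_gap <- nrow(gap_tets) > 0 &&
          any(points_in_tets(pts, ost$nodes, gap_tets))
        if (dmin >= params$screw_plane_clearance && !hits_gap) {
          screws$x[i] <- entry[1]; screws$z[i] <- z0
          screws$ax[i] <- ax[1]; screws$ay[i] <- 0; screws$az[i] <- ax[3]
          screws$length[i] <- ln
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed)
      stop("placement error: screw ", screws$label[i],
           " cannot clear the osteotomy gap")
  }
  screws
}

# march along the axis until the far cortex is crossed (section test)
bicortical_length <- function(entry, axis, ost, max_len = 90) {
  sct <- ost$section
  L <- ost$joint_line_z
  s <- seq(1, max_len, by = 0.5)
  pts <- matrix(entry, length(s), 3, byrow = TRUE) + outer(s, axis)
  w <- pmin(1, pmax(0, pts[, 3] / L))
  sec <- sct(w)
  inside <- (pts[, 1] / sec$a)^2 + (pts[, 2] / sec$b)^2 <= 1 &
    pts[, 3] >= 0 & pts[, 3] <= L
  out <- which(!inside & s > 5)
  if (length(out)) s[out[1]] else max_len
}

screw_gap_distances <- function(screws, ost) {
  gap <- ost$labels == "gap"
  if (!any(gap)) return(rep(NA_real_, nrow(screws)))
  gc <- tet_centroids(ost$nodes, ost$tets)[gap, , drop = FALSE]
  vapply(seq_len(nrow(screws)), function(i) {
    entry <- as.numeric(screws[i, c("x", "y", "z")])
    ax <- as.numeric(screws[i, c("ax", "ay", "az")])
    s <- seq(0, screws$length[i], length.out = 30)
    pts <- matrix(entry, length(s), 3, byrow = TRUE) + outer(s, ax)
    min(vapply(seq_len(nrow(pts)), function(j)
      min(sqrt(rowSums(sweep(gc, 2, pts[j, ])^2))), numeric(1)))
  }, numeric(1))
}

#' Apply a screw configuration mask
#'
#' SC1 keeps all screws; SC2 removes the screw with minimum distance to
#' the osteotomy gap; SC3 removes the most distal screw (shorter plate).
#' Ties are broken by screw label order.  Masking an already-masked
#' plate, or leaving fewer than two screws on one side, is an error.
#'
#' @param plate a `plate_model`.
#' @param sc one of "SC1", "SC2", "SC3".
#' @return the masked `plate_model` (with `config` updated).
#' @export
apply_screw_configuration <- function(plate, sc = c("SC1", "SC2", "SC3")) {
  sc <- match.arg(sc)
  if (sc == "SC1") return(plate)
  if (plate$config != "SC1")
    stop("configuration error: plate already masked with ", plate$config)
  s <- plate$screws
  if (sc == "SC2") {
    d <- s$dist_to_gap
    if (all(is.na(d)))
      stop("configuration error: no gap region to measure screw distance to")
    drop <- which(d == min(d, na.rm = TRUE))[1]
  } else {
    drop <- which(s$z == min(s$z))[1]
  }
  active <- plate$active
  active[drop] <- FALSE
  for (side in c("proximal", "distal"))
    if (sum(active[s$side == side]) < 2)
      stop("configuration error: fewer than 2 ", side,
           " screws would remain")
  plate$active <- active
  plate$config <- sc
  plate
}

#' Active screws of a plate
#' @param plate a `plate_model`.
#' @return data.frame of active screws.
#' @export
active_screws <- function(plate) plate$screws[plate$active, , drop = FALSE]
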