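# Small-deformation heterogeneous linear-elastic finite elements.
#
# Solid phase: 4-node constant-strain tetrahedra (bone, gap, plate) with
# per-element isotropic (E, nu).  Screws: 2-node Euler-Bernoulli beams on
# their own 6-DOF nodes, coupled to the plate and bone translations by
# penalty multipoint ties.  Units: mm, N, MPa.  Element stiffness is
# linear in E at fixed nu, so unit-modulus triplets are cached and only
# rescaled when the healing-stage or material field changes.

lame <- function(E, nu) list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
                             mu = E / (2 * (1 + nu)))

# shape-function gradients and volumes for all tets at once
tet_gradients <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4], , drop = FALSE] - p1
  det <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
    e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
    e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  if (any(det <= 0))
    stop("assembly error: inverted element(s) ",
         paste(utils::head(which(det <= 0), 5), collapse = ", "))
  V <- det / 6
  # rows of inv([e1; e2; e3]) give grad(N2), grad(N3), grad(N4)
  inv <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                              a[, 3] * b[, 1] - a[, 1] * b[, 3],
                              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  g2 <- inv(e2, e3) / det
  g3 <- inv(e3, e1) / det
  g4 <- inv(e1, e2) / det
  g1 <- -(g2 + g3 + g4)
  list(V = V, g = list(g1, g2, g3, g4))
}

# COO triplets of the solid stiffness for unit Young's modulus, using the
# closed-form node-pair blocks of the linear tet:
#   K_nm[i,j] = V * (lambda b_n[i] b_m[j] + mu b_n[j] b_m[i]
#                    + mu delta_ij (b_n . b_m))
tet_triplets_unitE <- function(nodes, tets, nu) {
  gr <- tet_gradients(nodes, tets)
  lam <- lame(1, nu)
  nel <- nrow(tets)
  ii <- jj <- vv <- vector("list", 144)
  blk <- 0
  for (n in 1:4) for (m in 1:4) {
    bn <- gr$g[[n]]; bm <- gr$g[[m]]
    dot <- rowSums(bn * bm)
    for (i in 1:3) for (j in 1:3) {
      blk <- blk + 1
      ii[[blk]] <- (tets[, n] - 1L) * 3L + i
      jj[[blk]] <- (tets[, m] - 1L) * 3L + j
      vv[[blk]] <- gr$V * (lam$lambda * bn[, i] * bm[, j] +
                             lam$mu * bn[, j] * bm[, i] +
                             (if (i == j) lam$mu * dot else 0))
    }
  }
  list(i = unlist(ii), j = unlist(jj), v = unlist(vv),
       elem = rep.int(seq_len(nel), 144))
}

# 12x12 global stiffness of a 2-node circular-section Euler-Bernoulli beam
beam_stiffness <- function(p1, p2, E, nu, diameter) {
  L <- sqrt(sum((p2 - p1)^2))
  stopifnot(L > 1e-9)
  G <- E / (2 * (1 + nu))
  A <- pi * diameter^2 / 4
  I <- pi * diameter^4 / 64
  J <- 2 * I
  k <- matrix(0, 12, 12)
  ax <- E * A / L; tr <- G * J / L
  b1 <- 12 * E * I / L^3; b2 <- 6 * E * I / L^2
  b3 <- 4 * E * I / L; b4 <- 2 * E * I / L
  # dof order per node: ux uy uz rx ry rz (local: x axial)
  idx <- function(n, d) (n - 1) * 6 + d
  set <- function(i, j, v) { k[i, j] <<- k[i, j] + v }
  # axial
  for (s in list(c(1, 1, ax), c(7, 7, ax), c(1, 7, -ax), c(7, 1, -ax)))
    set(s[1], s[2], s[3])
  # torsion
  for (s in list(c(4, 4, tr), c(10, 10, tr), c(4, 10, -tr), c(10, 4, -tr)))
    set(s[1], s[2], s[3])
  # bending about local z (displacement y, rotation rz: dofs 2,6,8,12)
  bz <- matrix(c(b1, b2, -b1, b2,
                 b2, b3, -b2, b4,
                 -b1, -b2, b1, -b2,
                 b2, b4, -b2, b3), 4, 4, byrow = TRUE)
  dz <- c(2, 6, 8, 12)
  k[dz, dz] <- k[dz, dz] + bz
  # bending about local y (displacement z, rotation ry: dofs 3,5,9,11)
  by <- matrix(c(b1, -b2, -b1, -b2,
                 -b2, b3, b2, b4,
                 -b1, b2, b1, b2,
                 -b2, b4, b2, b3), 4, 4, byrow = TRUE)
  dy <- c(3, 5, 9, 11)
  k[dy, dy] <- k[dy, dy] + by
  # local -> global
  ex <- (p2 - p1) / L
  ref <- if (abs(ex[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ey <- ref - sum(ref * ex) * ex
  ey <- ey / sqrt(sum(ey^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  Lam <- rbind(ex, ey, ez)
  T <- matrix(0, 12, 12)
  for (b in 0:3) T[b * 3 + 1:3, b * 3 + 1:3] <- Lam
  t(T) %*% k %*% T
}

# k nearest nodes of `pool` (row indices) to point p, with IDW weights
nearest_weights <- function(nodes, pool, p, k = 4) {
  d2 <- rowSums(sweep(nodes[pool, , drop = FALSE], 2, p)^2)
  o <- order(d2)[seq_len(min(k, length(pool)))]
  w <- 1 / (d2[o] + 1e-6)
  list(nodes = pool[o], w = w / sum(w))
}

#' Build a finite-element model of one implanted construct
#'
#' Combines the osteotomized tibia, the material field, the plate mesh
#' and beam-element screws into one system.  Screw beam nodes are placed
#' every `beam_spacing` mm along each active screw axis; the head node is
#' tied to the nearest plate nodes and in-bone nodes to the nearest bone
#' nodes by penalty multipoint constraints.  The distal end of the
#' meshed segment is fully constrained.
#'
#' @param ost an `osteotomized_tibia`.
#' @param materials a `material_field` from [assign_materials()].
#' @param plate optional `plate_model` (NULL for a bone-only model).
#' @param k_tie penalty tie stiffness (N/mm).
#' @param k_rot grounded rotational spring on beam nodes (N mm/rad).
#' @param beam_spacing screw beam segment length (mm).
#' @param probe_radius peri-screw strain probe radius (mm).
#' @return object of class `fe_model`.
#' @export
build_fe_model <- function(ost, materials, plate = NULL,
                           k_tie = 1e7, k_rot = 10, beam_spacing = 6,
                           probe_radius = 2) {
  nodes <- ost$nodes
  tets <- ost$tets
  E <- materials$E
  nu <- materials$nu
  labels <- materials$set
  n_bone_nodes <- nrow(nodes)
  screws <- NULL
  if (!is.null(plate)) {
    offset <- nrow(nodes)
    nodes <- rbind(nodes, plate$nodes)
    tets <- rbind(tets, plate$tets + offset)
    E <- c(E, rep(plate$E, nrow(plate$tets)))
    nu <- c(nu, rep(plate$nu, nrow(plate$tets)))
    labels <- c(labels, rep("plate", nrow(plate$tets)))
    screws <- active_screws(plate)
    plate_nodes <- offset + seq_len(nrow(plate$nodes))
  } else plate_nodes <- integer(0)
  bone_nodes <- seq_len(n_bone_nodes)
  # beam chains for screws
  beam_nodes <- NULL; beam_elems <- NULL; ties <- list()
  if (!is.null(screws) && nrow(screws) > 0) {
    for (si in seq_len(nrow(screws))) {
      entry <- as.numeric(screws[si, c("x", "y", "z")])
      axv <- as.numeric(screws[si, c("ax", "ay", "az")])
      len <- screws$length[si]
      svals <- unique(c(seq(0, len, by = beam_spacing), len))
      pts <- matrix(entry, length(svals), 3, byrow = TRUE) + outer(svals, axv)
      base <- if (is.null(beam_nodes)) 0 else nrow(beam_nodes)
      beam_nodes <- rbind(beam_nodes, pts)
      for (b in seq_len(length(svals) - 1))
        beam_elems <- rbind(beam_elems,
                            c(base + b, base + b + 1, screws$diameter[si]))
      # head node tied to plate, in-bone nodes tied to bone
      ties[[length(ties) + 1]] <-
        c(list(beam = base + 1), nearest_weights(nodes, plate_nodes, pts[1, ]))
      for (b in 2:length(svals))
        ties[[length(ties) + 1]] <-
          c(list(beam = base + b), nearest_weights(nodes, bone_nodes, pts[b, ]))
    }
  }
  n_beam <- if (is.null(beam_nodes)) 0L else nrow(beam_nodes)
  # constrain the distal face of the reference mesh (fixed distal end)
  ref_z <- if (!is.null(ost$ref_nodes)) ost$ref_nodes[, 3] else ost$nodes[, 3]
  fixed_nodes <- which(ref_z <= min(ref_z) + 1e-6)
  fixed_dofs <- as.vector(outer(1:3, (fixed_nodes - 1L) * 3L, "+"))
  trip <- tet_triplets_unitE(nodes, tets, nu[1])
  model <- structure(list(
    nodes = nodes, tets = tets, E = E, nu = nu, labels = labels,
    n_bone_nodes = n_bone_nodes, bone_nodes = bone_nodes,
    plate_nodes = plate_nodes,
    beam_nodes = beam_nodes, beam_elems = beam_elems, ties = ties,
    n_beam = n_beam, k_tie = k_tie, k_rot = k_rot,
    screws = screws, probe_radius = probe_radius,
    plate_E = if (!is.null(plate)) plate$E else NA_real_,
    plate_nu = if (!is.null(plate)) plate$nu else NA_real_,
    fixed_dofs = fixed_dofs, trip = trip,
    n_solid_dof = 3L * nrow(nodes),
    n_dof = 3L * nrow(nodes) + 6L * n_beam,
    ost = ost), class = "fe_model")
  model
}

#' Assemble the global sparse stiffness matrix
#'
#' Solid unit-modulus triplets are rescaled by the per-element modulus;
#' beams and penalty ties are added on top.  The result is symmetric and,
#' once the fixed DOFs are removed, positive definite.
#'
#' @param model an `fe_model`.
#' @param E optional per-element modulus override (defaults to the
#'   model's material field).
#' @return sparse symmetric `dgCMatrix` of size n_dof x n_dof.
#' @export
assemble <- function(model, E = model$E) {
  tr <- model$trip
  iL <- list(tr$i); jL <- list(tr$j); vL <- list(E[tr$elem] * tr$v)
  off <- model$n_solid_dof
  if (model$n_beam > 0) {
    for (r in seq_len(nrow(model$beam_elems))) {
      be <- model$beam_elems[r, ]
      n1 <- be[1]; n2 <- be[2]
      kb <- beam_stiffness(model$beam_nodes[n1, ], model$beam_nodes[n2, ],
                           model$plate_E, model$plate_nu, be[3])
      dofs <- c(off + (n1 - 1) * 6 + 1:6, off + (n2 - 1) * 6 + 1:6)
      iL[[length(iL) + 1]] <- rep(dofs, each = 12)
      jL[[length(jL) + 1]] <- rep(dofs, times = 12)
      vL[[length(vL) + 1]] <- as.vector(t(kb))
    }
    # weak grounded rotational springs: the penalty ties couple only
    # translations, leaving each screw's axial-spin mode unresisted;
    # physically that spin is restrained by thread purchase.  The spring
    # is ~4 orders below the beam torsional stiffness, so it removes the
    # singular mode without affecting the bending/shear response.
    rot_dofs <- off + as.vector(outer(4:6, (seq_len(model$n_beam) - 1L) * 6L,
                                      "+"))
    iL[[length(iL) + 1]] <- rot_dofs
    jL[[length(jL) + 1]] <- rot_dofs
    vL[[length(vL) + 1]] <- rep(model$k_rot, length(rot_dofs))
    for (tie in model$ties) {
      bdof <- off + (tie$beam - 1) * 6
      for (comp in 1:3) {
        g_idx <- c(bdof + comp, (tie$nodes - 1L) * 3L + comp)
        g_val <- c(1, -tie$w)
        iL[[length(iL) + 1]] <- rep(g_idx, each = length(g_idx))
        jL[[length(jL) + 1]] <- rep(g_idx, times = length(g_idx))
        vL[[length(vL) + 1]] <- model$k_tie *
          as.vector(outer(g_val, g_val))
      }
    }
  }
  Matrix::sparseMatrix(i = unlist(iL), j = unlist(jL), x = unlist(vL),
                       dims = c(model$n_dof, model$n_dof), symmetric = FALSE)
}

#' Solve one or more load steps
#'
#' Removes the fixed DOFs, factors the reduced stiffness once (sparse
#' Cholesky) and back-substitutes every right-hand side.  A step whose
#' relative residual exceeds 1e-8, or a factorization failure, is
#' reported as unsolved (`solved = FALSE`) rather than zero-filled.
#'
#' @param model an `fe_model`.
#' @param K assembled stiffness from [assemble()].
#' @param F n_dof x n_steps dense matrix of nodal loads (N).
#' @return list with `U` (n_dof x n_steps displacements, NA where
#'   unsolved) and logical `solved` per step.
#' @export
solve_load_steps <- function(model, K, F) {
  F <- as.matrix(F)
  free <- setdiff(seq_len(model$n_dof), model$fixed_dofs)
  if (length(model$fixed_dofs) < 6)
    stop("constraint error: fewer than 6 constrained DOFs")
  Kff <- K[free, free]
  U <- matrix(NA_real_, model$n_dof, ncol(F))
  solved <- rep(FALSE, ncol(F))
  ok <- TRUE
  uf <- tryCatch({
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE)
    as.matrix(Matrix::solve(ch, F[free, , drop = FALSE]))
  }, error = function(e) { ok <<- FALSE; NULL })
  if (ok) {
    res <- Kff %*% uf - F[free, , drop = FALSE]
    for (s in seq_len(ncol(F))) {
      fn <- sqrt(sum(F[free, s]^2))
      rn <- sqrt(sum(res[, s]^2))
      if (fn == 0 || rn / fn <= 1e-8) {
        U[free, s] <- uf[, s]
        U[model$fixed_dofs, s] <- 0
        solved[s] <- TRUE
      }
    }
  }
  list(U = U, solved = solved)
}

#' Element stresses, principal stresses and von Mises measures
#'
#' Constant-strain recovery per tetrahedron: principal stresses are the
#' closed-form eigenvalues of the 3x3 stress tensor, sorted
#' s1 >= s2 >= s3; von Mises stress is
#' sqrt(0.5 * ((s1-s2)^2 + (s2-s3)^2 + (s3-s1)^2)) and the von Mises
#' (equivalent deviatoric) strain is sqrt(2/3) * ||dev eps||.
#'
#' @param model an `fe_model`.
#' @param u displacement vector (solid DOFs used).
#' @return data.frame per element: vm stress (MPa), s1, s3, vm strain.
#' @export
element_von_mises <- function(model, u) {
  gr <- tet_gradients(model$nodes, model$tets)
  ux <- matrix(u[1:model$n_solid_dof], nrow = 3)[1, ]
  uy <- matrix(u[1:model$n_solid_dof], nrow = 3)[2, ]
  uz <- matrix(u[1:model$n_solid_dof], nrow = 3)[3, ]
  exx <- eyy <- ezz <- exy <- eyz <- ezx <- 0
  for (n in 1:4) {
    b <- gr$g[[n]]; nd <- model$tets[, n]
    exx <- exx + b[, 1] * ux[nd]
    eyy <- eyy + b[, 2] * uy[nd]
    ezz <- ezz + b[, 3] * uz[nd]
    exy <- exy + 0.5 * (b[, 2] * ux[nd] + b[, 1] * uy[nd])
    eyz <- eyz + 0.5 * (b[, 3] * uy[nd] + b[, 2] * uz[nd])
    ezx <- ezx + 0.5 * (b[, 1] * uz[nd] + b[, 3] * ux[nd])
  }
  lm <- lame(model$E, model$nu)
  tr_e <- exx + eyy + ezz
  sxx <- lm$lambda * tr_e + 2 * lm$mu * exx
  syy <- lm$lambda * tr_e + 2 * lm$mu * eyy
  szz <- lm$lambda * tr_e + 2 * lm$mu * ezz
  sxy <- 2 * lm$mu * exy; syz <- 2 * lm$mu * eyz; szx <- 2 * lm$mu * ezx
  pr <- sym3_eigenvalues(sxx, syy, szz, sxy, syz, szx)
  vm <- sqrt(0.5 * ((pr$l1 - pr$l2)^2 + (pr$l2 - pr$l3)^2 +
                      (pr$l3 - pr$l1)^2))
  me <- tr_e / 3
  dev2 <- (exx - me)^2 + (eyy - me)^2 + (ezz - me)^2 +
    2 * (exy^2 + eyz^2 + ezx^2)
  evm <- sqrt(2 / 3 * dev2)
  data.frame(vm_stress = vm, s1 = pr$l1, s2 = pr$l2, s3 = pr$l3,
             vm_strain = evm)
}

# closed-form eigenvalues of symmetric 3x3 tensors (vectorised Cardano)
sym3_eigenvalues <- function(axx, ayy, azz, axy, ayz, azx) {
  q <- (axx + ayy + azz) / 3
  bxx <- axx - q; byy <- ayy - q; bzz <- azz - q
  p2 <- bxx^2 + byy^2 + bzz^2 + 2 * (axy^2 + ayz^2 + azx^2)
  p <- sqrt(pmax(p2 / 6, 0))
  detB <- bxx * (byy * bzz - ayz^2) - axy * (axy * bzz - ayz * azx) +
    azx * (axy * ayz - byy * azx)
  r <- ifelse(p > 0, detB / 2 / p^3, 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  list(l1 = l1, l2 = l2, l3 = l3)
}

#' Trial outcomes of one solved load step
#'
#' Maximum plate von Mises stress, maximum von Mises strain in the bone
#' near any active screw (probe radius around the screw axes; widened to
#' the nearest bone element when the mesh is coarser than the radius),
#' and interfragmentary motion: the maximum relative displacement
#' magnitude between paired proximal/distal faces of the osteotomy gap.
#'
#' @param model an `fe_model`.
#' @param u displacement vector of one solved step.
#' @return one-row data.frame: max_plate_vm_stress (MPa),
#'   max_periscrew_bone_vm_strain, ifm (mm).
#' @export
extract_outcomes <- function(model, u) {
  st <- element_von_mises(model, u)
  is_plate <- model$labels == "plate"
  max_plate <- if (any(is_plate)) max(st$vm_stress[is_plate]) else NA_real_
  is_bone <- model$labels %in% c("proximal", "distal", "cortical_hinge")
  strain <- NA_real_
  if (!is.null(model$screws)) {
    if (nrow(model$screws) == 0)
      stop("strain probe error: no active screws")
    cent <- tet_centroids(model$nodes, model$tets)
    dmin <- rep(Inf, nrow(cent))
    for (si in seq_len(nrow(model$screws))) {
      entry <- as.numeric(model$screws[si, c("x", "y", "z")])
      axv <- as.numeric(model$screws[si, c("ax", "ay", "az")])
      len <- model$screws$length[si]
      rel <- sweep(cent, 2, entry)
      tproj <- pmin(pmax(rel %*% axv, 0), len)
      d <- sqrt(rowSums((rel - outer(as.numeric(tproj), axv))^2))
      dmin <- pmin(dmin, d)
    }
    dmin[!is_bone] <- Inf
    r <- max(model$probe_radius, min(dmin[is_bone]) + 1e-9)
    sel <- is_bone & dmin <= r
    strain <- max(st$vm_strain[sel])
  }
  ifm <- interfragmentary_motion(model, u)
  data.frame(max_plate_vm_stress = max_plate,
             max_periscrew_bone_vm_strain = strain, ifm = ifm)
}

interfragmentary_motion <- function(model, u) {
  ost <- model$ost
  gap <- ost$labels %in% c("gap", "cortical_hinge")
  if (!any(gap)) return(0)
  nid <- unique(as.vector(ost$tets[gap, , drop = FALSE]))
  prox <- nid[!ost$distal_node[nid]]
  dist <- nid[ost$distal_node[nid]]
  if (!length(prox) || !length(dist)) return(0)
  up <- matrix(u[1:model$n_solid_dof], ncol = 3, byrow = TRUE)
  # pair each proximal face node with its nearest distal face node
  best <- vapply(prox, function(p) {
    d2 <- rowSums(sweep(ost$nodes[dist, , drop = FALSE], 2,
                        ost$nodes[p, ])^2)
    dist[which.min(d2)]
  }, numeric(1))
  rel <- up[prox, , drop = FALSE] - up[best, , drop = FALSE]
  max(sqrt(rowSums(rel^2)))
}

#' Mesh-convergence decision
#'
#' Converged iff the peak plate von Mises stress changes by strictly
#' less than 5% when the element count is doubled.
#'
#' @param coarse,fine peak stresses (MPa) of the nested meshes.
#' @return logical.
#' @export
convergence_check <- function(coarse, fine) {
  abs(fine - coarse) / abs(coarse) < 0.05
}

#' Distribute an application-point force to nearby surface nodes
#'
#' Inverse-distance weights over the nodes within `radius` of the point
#' (falling back to the `k` nearest when none are inside), avoiding
#' point-load singularities.
#'
#' @param model an `fe_model`.
#' @param point 3-vector application point (mm).
#' @param force 3-vector force (N).
#' @param radius patch radius (mm).
#' @param k fallback node count.
#' @return sparse-ish dense force vector of length n_dof.
#' @export
nodal_force_patch <- function(model, point, force, radius = 6, k = 4) {
  f <- numeric(model$n_dof)
  bn <- model$bone_nodes
  d2 <- rowSums(sweep(model$nodes[bn, , drop = FALSE], 2, point)^2)
  sel <- which(d2 <= radius^2)
  if (!length(sel)) sel <- order(d2)[seq_len(k)]
  w <- 1 / (d2[sel] + 1e-6); w <- w / sum(w)
  for (comp in 1:3)
    f[(bn[sel] - 1L) * 3L + comp] <- f[(bn[sel] - 1L) * 3L + comp] +
      w * force[comp]
  f
}

#' Load vectors for all 15 steps of a registered patient load table
#'
#' @param model an `fe_model`.
#' @param plt registered, scaled `activity_load_table` (forces in N).
#' @param radius patch radius (mm).
#' @return n_dof x 15 matrix.
#' @export
load_step_matrix <- function(model, plt, radius = 6) {
  steps <- sort(unique(plt$table$step))
  F <- matrix(0, model$n_dof, length(steps))
  for (s in seq_along(steps)) {
    rows <- plt$table[plt$table$step == steps[s], ]
    for (r in seq_len(nrow(rows))) {
      p <- plt$points[plt$points$point_name == rows$point_name[r],
                      c("x", "y", "z")]
      F[, s] <- F[, s] + nodal_force_patch(model, as.numeric(p),
                                           as.numeric(rows[r, c("fx", "fy",
                                                                "fz")]),
                                           radius)
    }
  }
  F
}

#' Plain solid model (verification path)
#'
#' Wraps a bare tetrahedral mesh with uniform or per-element properties
#' into an `fe_model` without plate, screws or gap -- the configuration
#' used by the solver verification suite (patch test, bar, cantilever).
#'
#' @param mesh list with `nodes` and `tets`.
#' @param E Young's modulus, scalar or per element (MPa).
#' @param nu Poisson ratio (single value).
#' @param fixed_nodes node indices to constrain (all 3 components).
#' @return an `fe_model`.
#' @export
solid_model <- function(mesh, E, nu = 0.3, fixed_nodes = integer(0)) {
  nel <- nrow(mesh$tets)
  if (length(E) == 1) E <- rep(E, nel)
  trip <- tet_triplets_unitE(mesh$nodes, mesh$tets, nu)
  structure(list(
    nodes = mesh$nodes, tets = mesh$tets, E = E, nu = rep(nu, nel),
    labels = rep("proximal", nel),
    n_bone_nodes = nrow(mesh$nodes), bone_nodes = seq_len(nrow(mesh$nodes)),
    plate_nodes = integer(0), beam_nodes = NULL, beam_elems = NULL,
    ties = list(), n_beam = 0L, k_tie = 0, screws = NULL,
    probe_radius = 2, plate_E = NA_real_, plate_nu = NA_real_,
    fixed_dofs = as.vector(outer(1:3, (fixed_nodes - 1L) * 3L, "+")),
    trip = trip, n_solid_dof = 3L * nrow(mesh$nodes),
    n_dof = 3L * nrow(mesh$nodes),
    ost = list(labels = rep("proximal", nel), tets = mesh$tets,
               nodes = mesh$nodes,
               distal_node = rep(FALSE, nrow(mesh$nodes)))),
    class = "fe_model")
}

#' Solve with prescribed (possibly nonzero) boundary displacements
#'
#' Partitioned elimination: free DOFs solve
#' `K_ff u_f = f_f - K_fc u_c`.
#'
#' @param model an `fe_model`.
#' @param K assembled stiffness.
#' @param f load vector.
#' @param fixed_values displacements of the model's fixed DOFs (recycled).
#' @return full displacement vector.
#' @export
solve_prescribed <- function(model, K, f = numeric(model$n_dof),
                             fixed_values = 0) {
  fixed <- model$fixed_dofs
  uc <- rep_len(fixed_values, length(fixed))
  free <- setdiff(seq_len(model$n_dof), fixed)
  rhs <- f[free] - as.numeric(K[free, fixed] %*% uc)
  uf <- as.numeric(Matrix::solve(Matrix::forceSymmetric(K[free, free]), rhs))
  u <- numeric(model$n_dof)
  u[fixed] <- uc
  u[free] <- uf
  u
}

#' Consistent nodal forces for a uniform traction on boundary faces
#'
#' Lumps one third of `traction * face area` to each node of every
#' selected boundary triangle.
#'
#' @param model an `fe_model`.
#' @param face_select function(nodes) -> logical, TRUE for nodes on the
#'   loaded surface (a face is loaded when all 3 nodes qualify).
#' @param traction 3-vector traction (MPa).
#' @return force vector of length n_dof.
#' @export
traction_forces <- function(model, face_select, traction) {
  bf <- check_mesh(list(nodes = model$nodes,
                        tets = model$tets))$boundary_faces
  on <- face_select(model$nodes)
  sel <- bf[on[bf[, 1]] & on[bf[, 2]] & on[bf[, 3]], , drop = FALSE]
  f <- numeric(model$n_dof)
  for (r in seq_len(nrow(sel))) {
    p <- model$nodes[sel[r, ], ]
    cr <- crossprod3(p[2, ] - p[1, ], p[3, ] - p[1, ])
    area <- sqrt(sum(cr^2)) / 2
    for (n in sel[r, ]) for (comp in 1:3)
      f[(n - 1) * 3 + comp] <- f[(n - 1) * 3 + comp] +
        traction[comp] * area / 3
  }
  f
}

crossprod3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                               a[3] * b[1] - a[1] * b[3],
                               a[1] * b[2] - a[2] * b[1])
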