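symmetric_landmarks <- function(ankle_x = 0) {
  landmark_set(hip_center = c(0, 0, 800), knee_center = c(0, 0, 400),
               plateau_medial = c(-40, 0, 400),
               plateau_lateral = c(40, 0, 400),
               ankle_center = c(ankle_x, 0, 0))
}

test_that("a collinear limb axis crosses the plateau at its midpoint", {
  expect_equal(mechanical_axis_fraction(symmetric_landmarks()), 0.5)
})

test_that("the crossing fraction matches a 2-D line-segment oracle", {
  lm <- landmark_set(hip_center = c(0, 0, 800), knee_center = c(0, 0, 400),
                     plateau_medial = c(-40, 0, 400),
                     plateau_lateral = c(40, 0, 400),
                     ankle_center = c(-10, 0, 0))
  # independent 2-D intersection: x(z) interpolated hip->ankle at z = 400
  t <- (400 - 0) / (800 - 0)
  x_cross <- -10 + t * (0 - (-10))
  oracle <- (x_cross - (-40)) / 80
  expect_equal(mechanical_axis_fraction(lm), oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.4375)
})

test_that("degenerate plateau geometry raises errors", {
  expect_error(landmark_set(c(0, 0, 800), c(0, 0, 400), c(0, 0, 400),
                            c(0, 0, 400), c(0, 0, 0)), "coincide")
  lm <- symmetric_landmarks()
  lm2 <- unclass(lm)
  lm2["plateau_medial", 1] <- 0; lm2["plateau_lateral", 1] <- 0
  expect_error(
    mechanical_axis_fraction(structure(lm2, class = "landmark_set")),
    "zero-length")
})

test_that("a limb already at the target needs zero correction", {
  # construct the ankle offset that puts the crossing exactly at 0.625
  lm <- symmetric_landmarks()
  f <- function(ax) mechanical_axis_fraction(symmetric_landmarks(ax)) - 0.625
  ax <- uniroot(f, c(0, 50), tol = 1e-12)$root
  lm <- symmetric_landmarks(ax)
  expect_lt(abs(correction_angle(lm, 0.625)), 0.01)
})

test_that("planned angles match an exhaustive 0.001-degree scan", {
  for (tb in fixture_cohort()$tibias) {
    theta <- correction_angle(tb$landmarks)
    lm <- unclass(tb$landmarks)
    hinge <- lm["plateau_lateral", ] - c(0, 0, 10)
    grid <- seq(-30, 30, by = 0.001)
    err <- vapply(grid, function(th) {
      ank <- rotate_points(matrix(lm["ankle_center", ], 1, 3), hinge,
                           c(0, 1, 0), -th)
      lm2 <- lm; lm2["ankle_center", ] <- ank
      abs(mechanical_axis_fraction(structure(lm2,
                                             class = "landmark_set")) -
            0.625)
    }, numeric(1))
    expect_lt(abs(theta - grid[which.min(err)]), 0.01)
  }
})

test_that("re-planning after applying the plan returns zero", {
  ost <- fixture_ost()
  expect_lt(abs(correction_angle(ost$landmarks)), 0.01)
})

test_that("unreachable targets raise a planning error", {
  lm <- landmark_set(hip_center = c(0, 0, 800), knee_center = c(0, 0, 400),
                     plateau_medial = c(-40, 0, 400),
                     plateau_lateral = c(40, 0, 400),
                     ankle_center = c(-500, 0, 380))
  expect_error(correction_angle(lm), "planning error")
  expect_error(correction_angle(symmetric_landmarks(), hinge_depth = 5),
               "10 mm")
})

test_that("the osteotomy rotation is rigid and hinge-preserving", {
  ost <- fixture_ost()
  dn <- which(ost$distal_node)
  set.seed(1)
  pairs <- cbind(sample(dn, 50, replace = TRUE),
                 sample(dn, 50, replace = TRUE))
  d0 <- sqrt(rowSums((ost$ref_nodes[pairs[, 1], ] -
                        ost$ref_nodes[pairs[, 2], ])^2))
  d1 <- sqrt(rowSums((ost$nodes[pairs[, 1], ] -
                        ost$nodes[pairs[, 2], ])^2))
  expect_lt(max(abs(d0 - d1)), 1e-9)
  v <- tet_volumes(ost$nodes, ost$tets)
  expect_true(all(v > 0))
})

test_that("the opened wedge dihedral equals the correction angle", {
  tb <- fixture_cohort()$tibias[[1]]
  plan <- plan_correction(tb)
  plan$correction_angle <- 8
  ost <- build_osteotomy(tb, plan)
  expect_equal(gap_dihedral_angle(ost), 8, tolerance = 1e-6)
})

test_that("zero correction returns the geometry unchanged, empty gap", {
  tb <- fixture_cohort()$tibias[[1]]
  plan <- plan_correction(tb)
  plan$correction_angle <- 0
  ost <- build_osteotomy(tb, plan)
  expect_equal(ost$nodes, tb$nodes)
  expect_false(any(ost$labels == "gap"))
})

test_that("correction angle grows with the generator's varus offset", {
  thetas <- vapply(c(10, 20, 35), function(v) {
    spec <- coarse_spec(n = 1, varus_offset_mean = v, varus_offset_sd = 0,
                        varus_offset_min = 0)
    tb <- build_tibia(sample_demographics(spec)[1, ], spec)
    correction_angle(tb$landmarks)
  }, numeric(1))
  expect_true(all(diff(thetas) > 0))
})

test_that("a cut plane outside the mesh raises a geometry error", {
  tb <- fixture_cohort()$tibias[[1]]
  plan <- plan_correction(tb)
  plan$hinge_point[3] <- plan$hinge_point[3] + 500
  expect_error(build_osteotomy(tb, plan), "geometry error")
})
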