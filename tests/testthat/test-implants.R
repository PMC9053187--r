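test_that("generic plates are patient-invariant in shape and screws", {
  co <- fixture_cohort()
  plates <- lapply(seq_len(2), function(i) {
    tb <- co$tibias[[i]]
    build_generic_plate(build_osteotomy(tb, plan_correction(tb)))
  })
  expect_equal(plates[[1]]$dims, plates[[2]]$dims)
  expect_equal(plates[[1]]$screws$zeta, plates[[2]]$screws$zeta)
  expect_equal(plates[[1]]$screws[, c("ax", "ay", "az", "length")],
               plates[[2]]$screws[, c("ax", "ay", "az", "length")])
  # placement differs with anatomy
  expect_false(isTRUE(all.equal(plates[[1]]$nodes, plates[[2]]$nodes)))
})

test_that("the flat generic plate stands off a curved tibia by > 0.5 mm", {
  ost <- fixture_ost()
  gp <- build_generic_plate(ost)
  expect_gt(max(gp$standoff), 0.5)
  expect_true(all(gp$standoff >= 0))
})

test_that("personalised plates conform to the bone surface", {
  co <- fixture_cohort()
  cls <- list()
  for (i in 1:2) {
    tb <- co$tibias[[i]]
    ost <- build_osteotomy(tb, plan_correction(tb))
    pp <- build_personalised_plate(ost, co$patients$mass_kg[i])
    expect_lte(max(pp$standoff), 0.5)
    cls[[i]] <- pp$centerline
  }
  # conformity implies anatomy-dependent centerlines
  expect_false(isTRUE(all.equal(cls[[1]], cls[[2]])))
})

test_that("no active personalised screw axis crosses the gap region", {
  ost <- fixture_ost()
  pp <- build_personalised_plate(ost, 90)
  gap_tets <- ost$tets[ost$labels == "gap", , drop = FALSE]
  for (i in which(pp$active)) {
    s <- pp$screws[i, ]
    svals <- seq(1, s$length, length.out = 25)
    pts <- matrix(as.numeric(s[c("x", "y", "z")]), 25, 3, byrow = TRUE) +
      outer(svals, as.numeric(s[c("ax", "ay", "az")]))
    expect_false(any(points_in_any_tet(pts, ost$nodes, gap_tets)),
                 info = s$label)
  }
})

test_that("personalised sizing scales with patient mass", {
  ost <- fixture_ost()
  light <- build_personalised_plate(ost, 70)
  heavy <- build_personalised_plate(ost, 120)
  expect_lt(light$dims[["width"]], heavy$dims[["width"]])
  expect_lt(light$dims[["thickness"]], heavy$dims[["thickness"]])
})

test_that("an oversized footprint raises a placement error", {
  ost <- fixture_ost()
  pars <- default_plate_params(generic_length = 400)
  expect_error(build_generic_plate(ost, pars), "placement error")
})

test_that("screw configurations mask deterministically", {
  ost <- fixture_ost()
  gp <- build_generic_plate(ost)
  expect_identical(apply_screw_configuration(gp, "SC1"), gp)
  sc2 <- apply_screw_configuration(gp, "SC2")
  # brute-force: the removed screw is the one nearest the gap
  expect_equal(gp$screws$label[!sc2$active],
               gp$screws$label[which.min(gp$screws$dist_to_gap)])
  sc3 <- apply_screw_configuration(gp, "SC3")
  expect_equal(gp$screws$label[!sc3$active],
               gp$screws$label[which.min(gp$screws$z)])
  expect_error(apply_screw_configuration(sc3, "SC3"),
               "configuration error")
  expect_error(apply_screw_configuration(sc2, "SC3"),
               "configuration error")
})

test_that("plates keep at least three screws per side before masking", {
  ost <- fixture_ost()
  for (p in list(build_generic_plate(ost),
                 build_personalised_plate(ost, 90))) {
    expect_gte(sum(p$screws$side == "proximal"), 3)
    expect_gte(sum(p$screws$side == "distal"), 3)
  }
})
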