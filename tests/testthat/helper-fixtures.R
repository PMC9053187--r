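# Shared fixtures: a coarse-mesh cohort spec keeps unit tests fast; the
# builders are memoised because several files reuse the same construct.

coarse_geometry <- function(...) {
  default_geometry_params(nu = 6, nv = 6, nz = 12, ...)
}

coarse_spec <- function(n = 2, seed = 42, ...) {
  cohort_spec(n = n, seed = seed, geometry = coarse_geometry(...))
}

.fixtures <- new.env()

fixture_cohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generate_cohort(coarse_spec())
  .fixtures$cohort
}

fixture_ost <- function() {
  if (is.null(.fixtures$ost)) {
    tb <- fixture_cohort()$tibias[[1]]
    .fixtures$ost <- build_osteotomy(tb, plan_correction(tb))
  }
  .fixtures$ost
}

fixture_construct <- function(arm = "Generic") {
  key <- paste0("construct_", arm)
  if (is.null(.fixtures[[key]])) {
    ost <- fixture_ost()
    pat <- fixture_cohort()$patients[1, ]
    plate <- if (arm == "Generic") build_generic_plate(ost) else
      build_personalised_plate(ost, pat$mass_kg)
    plate <- apply_screw_configuration(plate, "SC3")
    mat <- assign_materials(ost, "HS2")
    model <- build_fe_model(ost, mat, plate)
    plt <- patient_loads(default_load_table(), ost$landmarks, pat$mass_kg)
    F <- load_step_matrix(model, plt)
    .fixtures[[key]] <- list(ost = ost, pat = pat, plate = plate,
                             mat = mat, model = model, F = F)
  }
  .fixtures[[key]]
}

# point-in-tet membership for a set of query points against a tet subset
points_in_any_tet <- function(pts, nodes, tets) {
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    for (r in seq_len(nrow(tets))) {
      a <- nodes[tets[r, 1], ]; b <- nodes[tets[r, 2], ]
      c_ <- nodes[tets[r, 3], ]; d <- nodes[tets[r, 4], ]
      M <- cbind(b - a, c_ - a, d - a)
      lam <- tryCatch(solve(M, p - a), error = function(e) NULL)
      if (!is.null(lam) && all(lam > -1e-9) && sum(lam) < 1 + 1e-9)
        return(TRUE)
    }
    FALSE
  }, logical(1))
}
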