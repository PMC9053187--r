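# Trial orchestration: cohort -> plan -> implants -> materials -> loads
# -> FE -> statistics, with per-patient RNG streams, a dropped-case
# ledger and a JSON report.

#' Trial configuration
#'
#' The default stage/configuration matrix mirrors the study design: all
#' three screw configurations at healing stage 2, and configuration SC3
#' at stages 3 and 4 -- five (stage, configuration) combinations per
#' model, so a 28-patient two-arm trial schedules
#' 28 x 2 x 5 x 15 = 4200 load steps.
#'
#' @param cohort a [cohort_spec()].
#' @param stage_configs data.frame with columns stage, config.
#' @param flim a [fatigue_limit()].
#' @param load_table an `activity_load_table` (default the installed
#'   template).
#' @param plate_params a [default_plate_params()].
#' @param law a [density_modulus_law()].
#' @param target_fraction plateau crossing target.
#' @param bootstrap_B,bootstrap_seed cluster-bootstrap settings.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return object of class `trial_config`.
#' @export
trial_config <- function(cohort = cohort_spec(),
                         stage_configs = default_stage_configs(),
                         flim = fatigue_limit(),
                         load_table = NULL,
                         plate_params = default_plate_params(),
                         law = density_modulus_law(),
                         target_fraction = 0.625,
                         bootstrap_B = 2000,
                         bootstrap_seed = NULL,
                         out_dir = NULL) {
  stopifnot(all(c("stage", "config") %in% names(stage_configs)))
  structure(as.list(environment()), class = "trial_config")
}

#' Default (stage, screw-configuration) matrix
#' @return data.frame: SC1-SC3 at HS2; SC3 at HS3 and HS4.
#' @export
default_stage_configs <- function() {
  data.frame(stage = c("HS2", "HS2", "HS2", "HS3", "HS4"),
             config = c("SC1", "SC2", "SC3", "SC3", "SC3"),
             stringsAsFactors = FALSE)
}

#' Read a trial configuration from YAML
#'
#' Recognised keys: n_patients, seed, stages (list of {stage, config}),
#' flim_mean, flim_half_width, target_fraction, out_dir.  (The key is
#' `n_patients` rather than `n` because YAML 1.1 readers resolve a bare
#' `n` to boolean false.)
#'
#' @param path YAML file.
#' @return a `trial_config`.
#' @export
read_trial_config <- function(path) {
  y <- yaml::read_yaml(path)
  n <- y$n_patients %||% y$n %||% y[["FALSE"]] %||% 28
  sc <- if (!is.null(y$stages))
    do.call(rbind, lapply(y$stages, as.data.frame)) else
      default_stage_configs()
  trial_config(
    cohort = cohort_spec(n = n, seed = y$seed %||% 1),
    stage_configs = sc,
    flim = fatigue_limit(y$flim_mean %||% 200, y$flim_half_width %||% 20),
    target_fraction = y$target_fraction %||% 0.625,
    out_dir = y$out_dir)
}

#' Scheduled load steps of a trial (dry run)
#'
#' @param config a `trial_config`.
#' @return data.frame with one row per (patient, arm, stage, config,
#'   step).
#' @export
schedule_trial <- function(config) {
  pats <- sprintf("P%04d", seq_len(config$cohort$n))
  arms <- c("Generic", "Personalised")
  sc <- config$stage_configs
  out <- expand.grid(step = 1:15, row = seq_len(nrow(sc)), arm = arms,
                     patient = pats, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$stage <- sc$stage[out$row]
  out$config <- sc$config[out$row]
  out$row <- NULL
  out[, c("patient", "arm", "stage", "config", "step")]
}

#' Run the in silico trial
#'
#' For each virtual patient: one osteotomy plan; two arms implanting the
#' same osteotomy with the generic and the personalised plate; per
#' (arm, stage, configuration) a 15-step FE solve; then the trial
#' statistics.  Patients whose planning or geometry fails are flagged
#' and skipped (the trial continues), and unsolved load steps are
#' dropped and counted.
#'
#' @param config a `trial_config`.
#' @param verbose print per-patient progress.
#' @return object of class `trial_report`: `results` (one row per load
#'   step), `exceedance`, `odds_ratios`, `deltas`, `dropped`,
#'   `provenance`.
#' @export
run_trial <- function(config, verbose = FALSE) {
  lt <- config$load_table %||% default_load_table()
  cohort <- generate_cohort(config$cohort)
  sc <- config$stage_configs
  rows <- list(); dropped <- list()
  for (i in seq_len(nrow(cohort$patients))) {
    pat <- cohort$patients[i, ]
    res <- tryCatch(
      simulate_patient(cohort$tibias[[i]], pat, sc, lt, config),
      error = function(e) e)
    if (inherits(res, "error")) {
      dropped[[length(dropped) + 1]] <-
        data.frame(patient = pat$id, reason = conditionMessage(res))
      if (verbose) message(pat$id, " dropped: ", conditionMessage(res))
      next
    }
    rows[[length(rows) + 1]] <- res
    if (verbose) message(pat$id, " done (", nrow(res), " steps)")
  }
  results <- do.call(rbind, rows)
  report <- if (is.null(results))
    list(results = NULL, exceedance = list(), odds_ratios = list(),
         deltas = list(), anova_hs2 = NULL)
  else trial_statistics(results, config)
  report$dropped <- if (length(dropped)) do.call(rbind, dropped) else NULL
  report$provenance <- list(seed = config$cohort$seed,
                            n = config$cohort$n,
                            scheduled_steps = nrow(schedule_trial(config)),
                            solved_steps = sum(results$solved))
  class(report) <- "trial_report"
  if (!is.null(config$out_dir)) write_trial_report(report, config$out_dir)
  report
}

simulate_patient <- function(tibia, pat, sc, lt, config) {
  plan <- plan_correction(tibia, config$target_fraction)
  ost <- build_osteotomy(tibia, plan)
  plates <- list(
    Generic = build_generic_plate(ost, config$plate_params),
    Personalised = build_personalised_plate(ost, pat$mass_kg,
                                            config$plate_params))
  out <- list()
  for (arm in names(plates)) {
    for (cfg in unique(sc$config)) {
      plate <- apply_screw_configuration(plates[[arm]], cfg)
      model <- NULL
      for (stage in sc$stage[sc$config == cfg]) {
        mat <- assign_materials(ost, stage, config$law)
        if (is.null(model)) {
          model <- build_fe_model(ost, mat, plate)
          plt <- patient_loads(lt, ost$landmarks, pat$mass_kg)
          F <- load_step_matrix(model, plt)
        }
        model$E <- c(mat$E, rep(plate$E, nrow(plate$tets)))
        K <- assemble(model)
        sol <- solve_load_steps(model, K, F)
        for (s in 1:15) {
          oc <- if (sol$solved[s]) extract_outcomes(model, sol$U[, s]) else
            data.frame(max_plate_vm_stress = NA_real_,
                       max_periscrew_bone_vm_strain = NA_real_,
                       ifm = NA_real_)
          out[[length(out) + 1]] <- data.frame(
            patient = pat$id, arm = arm, stage = stage, config = cfg,
            step = s, stress = oc$max_plate_vm_stress,
            strain = oc$max_periscrew_bone_vm_strain, ifm = oc$ifm,
            solved = sol$solved[s], stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Recompute the trial statistics from a results table
#'
#' Takes a per-load-step results table (as produced by [run_trial()] or
#' read back from `results.csv`) and recomputes exceedance tables, odds
#' ratios, paired deltas and the HS2 screw-configuration ANOVA.
#'
#' @param results data.frame with columns patient, arm, stage, config,
#'   step, stress, strain, ifm, solved.
#' @param config a `trial_config` (for FLIM and bootstrap settings).
#' @return a `trial_report` (without provenance).
#' @export
analyse_results <- function(results, config = trial_config()) {
  rep <- trial_statistics(results, config)
  class(rep) <- "trial_report"
  rep
}

trial_statistics <- function(results, config) {
  bseed <- config$bootstrap_seed %||% (config$cohort$seed + 1000L)
  sc3 <- results[results$config == "SC3", ]
  stages <- sort(unique(sc3$stage))
  exceed <- list(); ors <- list(); deltas <- list()
  for (st in stages) {
    d <- sc3[sc3$stage == st, ]
    tab <- exceedance_table(
      data.frame(arm = d$arm, patient = d$patient, stress = d$stress,
                 solved = d$solved), config$flim)
    exceed[[st]] <- tab
    ors[[st]] <- tryCatch(odds_ratio(tab, "auto"),
                          error = function(e) NULL)
    for (oc in c("stress", "strain", "ifm")) {
      g <- data.frame(patient = d$patient[d$arm == "Generic"],
                      step = d$step[d$arm == "Generic"],
                      value = d[[oc]][d$arm == "Generic"],
                      solved = d$solved[d$arm == "Generic"])
      p <- data.frame(patient = d$patient[d$arm == "Personalised"],
                      step = d$step[d$arm == "Personalised"],
                      value = d[[oc]][d$arm == "Personalised"],
                      solved = d$solved[d$arm == "Personalised"])
      deltas[[paste(st, oc, sep = "_")]] <-
        tryCatch(paired_delta(g, p, B = config$bootstrap_B, seed = bseed),
                 error = function(e) NULL)
    }
  }
  anova_hs2 <- NULL
  hs2 <- results[results$stage == "HS2" & results$solved, ]
  if (length(unique(hs2$config)) >= 2) {
    anova_hs2 <- lapply(split(hs2, hs2$arm), function(d)
      screw_config_anova(data.frame(step = d$step, config = d$config,
                                    value = d$stress)))
  }
  list(results = results, exceedance = exceed, odds_ratios = ors,
       deltas = deltas, anova_hs2 = anova_hs2)
}

#' Write a trial report to disk
#'
#' Emits results.csv, contingency.csv, odds_ratios.csv, deltas.csv and
#' report.json under `dir`.
#'
#' @param report a `trial_report`.
#' @param dir output directory.
#' @export
write_trial_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$results, file.path(dir, "results.csv"),
            row.names = FALSE)
  cont <- do.call(rbind, lapply(names(report$exceedance), function(st)
    cbind(stage = st, exceedance_percentages(report$exceedance[[st]]))))
  write.csv(cont, file.path(dir, "contingency.csv"), row.names = FALSE)
  ors <- do.call(rbind, lapply(names(report$odds_ratios), function(st) {
    o <- report$odds_ratios[[st]]
    if (is.null(o)) return(NULL)
    data.frame(stage = st, OR = o$OR, ci_low = o$ci_low,
               ci_high = o$ci_high, p = o$p, method = o$method)
  }))
  if (!is.null(ors))
    write.csv(ors, file.path(dir, "odds_ratios.csv"), row.names = FALSE)
  dl <- do.call(rbind, lapply(names(report$deltas), function(k) {
    d <- report$deltas[[k]]
    if (is.null(d)) return(NULL)
    data.frame(key = k, mean = d$mean, ci_low = d$ci_low,
               ci_high = d$ci_high, n = d$n)
  }))
  if (!is.null(dl))
    write.csv(dl, file.path(dir, "deltas.csv"), row.names = FALSE)
  json <- list(provenance = report$provenance,
               contingency = cont,
               odds_ratios = ors, deltas = dl)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Verify the finite-element core against analytic oracles
#'
#' Runs the patch test (interior constant stress), the uniaxial bar
#' (stress P/A, tip displacement PL/AE), the end-loaded cantilever
#' (tip deflection vs PL^3/3EI), zero stress under rigid translation,
#' and exact load linearity.  Any failure should block trial runs.
#'
#' @param cantilever_n mesh density of the cantilever case (cells across
#'   the section; the axial count is 5x this).
#' @param tol_bar,tol_cantilever relative tolerances.
#' @return data.frame of checks with measured errors and pass flags.
#' @export
validate_solver <- function(cantilever_n = 12, tol_bar = 0.01,
                            tol_cantilever = 0.05) {
  checks <- list()
  ## patch test
  m <- box_mesh(2, 2, 2, 3, 3, 3)
  bnodes <- sort(unique(as.vector(check_mesh(m)$boundary_faces)))
  mod <- solid_model(m, E = 1000, nu = 0.3, fixed_nodes = bnodes)
  K <- assemble(mod)
  A <- matrix(c(1, 0.2, 0, 0.3, -1, 0.1, 0, 0.5, 2), 3, 3) * 1e-3
  uc <- as.vector(t(m$nodes[bnodes, ] %*% t(A)))
  u <- solve_prescribed(mod, K, fixed_values = uc)
  st <- element_von_mises(mod, u)
  spread <- max(st$vm_stress) - min(st$vm_stress)
  checks$patch <- data.frame(check = "patch_constant_stress",
                             error = spread, tol = 1e-8,
                             pass = spread < 1e-8)
  ## uniaxial bar (nu = 0 so the clamped end is compatible with P/A)
  Lb <- 100; W <- 10; E <- 2000; P <- 500
  m2 <- box_mesh(W, W, Lb, 4, 4, 20)
  mod2 <- solid_model(m2, E = E, nu = 0,
                      fixed_nodes = which(m2$nodes[, 3] < 1e-9))
  K2 <- assemble(mod2)
  f <- traction_forces(mod2, function(nd) nd[, 3] > Lb - 1e-9,
                       c(0, 0, P / W^2))
  sol <- solve_load_steps(mod2, K2, matrix(f, ncol = 1))
  st2 <- element_von_mises(mod2, sol$U[, 1])
  uz <- sol$U[, 1][seq(3, mod2$n_dof, 3)]
  tip <- mean(uz[m2$nodes[, 3] > Lb - 1e-9])
  err_s <- max(abs(st2$s1 - P / W^2)) / (P / W^2)
  err_u <- abs(tip - P * Lb / (W^2 * E)) / (P * Lb / (W^2 * E))
  checks$bar_stress <- data.frame(check = "bar_axial_stress",
                                  error = err_s, tol = tol_bar,
                                  pass = err_s < tol_bar)
  checks$bar_disp <- data.frame(check = "bar_tip_displacement",
                                error = err_u, tol = tol_bar,
                                pass = err_u < tol_bar)
  ## cantilever tip deflection
  H <- 10; Pc <- 10
  m3 <- box_mesh(W, H, Lb, cantilever_n, cantilever_n, 5 * cantilever_n)
  mod3 <- solid_model(m3, E = 1000, nu = 0,
                      fixed_nodes = which(m3$nodes[, 3] < 1e-9))
  K3 <- assemble(mod3)
  f3 <- traction_forces(mod3, function(nd) nd[, 3] > Lb - 1e-9,
                        c(0, Pc / (W * H), 0))
  sol3 <- solve_load_steps(mod3, K3, matrix(f3, ncol = 1))
  uy <- sol3$U[, 1][seq(2, mod3$n_dof, 3)]
  tip3 <- mean(uy[m3$nodes[, 3] > Lb - 1e-9])
  exact <- Pc * Lb^3 / (3 * 1000 * (W * H^3 / 12))
  err_c <- abs(tip3 - exact) / exact
  checks$cant <- data.frame(check = "cantilever_tip_deflection",
                            error = err_c, tol = tol_cantilever,
                            pass = err_c < tol_cantilever)
  ## rigid translation -> zero stress; load linearity
  ut <- rep(c(1, 2, 3), nrow(m2$nodes))
  vm0 <- max(element_von_mises(mod2, ut)$vm_stress)
  checks$rigid <- data.frame(check = "rigid_translation_zero_stress",
                             error = vm0, tol = 1e-8, pass = vm0 < 1e-8)
  sol2x <- solve_load_steps(mod2, K2, matrix(2 * f, ncol = 1))
  lin <- max(abs(sol2x$U[, 1] - 2 * sol$U[, 1])) /
    max(abs(sol$U[, 1]))
  checks$linear <- data.frame(check = "load_linearity", error = lin,
                              tol = 1e-9, pass = lin < 1e-9)
  do.call(rbind, checks)
}
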