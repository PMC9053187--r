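# Trial statistics: fatigue-limit exceedance tables, odds ratios (crude,
# Haldane-Anscombe penalised, cluster bootstrap), paired cluster-aware
# deltas, per-load-step ANOVA with Bonferroni correction, and the
# power/sample-size calculator.

#' Fatigue limit of the additively manufactured titanium alloy
#'
#' The experimentally established fatigue limit is 200 +/- 20 MPa; the
#' conservative lower bound, 180 MPa, is the default decision threshold.
#'
#' @param mean mean fatigue limit (MPa).
#' @param half_width experimental half-width (MPa).
#' @return list with mean, half_width and `flim = mean - half_width`.
#' @export
fatigue_limit <- function(mean = 200, half_width = 20) {
  flim <- mean - half_width
  stopifnot(flim > 0)
  list(mean = mean, half_width = half_width, flim = flim)
}

#' Fatigue-limit exceedance contingency table
#'
#' Counts, over solved load steps only, the steps whose maximum plate
#' von Mises stress lies above (N1) or below (N2) the fatigue limit, per
#' arm.  A stress exactly equal to the limit counts as exceedance
#' (conservative tie rule).  Per-patient counts are retained for
#' cluster-aware methods.
#'
#' @param results data.frame with columns arm, patient, stress, solved.
#' @param flim a [fatigue_limit()] (or numeric threshold in MPa).
#' @return object of class `exceedance_table`.
#' @export
exceedance_table <- function(results, flim = fatigue_limit()) {
  thr <- if (is.list(flim)) flim$flim else flim
  res <- results[results$solved & is.finite(results$stress), , drop = FALSE]
  if (nrow(res) == 0) stop("empty-table error: no solved load steps")
  res$exceed <- res$stress >= thr
  arms <- sort(unique(res$arm))
  cells <- lapply(arms, function(a) {
    r <- res[res$arm == a, ]
    c(N1 = sum(r$exceed), N2 = sum(!r$exceed))
  })
  names(cells) <- arms
  per_patient <- aggregate(cbind(N1 = res$exceed, N2 = !res$exceed),
                           by = list(arm = res$arm, patient = res$patient),
                           sum)
  structure(list(cells = cells, per_patient = per_patient, flim = thr),
            class = "exceedance_table")
}

#' Build an exceedance table from explicit cell counts
#'
#' Convenience constructor for published 2x2 tables (no patient detail).
#'
#' @param generic_below,generic_above,personalised_below,personalised_above
#'   cell counts (N2 and N1 per arm).
#' @return an `exceedance_table`.
#' @export
exceedance_table_from_counts <- function(generic_below, generic_above,
                                         personalised_below,
                                         personalised_above) {
  stopifnot(generic_below >= 0, generic_above >= 0,
            personalised_below >= 0, personalised_above >= 0)
  structure(list(cells = list(
    Generic = c(N1 = generic_above, N2 = generic_below),
    Personalised = c(N1 = personalised_above, N2 = personalised_below)),
    per_patient = NULL, flim = NA_real_),
    class = "exceedance_table")
}

#' Exceedance percentages (presentation precision)
#' @param tab an `exceedance_table`.
#' @return data.frame with arm, N1, N2, total, pct_above (1 d.p.).
#' @export
exceedance_percentages <- function(tab) {
  do.call(rbind, lapply(names(tab$cells), function(a) {
    cl <- tab$cells[[a]]
    tot <- sum(cl)
    data.frame(arm = a, N1 = cl[["N1"]], N2 = cl[["N2"]], total = tot,
               pct_above = round(100 * cl[["N1"]] / tot, 1),
               pct_below = round(100 * cl[["N2"]] / tot, 1))
  }))
}

#' Odds ratio of fatigue-limit exceedance (Personalised vs Generic)
#'
#' crude: `OR = (N1_P * N2_G) / (N2_P * N1_G)` with the Woolf
#' log-interval `exp(ln OR +/- 1.96 sqrt(sum 1/cell))`.
#' haldane_penalised: the same after adding 0.5 to all four cells
#' (Haldane-Anscombe correction; equivalent to Firth penalisation for a
#' single binary covariate).  Auto-selected when any cell is zero.
#' cluster_bootstrap: percentile interval of the crude OR over
#' patient-level resamples (requires per-patient counts).
#'
#' @param tab an `exceedance_table` with arms Generic and Personalised.
#' @param method "auto", "crude", "haldane_penalised" or
#'   "cluster_bootstrap".
#' @param B bootstrap resamples.
#' @param seed bootstrap seed (mandatory for cluster_bootstrap).
#' @return list: OR, ci_low, ci_high, p (two-sided Wald), method.
#' @export
odds_ratio <- function(tab, method = c("auto", "crude", "haldane_penalised",
                                       "cluster_bootstrap"),
                       B = 2000, seed = NULL) {
  method <- match.arg(method)
  g <- tab$cells$Generic; p <- tab$cells$Personalised
  if (is.null(g) || is.null(p))
    stop("odds_ratio needs Generic and Personalised arms")
  if ((g[["N1"]] == 0 && g[["N2"]] == 0) ||
        (p[["N1"]] == 0 && p[["N2"]] == 0))
    stop("undefined-OR error: an arm has two zero cells")
  if (method == "auto")
    method <- if (any(c(g, p) == 0)) "haldane_penalised" else "crude"
  if (method == "cluster_bootstrap")
    return(odds_ratio_cluster_bootstrap(tab, B, seed))
  cells <- c(g[["N1"]], g[["N2"]], p[["N1"]], p[["N2"]])
  if (method == "haldane_penalised") cells <- cells + 0.5
  or <- (cells[3] * cells[2]) / (cells[4] * cells[1])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(0.975)
  lo <- exp(log(or) - z * se); hi <- exp(log(or) + z * se)
  pval <- 2 * stats::pnorm(-abs(log(or) / se))
  list(OR = or, ci_low = lo, ci_high = hi, p = pval, method = method)
}

odds_ratio_cluster_bootstrap <- function(tab, B = 2000, seed = NULL) {
  if (is.null(tab$per_patient))
    stop("cluster_bootstrap requires per-patient counts")
  if (is.null(seed)) stop("cluster_bootstrap requires a seed")
  pp <- tab$per_patient
  pats <- unique(pp$patient)
  point <- odds_ratio(tab, "haldane_penalised")$OR
  ors <- with_seed(seed, vapply(seq_len(B), function(b) {
    draw <- sample(pats, length(pats), replace = TRUE)
    sub <- do.call(rbind, lapply(draw, function(pt)
      pp[pp$patient == pt, , drop = FALSE]))
    cl <- aggregate(sub[, c("N1", "N2")], by = list(arm = sub$arm), sum)
    g <- unlist(cl[cl$arm == "Generic", c("N1", "N2")]) + 0.5
    p <- unlist(cl[cl$arm == "Personalised", c("N1", "N2")]) + 0.5
    (p[["N1"]] * g[["N2"]]) / (p[["N2"]] * g[["N1"]])
  }, numeric(1)))
  qs <- quantile(ors, c(0.025, 0.975), names = FALSE)
  list(OR = point, ci_low = qs[1], ci_high = qs[2], p = NA_real_,
       method = "cluster_bootstrap")
}

#' Paired per-step deltas (Generic minus Personalised)
#'
#' Deltas are computed only on (patient, step) keys solved in both arms
#' (each virtual patient is their own control); the confidence interval
#' is a seeded percentile cluster bootstrap with patients as resampling
#' units.
#'
#' @param generic,personalised data.frames with columns patient, step,
#'   value, solved.
#' @param B bootstrap resamples (default 2000).
#' @param seed bootstrap seed.
#' @return list: deltas (data.frame), mean, ci_low, ci_high, n.
#' @export
paired_delta <- function(generic, personalised, B = 2000, seed = 1) {
  key <- function(d) paste(d$patient, d$step)
  g <- generic[generic$solved, ]; p <- personalised[personalised$solved, ]
  common <- intersect(key(g), key(p))
  if (!length(common)) stop("pairing error: no common solved steps")
  g <- g[match(common, key(g)), ]; p <- p[match(common, key(p)), ]
  deltas <- data.frame(patient = g$patient, step = g$step,
                       delta = g$value - p$value)
  pats <- unique(deltas$patient)
  boot <- with_seed(seed, vapply(seq_len(B), function(b) {
    draw <- sample(pats, length(pats), replace = TRUE)
    mean(unlist(lapply(draw, function(pt)
      deltas$delta[deltas$patient == pt])))
  }, numeric(1)))
  qs <- quantile(boot, c(0.025, 0.975), names = FALSE)
  list(deltas = deltas, mean = mean(deltas$delta),
       ci_low = qs[1], ci_high = qs[2], n = nrow(deltas))
}

#' Delta as a percentage of a reference maximum stress
#'
#' @param mean_delta mean paired difference (MPa).
#' @param reference_max relevant maximum stress (MPa, > 0).
#' @return percentage, rounded to 1 d.p.
#' @export
delta_fraction <- function(mean_delta, reference_max) {
  if (!is.numeric(reference_max) || reference_max <= 0)
    stop("input error: reference maximum must be positive")
  round(100 * abs(mean_delta) / reference_max, 1)
}

#' Per-load-step one-way ANOVA across screw configurations
#'
#' One F test per load step across the configuration groups; a step is
#' flagged significant iff p < alpha / n_steps (Bonferroni over the 15
#' steps, default alpha 0.05).
#'
#' @param df data.frame with columns step, config, value.
#' @param alpha family alpha (default 0.05).
#' @param n_tests Bonferroni divisor (default the number of steps).
#' @return data.frame per step: F, p, significant.
#' @export
screw_config_anova <- function(df, alpha = 0.05, n_tests = NULL) {
  steps <- sort(unique(df$step))
  if (is.null(n_tests)) n_tests <- length(steps)
  thr <- alpha / n_tests
  out <- do.call(rbind, lapply(steps, function(s) {
    d <- df[df$step == s & is.finite(df$value), ]
    if (length(unique(d$config)) < 2 ||
          any(table(d$config) < 2))
      stop("screw_config_anova: need >= 2 configs with >= 2 values each")
    gm <- tapply(d$value, d$config, mean)
    wv <- tapply(d$value, d$config, var)
    if (all(wv == 0) && max(gm) - min(gm) == 0)
      return(data.frame(step = s, F = 0, p = 1, significant = FALSE))
    a <- anova(lm(value ~ factor(config), data = d))
    data.frame(step = s, F = a$`F value`[1], p = a$`Pr(>F)`[1],
               significant = a$`Pr(>F)`[1] < thr)
  }))
  attr(out, "alpha_corrected") <- thr
  out
}

#' Two-sample normal-approximation sample size
#'
#' `n per arm = ceil(2 (z_{1-alpha/2} + z_{power})^2 / d^2)` with the
#' standardised detectable difference
#' `d = relative_difference * mean / sd`.  In the paired virtual-trial
#' design every patient serves in both arms, so the total equals the
#' per-arm figure.
#'
#' @param mean,sd outcome mean and SD (e.g. construct stiffness, N/mm).
#' @param relative_difference detectable difference as a fraction of the
#'   mean.
#' @param power desired power (0 < power < 1).
#' @param alpha two-sided alpha.
#' @return list: n_per_arm, n_total_paired, d.
#' @export
power_sample_size <- function(mean, sd, relative_difference = 0.2,
                              power = 0.8, alpha = 0.05) {
  stopifnot(sd > 0, power > 0, power < 1)
  d <- relative_difference * mean / sd
  if (d == 0) stop("infinite-n error: zero detectable difference")
  n <- ceiling(2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 / d^2)
  list(n_per_arm = n, n_total_paired = n, d = d)
}
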