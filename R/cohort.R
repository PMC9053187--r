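#' Cohort specification for the virtual HTO trial
#'
#' Defines the statistical targets of the virtual cohort: demographic
#' means and admissible ranges mirroring the realised study cohort
#' (ages 50--87 yr with mean 68, 54% female, body mass 68.8--121.4 kg with
#' mean 90.1, height 147--190 cm with mean 169), plus the geometry
#' parameters of the parametric proximal tibia.  Sampling is a truncated
#' normal per variable; the location parameter is solved so that the
#' *truncated* distribution has the target mean, and the standard
#' deviation is set so the printed range spans roughly mean +/- 2.5 SD.
#'
#' @param n number of virtual patients (default 28, the realised cohort).
#' @param seed master seed; the cohort is a pure function of (spec, seed).
#' @param age_mean,age_range target mean and admissible range for age (yr).
#' @param mass_mean,mass_range body mass targets (kg).
#' @param height_mean,height_range height targets (cm).
#' @param female_fraction probability of female sex.
#' @param geometry list of parametric tibia parameters, see
#'   [default_geometry_params()].
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 28, seed = 1,
                        age_mean = 68, age_range = c(50, 87),
                        mass_mean = 90.1, mass_range = c(68.8, 121.4),
                        height_mean = 169, height_range = c(147, 190),
                        female_fraction = 0.54,
                        geometry = default_geometry_params()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("invalid cohort spec: n must be a positive integer")
  stopifnot(age_range[1] < age_range[2], mass_range[1] < mass_range[2],
            height_range[1] < height_range[2],
            female_fraction >= 0, female_fraction <= 1)
  spec <- list(n = as.integer(n), seed = as.integer(seed),
               age_mean = age_mean, age_range = age_range,
               mass_mean = mass_mean, mass_range = mass_range,
               height_mean = height_mean, height_range = height_range,
               female_fraction = female_fraction,
               geometry = geometry)
  class(spec) <- "cohort_spec"
  spec
}

#' Default parametric tibia geometry parameters
#'
#' All lengths in mm unless noted.  The proximal tibia is an extruded,
#' tapered elliptical cross-section with a plateau cap; sizes scale
#' linearly with patient height.  The varus offset displaces the ankle
#' center medially so the pre-operative mechanical axis crosses the
#' plateau below 50% of its medial-to-lateral width (varus knee OA).
#'
#' @param plateau_width_frac plateau ML width as a fraction of height (mm/mm).
#' @param plateau_width_noise_sd multiplicative noise SD on the width.
#' @param ap_ratio plateau AP depth over ML width.
#' @param shaft_ratio shaft ML half-width over plateau ML half-width.
#' @param segment_length_frac meshed segment length as fraction of height.
#' @param tibia_length_frac,femur_length_frac full tibia/femur lengths as
#'   fractions of height (used to synthesize ankle and hip centers).
#' @param varus_offset_mean,varus_offset_sd medial ankle offset (mm),
#'   truncated at `varus_offset_min`.
#' @param hu_cortical_mean,hu_cortical_sd,hu_trabecular_mean,hu_trabecular_sd
#'   Hounsfield-unit field parameters for the cortical shell and the
#'   trabecular core.
#' @param cortical_radius_frac normalised radius beyond which an element
#'   belongs to the cortical shell.
#' @param nu,nv,nz structured-mesh resolution (cross-section cells and
#'   axial layers).
#' @return named list of geometry parameters.
#' @export
default_geometry_params <- function(plateau_width_frac = 0.045,
                                    plateau_width_noise_sd = 0.02,
                                    ap_ratio = 0.72,
                                    shaft_ratio = 0.45,
                                    segment_length_frac = 0.085,
                                    tibia_length_frac = 0.22,
                                    femur_length_frac = 0.245,
                                    varus_offset_mean = 29,
                                    varus_offset_sd = 6,
                                    varus_offset_min = 5,
                                    hu_cortical_mean = 1400,
                                    hu_cortical_sd = 100,
                                    hu_trabecular_mean = 300,
                                    hu_trabecular_sd = 80,
                                    cortical_radius_frac = 0.70,
                                    nu = 8, nv = 8, nz = 16) {
  as.list(environment())
}

#' Sample virtual patient demographics
#'
#' Draws `spec$n` patient records.  Each variable is a truncated-normal
#' draw inside the printed cohort range, centred so the truncated mean
#' matches the configured target; sex is Bernoulli(`female_fraction`).
#' Each patient consumes an independent RNG stream derived from the
#' master seed, so enlarging the cohort never changes existing patients.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns id, age, sex, mass_kg, height_cm, side.
#' @export
sample_demographics <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("invalid cohort spec")
  sdv <- function(rng) diff(rng) / 5      # range ~ mean +/- 2.5 SD
  mu_age <- truncnorm_mu_for_mean(spec$age_mean, sdv(spec$age_range),
                                  spec$age_range[1], spec$age_range[2])
  mu_mass <- truncnorm_mu_for_mean(spec$mass_mean, sdv(spec$mass_range),
                                   spec$mass_range[1], spec$mass_range[2])
  mu_h <- truncnorm_mu_for_mean(spec$height_mean, sdv(spec$height_range),
                                spec$height_range[1], spec$height_range[2])
  one <- function(i) {
    with_seed(derive_seed(spec$seed, i, salt = 11L), {
      data.frame(
        id = sprintf("P%04d", i),
        age = rtruncnorm(1, mu_age, sdv(spec$age_range),
                         spec$age_range[1], spec$age_range[2]),
        sex = if (runif(1) < spec$female_fraction) "F" else "M",
        mass_kg = rtruncnorm(1, mu_mass, sdv(spec$mass_range),
                             spec$mass_range[1], spec$mass_range[2]),
        height_cm = rtruncnorm(1, mu_h, sdv(spec$height_range),
                               spec$height_range[1], spec$height_range[2]),
        side = if (runif(1) < 0.5) "left" else "right",
        stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, lapply(seq_len(spec$n), one))
  rownames(out) <- NULL
  validate_patients(out, spec)
  out
}

validate_patients <- function(df, spec) {
  stopifnot(!anyDuplicated(df$id),
            all(df$age >= spec$age_range[1] & df$age <= spec$age_range[2]),
            all(df$mass_kg >= spec$mass_range[1] &
                  df$mass_kg <= spec$mass_range[2]),
            all(df$height_cm >= spec$height_range[1] &
                  df$height_cm <= spec$height_range[2]),
            all(df$sex %in% c("F", "M")),
            all(df$side %in% c("left", "right")))
  invisible(df)
}
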