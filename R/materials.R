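# CT Hounsfield units -> bone elastic modulus, and healing-stage gap
# material.  The density calibration is the composed affine/power law
#   rho_CT  = -0.00393573 + 0.000791701 * HU        (g/cm^3)
#   rho_Ash =  0.079 + 0.877 * rho_CT               (g/cm^3)
#   E       =  14664 * rho_Ash^1.49                 (MPa)
# with negative ash densities clamped before the fractional power and a
# 1 MPa floor so assembled stiffness matrices stay positive definite.

#' Density-modulus law parameters
#'
#' @param a0,a1 HU to CT-density affine coefficients (g/cm^3, g/cm^3 per HU).
#' @param b0,b1 CT-density to ash-density affine coefficients.
#' @param c,p ash-density to modulus power-law coefficient (MPa) and exponent.
#' @param E_floor minimum bone modulus (MPa).
#' @param n_bins_proximal,n_bins_distal modulus bins per fragment.
#' @param nu Poisson ratio assigned to all bone and gap material.
#' @return object of class `density_modulus_law`.
#' @export
density_modulus_law <- function(a0 = -0.00393573, a1 = 0.000791701,
                                b0 = 0.079, b1 = 0.877,
                                c = 14664, p = 1.49, E_floor = 1,
                                n_bins_proximal = 240, n_bins_distal = 450,
                                nu = 0.3) {
  stopifnot(c > 0, p > 0, E_floor > 0)
  structure(as.list(environment()), class = "density_modulus_law")
}

#' Hounsfield units to CT density
#' @param hu Hounsfield units (finite).
#' @param law a [density_modulus_law()].
#' @return CT density in g/cm^3 (may be negative; clamping happens at the
#'   modulus step).
#' @export
hu_to_ct_density <- function(hu, law = density_modulus_law()) {
  if (any(!is.finite(hu))) stop("input error: non-finite HU")
  law$a0 + law$a1 * hu
}

#' CT density to ash density
#' @param rho_ct CT density (g/cm^3).
#' @param law a [density_modulus_law()].
#' @return ash density in g/cm^3.
#' @export
ct_to_ash_density <- function(rho_ct, law = density_modulus_law()) {
  if (any(!is.finite(rho_ct))) stop("input error: non-finite CT density")
  law$b0 + law$b1 * rho_ct
}

#' Ash density to Young's modulus
#' @param rho_ash ash density (g/cm^3).
#' @param law a [density_modulus_law()].
#' @return Young's modulus in MPa (clamped below at `E_floor`).
#' @export
ash_to_modulus <- function(rho_ash, law = density_modulus_law()) {
  if (any(!is.finite(rho_ash))) stop("input error: non-finite ash density")
  pmax(law$c * pmax(rho_ash, 0)^law$p, law$E_floor)
}

#' Full HU to modulus mapping
#' @param hu Hounsfield units.
#' @param law a [density_modulus_law()].
#' @return Young's modulus in MPa.
#' @export
hu_to_modulus <- function(hu, law = density_modulus_law()) {
  ash_to_modulus(ct_to_ash_density(hu_to_ct_density(hu, law), law), law)
}

#' Healing stages of the osteotomy gap
#'
#' HS2/HS3/HS4 are 2, 6 and 12 weeks post-operative with gap tissue
#' moduli of 1, 28 and 528 MPa.  HS1 (immediately post-operative) exists
#' as a configuration label only and is never simulated.
#'
#' @param id one of "HS2", "HS3", "HS4".
#' @return list with id, weeks, gap modulus (MPa).
#' @export
healing_stage <- function(id = c("HS2", "HS3", "HS4")) {
  id <- match.arg(id)
  weeks <- c(HS2 = 2, HS3 = 6, HS4 = 12)[[id]]
  gap_E <- c(HS2 = 1, HS3 = 28, HS4 = 528)[[id]]
  list(id = id, weeks = weeks, gap_modulus = gap_E)
}

# quantile binning: replace each value by the mean of its quantile bin
bin_by_quantile <- function(x, n_bins) {
  if (length(x) == 0) return(x)
  if (n_bins <= 1) return(rep(mean(x), length(x)))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) return(x)
  idx <- cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  means <- tapply(x, idx, mean)
  as.numeric(means[as.character(idx)])
}

#' Assign element materials for one healing stage
#'
#' Bone elements (proximal, distal, cortical hinge) get the HU-mapped
#' modulus, quantile-binned per fragment (default 240 proximal / 450
#' distal bins, bin value = bin mean); gap elements get the stage
#' modulus.
#'
#' @param ost an `osteotomized_tibia` carrying an HU field.
#' @param stage a [healing_stage()] (or its id string).
#' @param law a [density_modulus_law()].
#' @return object of class `material_field`: per-element `E` (MPa),
#'   `nu`, unbinned `E_raw`, and the element `set` labels.
#' @export
assign_materials <- function(ost, stage = healing_stage("HS2"),
                             law = density_modulus_law()) {
  if (is.character(stage)) stage <- healing_stage(stage)
  labels <- ost$labels
  if (is.null(ost$hu) || length(ost$hu) != length(labels))
    stop("assignment error: HU field missing or wrong length")
  E_raw <- hu_to_modulus(ost$hu, law)
  E <- E_raw
  prox <- labels %in% c("proximal", "cortical_hinge")
  dist <- labels == "distal"
  E[prox] <- bin_by_quantile(E_raw[prox], law$n_bins_proximal)
  E[dist] <- bin_by_quantile(E_raw[dist], law$n_bins_distal)
  gap <- labels == "gap"
  E[gap] <- stage$gap_modulus
  E <- pmax(E, law$E_floor)
  structure(list(E = E, nu = rep(law$nu, length(E)), E_raw = E_raw,
                 set = labels, stage = stage$id, law = law),
            class = "material_field")
}
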