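#' Laser configuration
#'
#' Bundles the laser delivery parameters used throughout the analysis:
#' modality (single ultra-short pulse, USP, or the dual-pulse Auto-SWEEPS
#' scheme, ASW), per-pulse energy, repetition rate, delivery-fiber diameter,
#' and the inter-pulse delay grid swept by the dual-pulse modality.
#'
#' @param modality `"USP"` (single pulse) or `"ASW"` (dual pulse with swept
#'   inter-pulse delay).
#' @param pulse_energy_mJ Per-pulse energy in millijoule. The experiments use
#'   10, 20 or 30 mJ; other positive values are accepted.
#' @param repetition_rate_Hz Pulse (or pulse-pair) repetition rate.
#' @param fiber_diameter_um Core diameter of the delivery fiber in micrometre.
#' @param t_d_range_us Two-element vector, inclusive range of the dual-pulse
#'   delay sweep in microseconds.
#' @param t_d_step_us Delay-sweep increment in microseconds.
#' @param treatment_time_s Total treatment time in seconds.
#' @return A list of class `laser_config`.
#' @export
laser_config <- function(modality = c("USP", "ASW"),
                         pulse_energy_mJ = 20,
                         repetition_rate_Hz = 15,
                         fiber_diameter_um = 400,
                         t_d_range_us = c(200, 650),
                         t_d_step_us = 10,
                         treatment_time_s = 10) {
  modality <- match.arg(modality)
  stopifnot_scalar(pulse_energy_mJ, "pulse_energy_mJ", positive = TRUE)
  stopifnot_scalar(repetition_rate_Hz, "repetition_rate_Hz", positive = TRUE)
  stopifnot_scalar(fiber_diameter_um, "fiber_diameter_um", positive = TRUE)
  stopifnot_scalar(t_d_step_us, "t_d_step_us", positive = TRUE)
  stopifnot_scalar(treatment_time_s, "treatment_time_s", positive = TRUE)
  if (length(t_d_range_us) != 2L || t_d_range_us[2] <= t_d_range_us[1]) {
    stop("'t_d_range_us' must be an increasing pair", call. = FALSE)
  }
  structure(list(
    modality = modality,
    pulse_energy_mJ = pulse_energy_mJ,
    repetition_rate_Hz = repetition_rate_Hz,
    fiber_diameter_um = fiber_diameter_um,
    t_d_range_us = as.numeric(t_d_range_us),
    t_d_step_us = t_d_step_us,
    treatment_time_s = treatment_time_s
  ), class = "laser_config")
}

#' Material configuration for the soft pocket wall
#'
#' The soft plate of the zero-gap pocket model is characterized by its
#' storage modulus G' (elastic part of the complex shear modulus, a proxy for
#' gingival stiffness) and its arithmetic-mean surface roughness Ra. The
#' Young's modulus is derived with the elastomer approximation E = 3 G'.
#'
#' @param storage_modulus_G_prime_kPa Storage modulus G' in kilopascal.
#' @param roughness_Ra_um Arithmetic-mean roughness Ra in micrometre.
#' @return A list of class `material_config` with the derived
#'   `youngs_modulus_E_kPa`.
#' @export
material_config <- function(storage_modulus_G_prime_kPa, roughness_Ra_um = 0.1) {
  stopifnot_scalar(storage_modulus_G_prime_kPa, "storage_modulus_G_prime_kPa",
                   nonneg = TRUE)
  stopifnot_scalar(roughness_Ra_um, "roughness_Ra_um", nonneg = TRUE)
  structure(list(
    storage_modulus_G_prime_kPa = storage_modulus_G_prime_kPa,
    youngs_modulus_E_kPa = youngs_from_storage(storage_modulus_G_prime_kPa),
    roughness_Ra_um = roughness_Ra_um
  ), class = "material_config")
}

#' Fluence at the fiber tip
#'
#' Per-pulse fluence delivered through a flat-ended fiber, i.e. the pulse
#' energy divided by the fiber cross-section:
#' F = E / (pi r^2) with E in joule and r in centimetre.
#'
#' @param energy_mJ Pulse energy in millijoule.
#' @param fiber_diameter_um Fiber core diameter in micrometre.
#' @return Fluence in J/cm^2.
#' @examples
#' fluence_J_cm2(10, 400)  # ~ 8 J/cm^2
#' fluence_J_cm2(30, 400)  # ~ 24 J/cm^2
#' @export
fluence_J_cm2 <- function(energy_mJ, fiber_diameter_um) {
  stopifnot_scalar(energy_mJ, "energy_mJ", positive = TRUE)
  stopifnot_scalar(fiber_diameter_um, "fiber_diameter_um", positive = TRUE)
  radius_cm <- fiber_diameter_um / 2 * 1e-4
  (energy_mJ / 1000) / (pi * radius_cm^2)
}

#' Young's modulus from storage modulus
#'
#' Elastomer approximation E = 3 G', valid for nearly incompressible
#' rubber-like materials (Poisson ratio close to 0.5).
#'
#' @param G_prime_kPa Storage modulus G' in kilopascal (>= 0).
#' @return Young's modulus E in kilopascal.
#' @examples
#' youngs_from_storage(14)  # 42
#' youngs_from_storage(29)  # 87
#' @export
youngs_from_storage <- function(G_prime_kPa) {
  if (any(!is.finite(G_prime_kPa)) || any(G_prime_kPa < 0)) {
    stop("'G_prime_kPa' must be non-negative", call. = FALSE)
  }
  3 * G_prime_kPa
}

#' Energy delivered per dual-pulse pair
#'
#' The dual-pulse (ASW) modality fires two pulses of equal energy, so each
#' pair delivers twice the per-pulse energy.
#'
#' @param per_pulse_mJ Energy of each pulse in millijoule.
#' @return Total energy per pulse pair in millijoule.
#' @export
asw_pair_energy <- function(per_pulse_mJ) {
  stopifnot_scalar(per_pulse_mJ, "per_pulse_mJ", positive = TRUE)
  2 * per_pulse_mJ
}

#' Inter-pulse delay grid
#'
#' Inclusive arithmetic sequence of dual-pulse delays swept by the ASW
#' modality (default 200, 210, ..., 650 microseconds).
#'
#' @param cfg A [laser_config()].
#' @return Numeric vector of delays in microseconds.
#' @export
delay_grid <- function(cfg = laser_config()) {
  stopifnot(inherits(cfg, "laser_config"))
  seq(cfg$t_d_range_us[1], cfg$t_d_range_us[2], by = cfg$t_d_step_us)
}
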