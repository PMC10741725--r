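# Physical constants, SI unless noted. Interfaces use the bench units the
# numbers are quoted in (g mol^-1, g cm^-3, nm, nm^2, mg m^-2, mV, elementary
# charges); conversion to SI happens inside operations only.

.N_AV <- 6.02214076e23     # Avogadro number, mol^-1
.K_B <- 1.380649e-23       # Boltzmann constant, J K^-1
.EPS0 <- 8.8541878128e-12  # vacuum permittivity, F m^-1

# Hydrodynamic diameter of a doublet of touching equal spheres relative to the
# monomer diameter (low-Reynolds-number mobility result).
.DIMER_HYDRO_FACTOR <- 1.39

# Jamming coverage of random sequential adsorption of equal hard disks on a
# plane; reproduced independently by estimate_jamming_coverage().
.THETA_RSA_DISKS <- 0.547

# Dynamic viscosity of water, Pa s, log-linearly interpolated in temperature
# between three anchor points spanning 273-373 K. Good to ~2% near 298 K,
# which is where the default conditions live; user-supplied viscosity always
# overrides.
.WATER_VISC_T <- c(273.15, 298.15, 373.15)
.WATER_VISC_ETA <- c(1.787e-3, 8.90e-4, 2.818e-4)

#' Dynamic viscosity of water
#'
#' Log-linear interpolation of the dynamic viscosity of pure water between
#' tabulated anchors at 273.15, 298.15 and 373.15 K. Used as the default
#' solvent viscosity when [solution_conditions()] is created without one.
#'
#' @param temperature Absolute temperature in K (scalar or vector), within
#'   273.15--373.15.
#' @return Dynamic viscosity in Pa s.
#' @examples
#' water_viscosity(298.15) # 8.9e-4 Pa s
#' @export
water_viscosity <- function(temperature) {
  if (any(!is.finite(temperature)) || any(temperature < .WATER_VISC_T[1]) ||
      any(temperature > .WATER_VISC_T[3])) {
    stop("temperature must lie within 273.15-373.15 K for the water viscosity table",
         call. = FALSE)
  }
  exp(approx(.WATER_VISC_T, log(.WATER_VISC_ETA), xout = temperature)$y)
}

.check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("%s must be a positive finite number", what), call. = FALSE)
  }
  invisible(x)
}
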