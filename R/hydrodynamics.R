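#' Solution conditions
#'
#' Temperature, viscosity and electrolyte metadata shared by the
#' hydrodynamic, kinetic and electrokinetic calculations. When `viscosity` is
#' omitted it defaults to the water value at `temperature` via
#' [water_viscosity()]; a user-supplied value always wins. `ionic_strength`
#' and `ph` are carried as metadata only -- the Stokes-Einstein relation does
#' not depend on them.
#'
#' @param temperature Absolute temperature, K. Default 298.15.
#' @param viscosity Dynamic viscosity, Pa s; optional.
#' @param ionic_strength Ionic strength, mol L^-1 (metadata). Default 0.01.
#' @param ph Solution pH (metadata). Default 7.4.
#' @return An object of class `solution_conditions`.
#' @export
solution_conditions <- function(temperature = 298.15, viscosity = NULL,
                                ionic_strength = 0.01, ph = 7.4) {
  .check_positive(temperature, "temperature")
  if (!is.null(viscosity)) .check_positive(viscosity, "viscosity")
  if (!is.numeric(ionic_strength) || ionic_strength < 0) {
    stop("ionic_strength must be >= 0", call. = FALSE)
  }
  structure(list(temperature = temperature, viscosity = viscosity,
                 ionic_strength = ionic_strength, ph = ph),
            class = "solution_conditions")
}

.resolve_viscosity <- function(cond) {
  if (!is.null(cond$viscosity)) cond$viscosity else water_viscosity(cond$temperature)
}

#' @export
print.solution_conditions <- function(x, ...) {
  cat(sprintf("<solution_conditions> T = %g K, eta = %.3g Pa s%s, I = %g M, pH %g\n",
              x$temperature, .resolve_viscosity(x),
              if (is.null(x$viscosity)) " (water default)" else "",
              x$ionic_strength, x$ph))
  invisible(x)
}

#' Hydrodynamic diameter from a diffusion coefficient
#'
#' Stokes-Einstein relation `d_H = k T / (3 pi eta D)`. The hydrodynamic
#' diameter is the size of the sphere diffusing at the measured rate, and --
#' unlike `D` itself -- is independent of temperature and solvent viscosity.
#'
#' @param diffusion Translational diffusion coefficient, m^2 s^-1.
#' @param cond [solution_conditions()] supplying temperature and viscosity.
#' @return Hydrodynamic diameter in nm.
#' @examples
#' hydrodynamic_diameter(1.33e-10, solution_conditions(298, viscosity = 8.9e-4))
#' @export
hydrodynamic_diameter <- function(diffusion, cond = solution_conditions()) {
  .check_positive(diffusion, "diffusion")
  eta <- .resolve_viscosity(cond)
  .K_B * cond$temperature / (3 * pi * eta * diffusion) * 1e9
}

#' Diffusion coefficient from a hydrodynamic diameter
#'
#' Inverse Stokes-Einstein relation, `D = k T / (3 pi eta d_H)`.
#'
#' @param d_h Hydrodynamic diameter, nm.
#' @param cond [solution_conditions()] supplying temperature and viscosity.
#' @return Diffusion coefficient in m^2 s^-1.
#' @export
diffusion_coefficient <- function(d_h, cond = solution_conditions()) {
  .check_positive(d_h, "d_h")
  eta <- .resolve_viscosity(cond)
  .K_B * cond$temperature / (3 * pi * eta * d_h * 1e-9)
}
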