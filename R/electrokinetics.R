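#' Streaming-potential data set
#'
#' Streaming potentials measured at several driving pressure differences in a
#' parallel-plate cell, together with the electrolyte conductivity and
#' solution conditions needed for the Smoluchowski conversion.
#'
#' @param pressure_differences Hydrostatic pressure differences, Pa; at least
#'   two distinct values.
#' @param streaming_potentials Streaming potentials, V; same length.
#' @param conductivity Bulk electrolyte conductivity, S m^-1.
#' @param cond [solution_conditions()].
#' @return An object of class `streaming_potential_data`.
#' @export
streaming_potential_data <- function(pressure_differences, streaming_potentials,
                                     conductivity, cond = solution_conditions()) {
  p <- as.numeric(pressure_differences)
  u <- as.numeric(streaming_potentials)
  if (length(p) != length(u)) {
    stop("pressure and potential vectors must have the same length", call. = FALSE)
  }
  if (length(unique(p)) < 2L) {
    stop("need at least 2 distinct pressure differences", call. = FALSE)
  }
  .check_positive(conductivity, "conductivity")
  structure(list(pressure_differences = p, streaming_potentials = u,
                 conductivity = conductivity, cond = cond),
            class = "streaming_potential_data")
}

#' Read streaming-potential data from CSV
#'
#' CSV columns: `pressure_pa,potential_v`.
#'
#' @param path CSV path.
#' @param conductivity Bulk conductivity, S m^-1.
#' @param cond [solution_conditions()].
#' @return A [streaming_potential_data()].
#' @export
read_streaming_potential <- function(path, conductivity,
                                     cond = solution_conditions()) {
  if (!file.exists(path)) stop("data file not found: ", path, call. = FALSE)
  df <- read.csv(path)
  if (!all(c("pressure_pa", "potential_v") %in% names(df))) {
    stop("streaming-potential CSV must have columns pressure_pa, potential_v",
         call. = FALSE)
  }
  streaming_potential_data(df$pressure_pa, df$potential_v, conductivity, cond)
}

#' @rdname read_streaming_potential
#' @param data A [streaming_potential_data()] to write.
#' @export
write_streaming_potential <- function(data, path) {
  write.csv(data.frame(pressure_pa = data$pressure_differences,
                       potential_v = data$streaming_potentials),
            path, row.names = FALSE)
  invisible(path)
}

#' Slope of streaming potential versus pressure
#'
#' Least-squares slope (with intercept) of the streaming potential against
#' the driving pressure difference, `dU_s/dDp`, the quantity the Smoluchowski
#' relation converts to a zeta potential.
#'
#' @param data A [streaming_potential_data()].
#' @return A list: `slope` (V Pa^-1), `intercept` (V), `r_squared`, `stderr`.
#' @export
streaming_slope <- function(data) {
  stopifnot(inherits(data, "streaming_potential_data"))
  fit <- .ols_line(data$pressure_differences, data$streaming_potentials)
  list(slope = fit$slope, intercept = fit$intercept,
       r_squared = fit$r_squared, stderr = fit$stderr_slope)
}

#' Zeta potential by the Smoluchowski relation
#'
#' Converts a streaming-potential slope to the zeta potential of the channel
#' walls: `zeta = eta * lambda / (eps_r * eps_0) * dU_s/dDp`, with `eta` the
#' solution viscosity and `lambda` the bulk electrolyte conductivity. The
#' sign of zeta follows the sign of the slope. No surface-conductance or
#' cell-geometry corrections are applied.
#'
#' @param slope Streaming-potential slope, V Pa^-1 (or the list returned by
#'   [streaming_slope()]).
#' @param conductivity Bulk conductivity, S m^-1.
#' @param cond [solution_conditions()] resolving viscosity and temperature.
#' @param relative_permittivity Relative permittivity of the medium.
#'   Default 78.5 (water at 298 K).
#' @return Zeta potential in mV.
#' @examples
#' smoluchowski_zeta(1e-8, conductivity = 0.12,
#'                   cond = solution_conditions(298, viscosity = 8.9e-4))
#' @export
smoluchowski_zeta <- function(slope, conductivity, cond = solution_conditions(),
                              relative_permittivity = 78.5) {
  if (is.list(slope)) slope <- slope$slope
  .check_positive(conductivity, "conductivity")
  .check_positive(relative_permittivity, "relative_permittivity")
  eta <- .resolve_viscosity(cond)
  eta * conductivity * slope / (relative_permittivity * .EPS0) * 1e3
}

#' Zeta potential directly from a streaming-potential data set
#'
#' Convenience composition of [streaming_slope()] and [smoluchowski_zeta()].
#'
#' @param data A [streaming_potential_data()].
#' @param relative_permittivity Relative permittivity. Default 78.5.
#' @return A list: `zeta_mV`, plus the slope fit fields.
#' @export
zeta_from_streaming <- function(data, relative_permittivity = 78.5) {
  fit <- streaming_slope(data)
  zeta <- smoluchowski_zeta(fit$slope, data$conductivity, data$cond,
                            relative_permittivity)
  c(list(zeta_mV = zeta), fit)
}
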