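#' Generate a synthetic flow-cell adsorption trace
#'
#' Builds a [kinetic_trace()] with a transport-limited rise to a plateau,
#' followed at `rinse_time` by an exponential partial desorption toward the
#' irreversible coverage, plus additive iid Gaussian noise. Two rise shapes
#' are available; both have initial derivative exactly `slope` and plateau
#' exactly `plateau`, the only two features the analysis consumes:
#' \describe{
#'   \item{`"linear"` (default)}{`Gamma(t) = min(slope * t, plateau)` -- the
#'     linear-rise-then-plateau shape transport-limited adsorption actually
#'     shows, and the shape consistent with an ordinary least-squares slope
#'     fit.}
#'   \item{`"exponential"`}{`Gamma(t) = plateau * (1 - exp(-slope t /
#'     plateau))` -- a smooth saturating alternative.}
#' }
#'
#' @param slope Initial adsorption slope, mg m^-2 s^-1.
#' @param plateau Adsorption plateau coverage, mg m^-2.
#' @param rinse_time Rinse (desorption) onset, s. Default 1800.
#' @param irreversible Coverage retained after rinsing, mg m^-2; must not
#'   exceed `plateau`. Default 0.8.
#' @param desorption_rate First-order desorption rate toward the
#'   irreversible coverage, s^-1. Default 0.01 (a visually step-like rinse).
#' @param noise_sd Gaussian noise standard deviation, mg m^-2. Default 0.
#' @param dt Sampling interval, s. Default 1.
#' @param duration Trace length, s. Default 3600.
#' @param seed Optional integer seed (calls `set.seed`) for bit-reproducible
#'   noise.
#' @param shape Rise shape, `"linear"` or `"exponential"`.
#' @param bulk_concentration,flow_rate Metadata stored on the trace.
#'   Defaults 2 mg L^-1 and 1.1e-3 cm^3 s^-1.
#' @return A [kinetic_trace()] with the generating parameters attached as
#'   attribute `"truth"`.
#' @examples
#' tr <- generate_owls_trace(slope = 2.2e-3, plateau = 1, noise_sd = 0.01, seed = 1)
#' @export
generate_owls_trace <- function(slope = 2.2e-3, plateau = 1.0, rinse_time = 1800,
                                irreversible = 0.8, desorption_rate = 0.01,
                                noise_sd = 0, dt = 1, duration = 3600,
                                seed = NULL, shape = c("linear", "exponential"),
                                bulk_concentration = 2, flow_rate = 1.1e-3) {
  shape <- match.arg(shape)
  .check_positive(slope, "slope")
  .check_positive(plateau, "plateau")
  if (irreversible < 0 || irreversible > plateau) {
    stop("irreversible coverage must lie in [0, plateau]", call. = FALSE)
  }
  times <- seq(0, duration, by = dt)
  rise <- switch(shape,
    linear = pmin(slope * times, plateau),
    exponential = plateau * (1 - exp(-slope * times / plateau)))
  gamma <- rise
  post <- times >= rinse_time
  if (any(post)) {
    g_rinse <- switch(shape,
      linear = min(slope * rinse_time, plateau),
      exponential = plateau * (1 - exp(-slope * rinse_time / plateau)))
    gamma[post] <- irreversible +
      (g_rinse - irreversible) * exp(-desorption_rate * (times[post] - rinse_time))
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    gamma <- gamma + rnorm(length(gamma), sd = noise_sd)
  }
  tr <- kinetic_trace(times, gamma, bulk_concentration = bulk_concentration,
                      flow_rate = flow_rate, adsorption_start = 0,
                      rinse_start = if (any(post)) rinse_time else NULL)
  attr(tr, "truth") <- list(slope = slope, plateau = plateau,
                            irreversible = irreversible,
                            desorption_rate = desorption_rate, shape = shape)
  tr
}

#' Generate a synthetic multi-overtone QCM-D trace
#'
#' Builds a [qcm_trace()] that is the exact functional inverse of the
#' Sauerbrey + hydration analysis: given a dry coverage profile `Gamma(t)`,
#' each overtone `n` carries
#' `df_n(t) = -n * Gamma(t) / ((1 - H) * C_Q) + drift * t + noise`,
#' with noise independent across overtones. At zero noise and drift,
#' [analyze_qcm_trace()] recovers the dry plateau exactly.
#'
#' @param profile A [kinetic_trace()] giving the *dry* coverage profile, or
#'   `NULL` to generate one internally from `...` via
#'   [generate_owls_trace()] (noiseless).
#' @param hydration Hydration correction H in `[0, 1)`. Default 0.5.
#' @param overtones Overtone numbers. Default `c(3, 5, 7, 9, 11)`.
#' @param noise_sd Frequency noise standard deviation, Hz. Default 0.
#' @param drift Linear baseline drift, Hz s^-1. Default 0.
#' @param seed Optional integer seed.
#' @param constants A [qcm_constants()] (its hydration field is ignored in
#'   favour of `hydration`).
#' @param ... Passed to [generate_owls_trace()] when `profile` is `NULL`.
#' @return A [qcm_trace()] with attribute `"truth"` recording the dry
#'   profile parameters and H.
#' @export
generate_qcm_trace <- function(profile = NULL, hydration = 0.5,
                               overtones = c(3, 5, 7, 9, 11), noise_sd = 0,
                               drift = 0, seed = NULL,
                               constants = qcm_constants(), ...) {
  if (hydration < 0 || hydration >= 1) {
    stop("hydration must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(profile)) profile <- generate_owls_trace(..., noise_sd = 0)
  stopifnot(inherits(profile, "kinetic_trace"))
  times <- profile$times
  wet <- profile$coverage / (1 - hydration)
  if (!is.null(seed)) set.seed(seed)
  shifts <- vapply(overtones, function(n) {
    df <- -n * wet / constants$sauerbrey + drift * times
    if (noise_sd > 0) df <- df + rnorm(length(df), sd = noise_sd)
    df
  }, numeric(length(times)))
  tr <- qcm_trace(times, shifts, overtones, rinse_start = profile$rinse_start)
  attr(tr, "truth") <- c(attr(profile, "truth"),
                         list(hydration = hydration, drift = drift))
  tr
}

#' Generate a stationary dynamic-light-scattering size series
#'
#' Emulates repeated sizing of a stable solution containing several
#' populations (e.g. monomer and dimer peaks): at each time point one noisy
#' diameter draw per population, stationary by construction.
#'
#' @param diameters Population mean hydrodynamic diameters, nm. Default
#'   `c(3.7, 5.4)` (monomer and dimer of a small globular protein).
#' @param sd Measurement noise standard deviation, nm. Default 0.15.
#' @param times Measurement time points, min. Default
#'   `c(0, 30, 60, 180, 360, 720, 1440)`.
#' @param seed Optional integer seed.
#' @return `data.frame(time_min, population, diameter_nm)`.
#' @export
generate_dls_series <- function(diameters = c(3.7, 5.4), sd = 0.15,
                                times = c(0, 30, 60, 180, 360, 720, 1440),
                                seed = NULL) {
  .check_positive(diameters, "diameters")
  if (!is.null(seed)) set.seed(seed)
  out <- expand.grid(time_min = times, population = seq_along(diameters))
  out <- out[order(out$time_min, out$population), ]
  mu <- diameters[out$population]
  out$diameter_nm <- mu + if (sd > 0) rnorm(nrow(out), sd = sd) else 0
  rownames(out) <- NULL
  out
}

#' Generate synthetic streaming-potential data
#'
#' Exact inverse of the Smoluchowski conversion: for each pressure
#' difference, `U_s = Dp * zeta * eps_r * eps_0 / (eta * lambda) + noise`.
#' At zero noise, [zeta_from_streaming()] returns `zeta` exactly.
#'
#' @param zeta Wall zeta potential, mV. Default 20 (a cationic-polymer-layer
#'   scale).
#' @param pressures Pressure differences, Pa; at least 2. Default four
#'   values 5--20 kPa.
#' @param conductivity Bulk conductivity, S m^-1. Default 0.12 (about 0.01 M
#'   NaCl).
#' @param cond [solution_conditions()].
#' @param relative_permittivity Relative permittivity. Default 78.5.
#' @param noise_sd Potential noise standard deviation, V. Default 0.
#' @param seed Optional integer seed.
#' @return A [streaming_potential_data()] with attribute `"truth"`.
#' @export
generate_streaming_potential <- function(zeta = 20,
                                         pressures = c(5e3, 1e4, 1.5e4, 2e4),
                                         conductivity = 0.12,
                                         cond = solution_conditions(),
                                         relative_permittivity = 78.5,
                                         noise_sd = 0, seed = NULL) {
  if (length(pressures) < 2L) stop("need at least 2 pressures", call. = FALSE)
  eta <- .resolve_viscosity(cond)
  u <- pressures * (zeta * 1e-3) * relative_permittivity * .EPS0 /
    (eta * conductivity)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    u <- u + rnorm(length(u), sd = noise_sd)
  }
  out <- streaming_potential_data(pressures, u, conductivity, cond)
  attr(out, "truth") <- list(zeta_mV = zeta,
                             relative_permittivity = relative_permittivity)
  out
}
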