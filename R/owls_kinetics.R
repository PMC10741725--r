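#' Flow-cell adsorption kinetic trace
#'
#' Time series of surface coverage from a flow-cell experiment (e.g. OWLS),
#' with phase markers and the experiment metadata the transport-limited
#' analysis needs.
#'
#' @param times Time points, s; strictly increasing.
#' @param coverage Surface coverage, mg m^-2; same length, finite.
#' @param bulk_concentration Bulk protein concentration, mg L^-1.
#' @param flow_rate Volumetric flow rate, cm^3 s^-1.
#' @param adsorption_start Time at which protein enters the cell, s.
#' @param rinse_start Optional time at which the rinse (desorption run)
#'   begins, s; must exceed `adsorption_start`.
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, coverage, bulk_concentration, flow_rate,
                          adsorption_start = 0, rinse_start = NULL) {
  times <- as.numeric(times)
  coverage <- as.numeric(coverage)
  if (length(times) != length(coverage)) {
    stop("times and coverage must have the same length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(coverage))) {
    stop("coverage must be finite", call. = FALSE)
  }
  .check_positive(bulk_concentration, "bulk_concentration")
  .check_positive(flow_rate, "flow_rate")
  if (!is.null(rinse_start) && rinse_start <= adsorption_start) {
    stop("rinse_start must exceed adsorption_start", call. = FALSE)
  }
  structure(
    list(times = times, coverage = coverage,
         bulk_concentration = bulk_concentration, flow_rate = flow_rate,
         adsorption_start = adsorption_start, rinse_start = rinse_start),
    class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> %d samples, t = %g..%g s\n",
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  c_b = %g mg L^-1, Q = %g cm^3 s^-1, adsorption from %g s%s\n",
              x$bulk_concentration, x$flow_rate, x$adsorption_start,
              if (is.null(x$rinse_start)) "" else
                sprintf(", rinse from %g s", x$rinse_start)))
  invisible(x)
}

#' Read/write a kinetic trace as CSV
#'
#' The CSV carries `time_s,coverage_mg_m2`; phase markers and metadata live in
#' a JSON sidecar (same path with `.json` appended) or are passed as
#' arguments, which take precedence.
#'
#' @param path CSV path.
#' @param bulk_concentration,flow_rate,adsorption_start,rinse_start Metadata;
#'   read from the sidecar when omitted.
#' @return A [kinetic_trace()].
#' @export
read_kinetic_trace <- function(path, bulk_concentration = NULL, flow_rate = NULL,
                               adsorption_start = NULL, rinse_start = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  df <- read.csv(path)
  if (!all(c("time_s", "coverage_mg_m2") %in% names(df))) {
    stop("kinetic trace CSV must have columns time_s, coverage_mg_m2",
         call. = FALSE)
  }
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  pick <- function(arg, name, default = NULL) {
    if (!is.null(arg)) arg else if (!is.null(meta[[name]])) meta[[name]] else default
  }
  kinetic_trace(df$time_s, df$coverage_mg_m2,
                bulk_concentration = pick(bulk_concentration, "bulk_concentration"),
                flow_rate = pick(flow_rate, "flow_rate"),
                adsorption_start = pick(adsorption_start, "adsorption_start", 0),
                rinse_start = pick(rinse_start, "rinse_start"))
}

#' @rdname read_kinetic_trace
#' @param trace A [kinetic_trace()] to write.
#' @param sidecar Also write the metadata sidecar JSON? Default `TRUE`.
#' @export
write_kinetic_trace <- function(trace, path, sidecar = TRUE) {
  write.csv(data.frame(time_s = trace$times, coverage_mg_m2 = trace$coverage),
            path, row.names = FALSE)
  if (sidecar) {
    meta <- list(bulk_concentration = trace$bulk_concentration,
                 flow_rate = trace$flow_rate,
                 adsorption_start = trace$adsorption_start,
                 rinse_start = trace$rinse_start)
    jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Reference protein for slope calibration
#'
#' A protein of known hydrodynamic diameter measured in the same flow cell,
#' used by [dh_calibrated()] to bypass the cell's mass-transfer constant.
#'
#' @param d_h0 Known hydrodynamic diameter, nm.
#' @param slope0 Initial adsorption slope of the reference run, mg m^-2 s^-1.
#' @param flow_rate0 Flow rate of the reference run, cm^3 s^-1.
#' @param concentration0 Bulk concentration of the reference run, mg L^-1.
#' @return An object of class `calibration_reference`.
#' @examples
#' hsa_reference() # serum-albumin defaults
#' @export
calibration_reference <- function(d_h0, slope0, flow_rate0, concentration0) {
  for (v in c("d_h0", "slope0", "flow_rate0", "concentration0")) {
    .check_positive(get(v), v)
  }
  structure(list(d_h0 = d_h0, slope0 = slope0, flow_rate0 = flow_rate0,
                 concentration0 = concentration0),
            class = "calibration_reference")
}

#' @rdname calibration_reference
#' @details `hsa_reference()` returns the human serum albumin calibration
#'   tuple: d_H0 = 7.5 nm, slope 5.5e-3 mg m^-2 s^-1 at a flow rate of
#'   2.5e-3 cm^3 s^-1 and 5 mg L^-1 bulk concentration.
#' @export
hsa_reference <- function() {
  calibration_reference(d_h0 = 7.5, slope0 = 5.5e-3,
                        flow_rate0 = 2.5e-3, concentration0 = 5)
}

# Indices of the trace lying in the requested phase.
.phase_index <- function(trace, phase = c("adsorption", "post_rinse")) {
  phase <- match.arg(phase)
  t <- trace$times
  if (phase == "adsorption") {
    hi <- if (is.null(trace$rinse_start)) max(t) else trace$rinse_start
    which(t >= trace$adsorption_start & t <= hi)
  } else {
    if (is.null(trace$rinse_start)) {
      stop("trace has no rinse phase (rinse_start is not set)", call. = FALSE)
    }
    which(t >= trace$rinse_start)
  }
}

#' Fit the initial (transport-limited) adsorption slope
#'
#' Ordinary least squares over the early linear part of the adsorption phase.
#' The coverage at `adsorption_start` is subtracted first, so the fitted line
#' is anchored near zero (the transport-limited model has no intercept, and
#' instrument baselines drift). The default window runs from
#' `adsorption_start` to `adsorption_start + 450` s, additionally truncated
#' where the baseline-subtracted coverage first exceeds `max_fraction` of its
#' maximum -- a guard against traces whose plateau arrives early.
#'
#' @param trace A [kinetic_trace()].
#' @param window_length Window length after `adsorption_start`, s. Default 450.
#' @param max_fraction Truncate the window where coverage first exceeds this
#'   fraction of the (baseline-subtracted) trace maximum. Default 0.5.
#' @param min_points Minimum number of samples required. Default 5.
#' @return An object of class `slope_fit`: `slope` (mg m^-2 s^-1),
#'   `intercept` (mg m^-2), `r_squared`, `stderr` (slope standard error),
#'   `window` (s), `n`. Warns when R^2 < 0.98, a sign the window is not
#'   linear.
#' @export
fit_initial_slope <- function(trace, window_length = 450, max_fraction = 0.5,
                              min_points = 5) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t0 <- trace$adsorption_start
  baseline <- approx(trace$times, trace$coverage, xout = t0, rule = 2)$y
  y_all <- trace$coverage - baseline
  ads <- .phase_index(trace, "adsorption")
  t_end <- min(t0 + window_length,
               if (is.null(trace$rinse_start)) Inf else trace$rinse_start)
  sel <- ads[trace$times[ads] >= t0 & trace$times[ads] <= t_end]
  ymax <- max(y_all[ads])
  over <- sel[y_all[sel] > max_fraction * ymax]
  if (length(over) > 0L) sel <- sel[trace$times[sel] < trace$times[over[1]]]
  if (length(sel) < min_points) {
    stop(sprintf("only %d samples in the slope window; need at least %d",
                 length(sel), min_points), call. = FALSE)
  }
  tt <- trace$times[sel]
  yy <- y_all[sel]
  fit <- .ols_line(tt, yy)
  if (is.finite(fit$r_squared) && fit$r_squared < 0.98) {
    warning(sprintf("initial-slope fit R^2 = %.3f < 0.98; window may not be linear",
                    fit$r_squared), call. = FALSE)
  }
  structure(
    list(slope = fit$slope, intercept = fit$intercept,
         r_squared = fit$r_squared, stderr = fit$stderr_slope,
         window = c(min(tt), max(tt)), n = length(sel)),
    class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> slope = %.4g mg m^-2 s^-1 (SE %.2g), R^2 = %.4f, window %g-%g s (n = %d)\n",
              x$slope, x$stderr, x$r_squared, x$window[1], x$window[2], x$n))
  invisible(x)
}

#' Transport-limited coverage forward model
#'
#' Coverage accumulated under convective-diffusion (transport-limited)
#' conditions in a flow cell: `Gamma = k_c0 * D^(2/3) * Q^(1/3) * c_b * t`,
#' linear in both time and bulk concentration. `k_c0` is the cell's
#' mass-transfer constant; it depends on cell geometry and must carry units
#' making `Gamma` come out in mg m^-2 for `D` in m^2 s^-1, `Q` in cm^3 s^-1
#' and `c_b` in mg L^-1.
#'
#' @param t Adsorption time, s (vectorized); non-negative.
#' @param k_c0 Mass-transfer constant (see Details above).
#' @param diffusion Molecular diffusion coefficient, m^2 s^-1.
#' @param flow_rate Volumetric flow rate, cm^3 s^-1.
#' @param concentration Bulk concentration, mg L^-1.
#' @return Coverage in mg m^-2.
#' @export
transport_limited_coverage <- function(t, k_c0, diffusion, flow_rate, concentration) {
  if (any(t < 0)) stop("adsorption time must be non-negative", call. = FALSE)
  .check_positive(k_c0, "k_c0")
  .check_positive(diffusion, "diffusion")
  .check_positive(flow_rate, "flow_rate")
  .check_positive(concentration, "concentration")
  k_c0 * diffusion^(2 / 3) * flow_rate^(1 / 3) * concentration * t
}

.fit_slope_value <- function(fit) {
  if (inherits(fit, "slope_fit")) fit$slope else as.numeric(fit)
}

#' Hydrodynamic diameter from the adsorption slope (direct route)
#'
#' Inverts the transport-limited slope relation: the slope
#' `s_l = k_c0 * D^(2/3) * Q^(1/3) * c_b` yields
#' `D = (s_l / (k_c0 Q^(1/3) c_b))^(3/2)` and then Stokes-Einstein gives
#' `d_H = kT/(3 pi eta) * (k_c0 Q^(1/3) c_b / s_l)^(3/2)`. This route needs
#' the cell's mass-transfer constant `k_c0`, which is instrument-specific; if
#' you do not know it, use the calibration route [dh_calibrated()] with a
#' reference protein instead.
#'
#' @param fit A [fit_initial_slope()] result, or a slope in mg m^-2 s^-1.
#' @param flow_rate Flow rate, cm^3 s^-1.
#' @param concentration Bulk concentration, mg L^-1.
#' @param k_c0 Mass-transfer constant, units as in
#'   [transport_limited_coverage()]. Required.
#' @param cond [solution_conditions()] for temperature/viscosity.
#' @return Hydrodynamic diameter, nm; monotone decreasing in the slope.
#' @export
dh_from_slope <- function(fit, flow_rate, concentration, k_c0 = NULL,
                          cond = solution_conditions()) {
  if (is.null(k_c0)) {
    stop("k_c0 (the cell mass-transfer constant) is required for the direct ",
         "route; it is instrument-specific and not generally known. Use ",
         "dh_calibrated() with a reference protein instead.", call. = FALSE)
  }
  slope <- .fit_slope_value(fit)
  .check_positive(slope, "slope")
  diffusion <- (slope / (k_c0 * flow_rate^(1 / 3) * concentration))^(3 / 2)
  hydrodynamic_diameter(diffusion, cond)
}

#' Hydrodynamic diameter by slope calibration (reference-protein route)
#'
#' Ratio form of the transport-limited inversion that cancels the cell's
#' mass-transfer constant by comparing against a reference protein of known
#' size measured in the same cell:
#' `d_H = d_H0 * [(s_l0 Q^(1/3) c_b) / (s_l Q0^(1/3) c_b0)]^(3/2)`.
#' Invariant under any common rescaling of slope, flow-rate or concentration
#' units applied to both experiment and reference.
#'
#' @inheritParams dh_from_slope
#' @param ref A [calibration_reference()], e.g. [hsa_reference()].
#' @return Hydrodynamic diameter, nm.
#' @examples
#' dh_calibrated(2.2e-3, flow_rate = 1.1e-3, concentration = 2,
#'               ref = hsa_reference()) # ~5.0 nm
#' @export
dh_calibrated <- function(fit, flow_rate, concentration, ref) {
  stopifnot(inherits(ref, "calibration_reference"))
  slope <- .fit_slope_value(fit)
  .check_positive(slope, "slope")
  .check_positive(flow_rate, "flow_rate")
  .check_positive(concentration, "concentration")
  ratio <- (ref$slope0 * flow_rate^(1 / 3) * concentration) /
    (slope * ref$flow_rate0^(1 / 3) * ref$concentration0)
  ref$d_h0 * ratio^(3 / 2)
}

#' Plateau coverage of a kinetic phase
#'
#' Mean coverage over the final 20% of the requested phase's time span,
#' together with its standard deviation. If the tail is still drifting
#' (tail-window slope significant at 3 standard errors) a warning is emitted
#' and the `rising` flag is set.
#'
#' @param trace A [kinetic_trace()].
#' @param phase `"adsorption"` (up to `rinse_start`, or the whole trace when
#'   there is none) or `"post_rinse"`.
#' @param tail_fraction Fraction of the phase used as the plateau window.
#'   Default 0.2.
#' @return A list: `mean`, `sd` (mg m^-2), `window` (s), `n`, `rising`.
#' @export
plateau_coverage <- function(trace, phase = c("adsorption", "post_rinse"),
                             tail_fraction = 0.2) {
  stopifnot(inherits(trace, "kinetic_trace"))
  phase <- match.arg(phase)
  idx <- .phase_index(trace, phase)
  if (length(idx) < 2L) stop("phase has too few samples", call. = FALSE)
  t <- trace$times[idx]
  t_from <- max(t) - tail_fraction * (max(t) - min(t))
  tail_idx <- idx[t >= t_from]
  y <- trace$coverage[tail_idx]
  tt <- trace$times[tail_idx]
  rising <- FALSE
  if (length(tail_idx) >= 3L && sd(y) > 0) {
    fit <- .ols_line(tt, y)
    se <- fit$stderr_slope
    if (is.finite(se) && se > 0 && fit$slope > 3 * se) {
      rising <- TRUE
      warning(sprintf("%s tail is still rising; plateau value may be biased", phase),
              call. = FALSE)
    }
  }
  list(mean = mean(y), sd = sd(y), window = c(min(tt), max(tt)),
       n = length(tail_idx), rising = rising)
}

#' Irreversibly adsorbed coverage
#'
#' Coverage remaining after the rinse step: the plateau of the post-rinse
#' phase. Requires a trace with `rinse_start` set.
#'
#' @inheritParams plateau_coverage
#' @return As [plateau_coverage()], for the post-rinse phase.
#' @export
irreversible_coverage <- function(trace, tail_fraction = 0.2) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (is.null(trace$rinse_start)) {
    stop("trace has no rinse phase; irreversible coverage is undefined",
         call. = FALSE)
  }
  plateau_coverage(trace, "post_rinse", tail_fraction = tail_fraction)
}

#' Full analysis of a flow-cell adsorption trace
#'
#' Runs the slope fit, plateau and (when a rinse phase exists) irreversible
#' coverage extraction, and infers the hydrodynamic diameter by the
#' calibration route when a reference is supplied, or by the direct route
#' when `k_c0` is given.
#'
#' @param trace A [kinetic_trace()].
#' @param ref Optional [calibration_reference()].
#' @param k_c0 Optional mass-transfer constant for the direct route.
#' @param cond [solution_conditions()].
#' @param ... Passed to [fit_initial_slope()].
#' @return An object of class `owls_report`.
#' @export
analyze_owls_trace <- function(trace, ref = NULL, k_c0 = NULL,
                               cond = solution_conditions(), ...) {
  fit <- fit_initial_slope(trace, ...)
  plateau <- plateau_coverage(trace, "adsorption")
  irr <- if (!is.null(trace$rinse_start)) irreversible_coverage(trace) else NULL
  d_h <- NA_real_
  route <- "none"
  if (!is.null(ref)) {
    d_h <- dh_calibrated(fit, trace$flow_rate, trace$bulk_concentration, ref)
    route <- "calibration"
  } else if (!is.null(k_c0)) {
    d_h <- dh_from_slope(fit, trace$flow_rate, trace$bulk_concentration,
                         k_c0 = k_c0, cond = cond)
    route <- "direct"
  }
  structure(
    list(slope_fit = fit, plateau = plateau, irreversible = irr,
         d_h = d_h, d_h_route = route,
         bulk_concentration = trace$bulk_concentration,
         flow_rate = trace$flow_rate),
    class = "owls_report")
}

#' @export
print.owls_report <- function(x, ...) {
  cat("<owls_report>\n")
  cat(sprintf("  initial slope: %.4g mg m^-2 s^-1 (R^2 = %.4f)\n",
              x$slope_fit$slope, x$slope_fit$r_squared))
  cat(sprintf("  adsorption plateau: %.3g +/- %.2g mg m^-2\n",
              x$plateau$mean, x$plateau$sd))
  if (!is.null(x$irreversible)) {
    cat(sprintf("  irreversible coverage: %.3g +/- %.2g mg m^-2\n",
                x$irreversible$mean, x$irreversible$sd))
  }
  if (is.finite(x$d_h)) {
    cat(sprintf("  hydrodynamic diameter: %.3g nm (%s route)\n", x$d_h, x$d_h_route))
  }
  invisible(x)
}

#' Serialize an OWLS analysis report to JSON
#'
#' @param report An [analyze_owls_trace()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_owls_report <- function(report, path) {
  out <- list(
    slope_mg_m2_s = report$slope_fit$slope,
    slope_stderr = report$slope_fit$stderr,
    r_squared = report$slope_fit$r_squared,
    window_s = report$slope_fit$window,
    plateau_mg_m2 = report$plateau$mean,
    plateau_sd = report$plateau$sd,
    irreversible_mg_m2 = if (is.null(report$irreversible)) NULL else report$irreversible$mean,
    d_h_nm = if (is.finite(report$d_h)) report$d_h else NULL,
    d_h_route = report$d_h_route,
    bulk_concentration_mg_L = report$bulk_concentration,
    flow_rate_cm3_s = report$flow_rate)
  jsonlite::write_json(out[!vapply(out, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
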