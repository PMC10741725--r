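#' Quartz-sensor constants
#'
#' Physical constants of the QCM sensor plus the hydration correction. The
#' default Sauerbrey constant 0.177 mg m^-2 Hz^-1 corresponds to a 5 MHz
#' AT-cut quartz sensor and can be recomputed from the quartz properties with
#' [sauerbrey_constant()]. `hydration` is the dimensionless fraction by which
#' the acoustically sensed (wet) mass exceeds the dry protein mass because of
#' hydrodynamically coupled solvent; the 0.5 default was established for
#' compact globular proteins (serum albumin) and is a configurable parameter,
#' not a constant, since its protein-specificity is not settled.
#'
#' @param sauerbrey Sauerbrey constant, mg m^-2 Hz^-1. Default 0.177.
#' @param fundamental_frequency Fundamental resonance frequency, Hz.
#'   Default 5e6.
#' @param quartz_density Density of quartz, kg m^-3. Default 2648.
#' @param quartz_shear_modulus AT-cut quartz shear modulus, Pa.
#'   Default 2.947e10.
#' @param hydration Hydration correction H in `[0, 1]`. Default 0.5.
#' @return An object of class `qcm_constants`.
#' @export
qcm_constants <- function(sauerbrey = 0.177, fundamental_frequency = 5e6,
                          quartz_density = 2648, quartz_shear_modulus = 2.947e10,
                          hydration = 0.5) {
  for (v in c("sauerbrey", "fundamental_frequency", "quartz_density",
              "quartz_shear_modulus")) {
    .check_positive(get(v), v)
  }
  if (!is.numeric(hydration) || hydration < 0 || hydration > 1) {
    stop("hydration must lie in [0, 1]", call. = FALSE)
  }
  structure(list(sauerbrey = sauerbrey,
                 fundamental_frequency = fundamental_frequency,
                 quartz_density = quartz_density,
                 quartz_shear_modulus = quartz_shear_modulus,
                 hydration = hydration),
            class = "qcm_constants")
}

#' Sauerbrey constant from quartz properties
#'
#' `C_Q = sqrt(rho_q * mu_q) / (2 f0^2)`, converted to mg m^-2 Hz^-1. For a
#' 5 MHz AT-cut sensor (rho_q = 2648 kg m^-3, mu_q = 2.947e10 Pa) this gives
#' 0.177 mg m^-2 Hz^-1; the constant scales as 1/f0^2.
#'
#' @param constants A [qcm_constants()] supplying the quartz properties.
#' @return Sauerbrey constant in mg m^-2 Hz^-1.
#' @examples
#' sauerbrey_constant() # 0.177
#' @export
sauerbrey_constant <- function(constants = qcm_constants()) {
  stopifnot(inherits(constants, "qcm_constants"))
  # kg m^-2 Hz^-1 -> mg m^-2 Hz^-1
  sqrt(constants$quartz_density * constants$quartz_shear_modulus) /
    (2 * constants$fundamental_frequency^2) * 1e6
}

#' Sauerbrey coverage from a frequency shift
#'
#' `Gamma_Q = -C_Q * df / n_o` for overtone `n_o`. A positive frequency shift
#' implies mass loss and yields a negative coverage, flagged by a warning.
#'
#' @param frequency_shift Frequency shift, Hz (vectorized).
#' @param overtone Overtone number; an odd positive integer.
#' @param constants A [qcm_constants()].
#' @return Acoustic (wet) coverage, mg m^-2.
#' @examples
#' sauerbrey_coverage(-27.1, 3) # ~1.6 mg m^-2
#' @export
sauerbrey_coverage <- function(frequency_shift, overtone,
                               constants = qcm_constants()) {
  .check_overtone(overtone)
  out <- -constants$sauerbrey * frequency_shift / overtone
  if (any(out < 0)) {
    warning("positive frequency shift: negative coverage indicates mass loss",
            call. = FALSE)
  }
  out
}

.check_overtone <- function(overtone) {
  if (!is.numeric(overtone) || length(overtone) != 1L || overtone <= 0 ||
      overtone != round(overtone) || overtone %% 2 == 0) {
    stop("overtone must be an odd positive integer", call. = FALSE)
  }
  invisible(overtone)
}

#' Dry coverage via the hydration correction
#'
#' `Gamma = Gamma_Q * (1 - H)`: the acoustically sensed (wet) QCM coverage
#' reduced by the hydration fraction H to the dry protein mass.
#'
#' @param wet Wet (Sauerbrey) coverage, mg m^-2 (vectorized).
#' @param hydration Hydration correction H in `[0, 1]`. Default 0.5.
#' @return Dry coverage, mg m^-2.
#' @examples
#' dry_coverage(1.6, 0.5) # 0.8
#' @export
dry_coverage <- function(wet, hydration = 0.5) {
  if (!is.numeric(hydration) || any(hydration < 0) || any(hydration > 1)) {
    stop("hydration must lie in [0, 1]", call. = FALSE)
  }
  wet * (1 - hydration)
}

#' Multi-overtone QCM-D trace
#'
#' Per-overtone frequency-shift time series from a quartz sensor.
#'
#' @param times Time points, s; strictly increasing.
#' @param shifts Matrix (or data frame) of frequency shifts in Hz, one column
#'   per overtone, rows matching `times`.
#' @param overtones Odd positive integers, one per column of `shifts`.
#' @param rinse_start Optional rinse onset, s.
#' @return An object of class `qcm_trace`.
#' @export
qcm_trace <- function(times, shifts, overtones, rinse_start = NULL) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  shifts <- as.matrix(shifts)
  if (nrow(shifts) != length(times)) {
    stop("shifts must have one row per time point", call. = FALSE)
  }
  if (ncol(shifts) != length(overtones)) {
    stop("shifts must have one column per overtone", call. = FALSE)
  }
  for (n in overtones) .check_overtone(n)
  colnames(shifts) <- paste0("n", overtones)
  structure(list(times = times, shifts = shifts,
                 overtones = as.integer(overtones), rinse_start = rinse_start),
            class = "qcm_trace")
}

#' @export
print.qcm_trace <- function(x, ...) {
  cat(sprintf("<qcm_trace> %d samples, overtones {%s}, t = %g..%g s%s\n",
              length(x$times), paste(x$overtones, collapse = ", "),
              min(x$times), max(x$times),
              if (is.null(x$rinse_start)) "" else
                sprintf(", rinse from %g s", x$rinse_start)))
  invisible(x)
}

#' Read/write QCM-D traces as CSV
#'
#' Two dialects are supported and auto-detected from the header: wide
#' (`time_s,df3_hz,df5_hz,...`) and long (`time_s,overtone,df_hz`). Rinse
#' onset comes from the `rinse_start` argument or a JSON sidecar as in
#' [read_kinetic_trace()].
#'
#' @param path CSV path.
#' @param rinse_start Optional rinse onset, s.
#' @return A [qcm_trace()].
#' @export
read_qcm_trace <- function(path, rinse_start = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  df <- read.csv(path)
  side <- paste0(path, ".json")
  if (is.null(rinse_start) && file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    rinse_start <- meta$rinse_start
  }
  if (all(c("time_s", "overtone", "df_hz") %in% names(df))) {
    overtones <- sort(unique(df$overtone))
    times <- sort(unique(df$time_s))
    shifts <- vapply(overtones, function(n) {
      sub <- df[df$overtone == n, ]
      sub$df_hz[order(sub$time_s)]
    }, numeric(length(times)))
    return(qcm_trace(times, shifts, overtones, rinse_start = rinse_start))
  }
  wide <- grep("^df([0-9]+)_hz$", names(df), value = TRUE)
  if ("time_s" %in% names(df) && length(wide) > 0L) {
    overtones <- as.integer(sub("^df([0-9]+)_hz$", "\\1", wide))
    return(qcm_trace(df$time_s, df[wide], overtones, rinse_start = rinse_start))
  }
  stop("unrecognized QCM CSV dialect: expected wide (time_s,df3_hz,...) or ",
       "long (time_s,overtone,df_hz) columns", call. = FALSE)
}

#' @rdname read_qcm_trace
#' @param trace A [qcm_trace()] to write.
#' @param format `"wide"` (default) or `"long"`.
#' @param sidecar Also write the metadata sidecar JSON? Default `TRUE`.
#' @export
write_qcm_trace <- function(trace, path, format = c("wide", "long"),
                            sidecar = TRUE) {
  format <- match.arg(format)
  if (format == "wide") {
    df <- data.frame(time_s = trace$times)
    for (i in seq_along(trace$overtones)) {
      df[[sprintf("df%d_hz", trace$overtones[i])]] <- trace$shifts[, i]
    }
  } else {
    df <- do.call(rbind, lapply(seq_along(trace$overtones), function(i) {
      data.frame(time_s = trace$times, overtone = trace$overtones[i],
                 df_hz = trace$shifts[, i])
    }))
  }
  write.csv(df, path, row.names = FALSE)
  if (sidecar && !is.null(trace$rinse_start)) {
    jsonlite::write_json(list(rinse_start = trace$rinse_start),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Coverage analysis of a QCM-D trace
#'
#' Extracts the post-rinse plateau frequency shift per overtone (tail window:
#' final 20% of the post-rinse phase, or of the whole trace when there is no
#' rinse), converts each to wet coverage by [sauerbrey_coverage()], averages
#' the requested overtone subset, and applies the hydration correction to get
#' the dry coverage. The default subset `{3, 11}` averages the extreme
#' overtones commonly reported.
#'
#' @param trace A [qcm_trace()].
#' @param constants A [qcm_constants()] (supplies the hydration H).
#' @param overtones Overtone subset to average. Default `c(3, 11)`; pass
#'   `trace$overtones` for full-set averaging.
#' @param tail_fraction Plateau tail window fraction. Default 0.2.
#' @return An object of class `qcm_coverage`: `wet_coverage_per_overtone`
#'   (named, mg m^-2), `dry_coverage` (mg m^-2), `overtones_used`,
#'   `hydration`.
#' @export
analyze_qcm_trace <- function(trace, constants = qcm_constants(),
                              overtones = c(3, 11), tail_fraction = 0.2) {
  stopifnot(inherits(trace, "qcm_trace"))
  missing_n <- setdiff(overtones, trace$overtones)
  if (length(missing_n) > 0L) {
    stop(sprintf("overtone(s) %s not in trace; available: %s",
                 paste(missing_n, collapse = ", "),
                 paste(trace$overtones, collapse = ", ")), call. = FALSE)
  }
  t <- trace$times
  lo <- if (is.null(trace$rinse_start)) min(t) else trace$rinse_start
  idx <- which(t >= lo)
  tw <- t[idx]
  tail_idx <- idx[tw >= max(tw) - tail_fraction * (max(tw) - min(tw))]
  wet <- vapply(overtones, function(n) {
    col <- match(n, trace$overtones)
    sauerbrey_coverage(mean(trace$shifts[tail_idx, col]), n, constants)
  }, numeric(1))
  names(wet) <- paste0("n", overtones)
  structure(
    list(wet_coverage_per_overtone = wet,
         dry_coverage = dry_coverage(mean(wet), constants$hydration),
         overtones_used = as.integer(overtones),
         hydration = constants$hydration,
         window = range(t[tail_idx])),
    class = "qcm_coverage")
}

#' @export
print.qcm_coverage <- function(x, ...) {
  cat("<qcm_coverage>\n")
  for (i in seq_along(x$wet_coverage_per_overtone)) {
    cat(sprintf("  wet coverage (overtone %d): %.3g mg m^-2\n",
                x$overtones_used[i], x$wet_coverage_per_overtone[i]))
  }
  cat(sprintf("  dry coverage (H = %.2g): %.3g mg m^-2\n",
              x$hydration, x$dry_coverage))
  invisible(x)
}

#' Serialize a QCM coverage result to JSON
#'
#' @param result An [analyze_qcm_trace()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_qcm_report <- function(result, path) {
  out <- list(
    wet_coverage_per_overtone_mg_m2 = as.list(result$wet_coverage_per_overtone),
    dry_coverage_mg_m2 = result$dry_coverage,
    overtones_used = result$overtones_used,
    hydration = result$hydration)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
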