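#' Pipeline run configuration
#'
#' Bundles everything the end-to-end characterization needs. All validation
#' problems are collected and reported in a single error, so a broken config
#' can be fixed in one pass.
#'
#' @param protein A [protein_spec()].
#' @param charge_poly Optional [charge_polynomial()].
#' @param conditions [solution_conditions()].
#' @param qcm A [qcm_constants()].
#' @param calibration Optional [calibration_reference()] for the OWLS route.
#' @param theta Jamming coverage used for the packing limit. Default 0.547.
#' @param owls_trace Optional [kinetic_trace()].
#' @param qcm_trace Optional [qcm_trace()].
#' @param sp_data Optional [streaming_potential_data()].
#' @param seed Integer seed recorded in the report. Default 1.
#' @return An object of class `run_config`.
#' @export
run_config <- function(protein, charge_poly = NULL,
                       conditions = solution_conditions(),
                       qcm = qcm_constants(), calibration = NULL,
                       theta = .THETA_RSA_DISKS, owls_trace = NULL,
                       qcm_trace = NULL, sp_data = NULL, seed = 1) {
  problems <- character(0)
  check <- function(obj, cls, name, optional = TRUE) {
    if (is.null(obj)) {
      if (!optional) problems <<- c(problems, sprintf("missing required field: %s", name))
    } else if (!inherits(obj, cls)) {
      problems <<- c(problems, sprintf("%s must be a %s", name, cls))
    }
  }
  if (missing(protein)) protein <- NULL
  check(protein, "protein_spec", "protein", optional = FALSE)
  check(charge_poly, "charge_polynomial", "charge_poly")
  check(conditions, "solution_conditions", "conditions", optional = FALSE)
  check(qcm, "qcm_constants", "qcm", optional = FALSE)
  check(calibration, "calibration_reference", "calibration")
  check(owls_trace, "kinetic_trace", "owls_trace")
  check(qcm_trace, "qcm_trace", "qcm_trace")
  check(sp_data, "streaming_potential_data", "sp_data")
  if (length(problems) > 0L) {
    stop("invalid run configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(list(protein = protein, charge_poly = charge_poly,
                 conditions = conditions, qcm = qcm, calibration = calibration,
                 theta = theta, owls_trace = owls_trace, qcm_trace = qcm_trace,
                 sp_data = sp_data, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file supplies scalar fields (protein, charge polynomial, conditions,
#' QCM constants, calibration reference, seed) and optional paths to trace
#' CSVs, which are loaded relative to the config file's directory.
#'
#' @param path Config file; `.json` is parsed as JSON, anything else as YAML
#'   (JSON being a YAML subset, both work either way).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(path)
  rel <- function(p) if (file.exists(p)) p else file.path(base, p)
  p <- raw$protein
  if (is.null(p)) stop("config must define a protein block", call. = FALSE)
  protein <- protein_spec(
    name = if (is.null(p$name)) "protein" else p$name,
    molar_mass = p$molar_mass,
    density = if (is.null(p$density)) 1.35 else p$density,
    cross_section_area = p$cross_section_area,
    sequence = if (!is.null(p$fasta)) read_fasta_sequence(rel(p$fasta), p$fasta_id)
               else p$sequence)
  cp <- raw$charge_polynomial
  charge_poly <- if (!is.null(cp)) {
    charge_polynomial(cp$c0, cp$c1,
                      ph_range = if (is.null(cp$ph_range)) c(4, 8) else unlist(cp$ph_range))
  }
  cd <- if (is.null(raw$conditions)) list() else raw$conditions
  conditions <- do.call(solution_conditions, cd)
  qc <- if (is.null(raw$qcm_constants)) list() else raw$qcm_constants
  qcm <- do.call(qcm_constants, qc)
  cal <- raw$calibration
  calibration <- if (!is.null(cal)) {
    calibration_reference(cal$d_h0, cal$slope0, cal$flow_rate0, cal$concentration0)
  }
  tr <- raw$owls_trace
  owls <- if (!is.null(tr)) {
    read_kinetic_trace(rel(tr$path), bulk_concentration = tr$bulk_concentration,
                       flow_rate = tr$flow_rate,
                       adsorption_start = tr$adsorption_start,
                       rinse_start = tr$rinse_start)
  }
  qt <- raw$qcm_trace
  qtr <- if (!is.null(qt)) read_qcm_trace(rel(qt$path), rinse_start = qt$rinse_start)
  sp <- raw$streaming_potential
  spd <- if (!is.null(sp)) {
    read_streaming_potential(rel(sp$path), conductivity = sp$conductivity,
                             cond = conditions)
  }
  run_config(protein = protein, charge_poly = charge_poly,
             conditions = conditions, qcm = qcm, calibration = calibration,
             theta = if (is.null(raw$theta)) .THETA_RSA_DISKS else raw$theta,
             owls_trace = owls, qcm_trace = qtr, sp_data = spd,
             seed = if (is.null(raw$seed)) 1L else raw$seed)
}

#' End-to-end protein characterization report
#'
#' Aggregates the package's whole desk workflow for one protein: geometry and
#' packing limit from the molar mass, charge curve and isoelectric point from
#' the charge polynomial, and -- when the corresponding traces are present in
#' the config -- the OWLS slope analysis with hydrodynamic-diameter
#' inference, the QCM wet/dry coverages, and the streaming-potential zeta.
#' The report is deterministic: rebuilding it from the same config yields
#' byte-identical JSON.
#'
#' @param config A [run_config()] or a path accepted by [read_run_config()].
#' @return An object of class `characterization_report` (a named list with
#'   explicit unit-suffixed fields).
#' @export
characterize <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  geo <- geometry_report(config$protein, theta = config$theta)
  report <- list(
    protein = list(name = config$protein$name,
                   molar_mass_g_mol = config$protein$molar_mass,
                   density_g_cm3 = config$protein$density,
                   cross_section_area_nm2 = config$protein$cross_section_area),
    geometry = list(volume_nm3 = geo$volume,
                    equivalent_diameter_nm = geo$equivalent_diameter,
                    dimer_diameter_nm = geo$dimer_diameter,
                    max_coverage_mg_m2 = geo$max_coverage,
                    theta = geo$theta),
    seed = config$seed)
  if (!is.null(config$charge_poly)) {
    poly <- config$charge_poly
    report$charge <- list(
      c0 = poly$c0, c1 = poly$c1, ph_range = poly$ph_range,
      isoelectric_point = tryCatch(isoelectric_point(poly),
                                   error = function(e) NA_real_),
      charge_at_ph4_e = nominal_charge(poly, 4))
  }
  if (!is.null(config$owls_trace)) {
    rep_owls <- analyze_owls_trace(config$owls_trace, ref = config$calibration,
                                   cond = config$conditions)
    report$owls <- list(
      slope_mg_m2_s = rep_owls$slope_fit$slope,
      r_squared = rep_owls$slope_fit$r_squared,
      plateau_mg_m2 = rep_owls$plateau$mean,
      irreversible_mg_m2 = if (is.null(rep_owls$irreversible)) NULL else
        rep_owls$irreversible$mean,
      d_h_nm = if (is.finite(rep_owls$d_h)) rep_owls$d_h else NULL,
      d_h_route = rep_owls$d_h_route)
  }
  if (!is.null(config$qcm_trace)) {
    subset_n <- intersect(c(3, 11), config$qcm_trace$overtones)
    if (length(subset_n) == 0L) subset_n <- config$qcm_trace$overtones
    qr <- analyze_qcm_trace(config$qcm_trace, constants = config$qcm,
                            overtones = subset_n)
    report$qcm <- list(
      wet_coverage_per_overtone_mg_m2 = as.list(qr$wet_coverage_per_overtone),
      dry_coverage_mg_m2 = qr$dry_coverage,
      hydration = qr$hydration,
      overtones_used = qr$overtones_used)
  }
  if (!is.null(config$sp_data)) {
    report$zeta <- zeta_from_streaming(config$sp_data)
  }
  structure(report, class = "characterization_report")
}

#' @export
print.characterization_report <- function(x, ...) {
  cat(sprintf("<characterization_report> %s\n", x$protein$name))
  g <- x$geometry
  cat(sprintf("  volume %.1f nm^3 | d1 %.2f nm | dimer %.2g nm | Gamma_mx %.2g mg m^-2\n",
              g$volume_nm3, g$equivalent_diameter_nm, g$dimer_diameter_nm,
              g$max_coverage_mg_m2))
  if (!is.null(x$charge)) {
    cat(sprintf("  pI %.2f | charge at pH 4: %.1f e\n",
                x$charge$isoelectric_point, x$charge$charge_at_ph4_e))
  }
  if (!is.null(x$owls)) {
    cat(sprintf("  OWLS slope %.3g mg m^-2 s^-1, d_H %.3g nm (%s)\n",
                x$owls$slope_mg_m2_s,
                if (is.null(x$owls$d_h_nm)) NA else x$owls$d_h_nm,
                x$owls$d_h_route))
  }
  if (!is.null(x$qcm)) {
    cat(sprintf("  QCM dry coverage %.3g mg m^-2 (H = %.2g)\n",
                x$qcm$dry_coverage_mg_m2, x$qcm$hydration))
  }
  if (!is.null(x$zeta)) {
    cat(sprintf("  zeta %.3g mV\n", x$zeta$zeta_mV))
  }
  invisible(x)
}

#' Write a characterization report
#'
#' @param report A [characterize()] result.
#' @param path Output path; `format` defaults from the extension.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path,
                         format = if (grepl("\\.md$", path)) "markdown" else "json") {
  format <- match.arg(format, c("json", "markdown"))
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  g <- report$geometry
  lines <- c(
    sprintf("# Characterization report: %s", report$protein$name), "",
    sprintf("- molar mass: %g g mol^-1", report$protein$molar_mass_g_mol),
    sprintf("- molecular volume: %.1f nm^3", g$volume_nm3),
    sprintf("- equivalent-sphere diameter: %.2f nm", g$equivalent_diameter_nm),
    sprintf("- dimer hydrodynamic diameter: %.2g nm", g$dimer_diameter_nm),
    sprintf("- max jamming coverage (theta = %.3f): %.2g mg m^-2",
            g$theta, g$max_coverage_mg_m2))
  if (!is.null(report$charge)) {
    lines <- c(lines,
      sprintf("- isoelectric point: %.2f", report$charge$isoelectric_point),
      sprintf("- nominal charge at pH 4: %.1f e", report$charge$charge_at_ph4_e))
  }
  if (!is.null(report$owls)) {
    lines <- c(lines,
      sprintf("- OWLS initial slope: %.3g mg m^-2 s^-1 (R^2 = %.4f)",
              report$owls$slope_mg_m2_s, report$owls$r_squared),
      if (!is.null(report$owls$irreversible_mg_m2))
        sprintf("- OWLS irreversible coverage: %.3g mg m^-2",
                report$owls$irreversible_mg_m2),
      if (!is.null(report$owls$d_h_nm))
        sprintf("- hydrodynamic diameter (%s route): %.3g nm",
                report$owls$d_h_route, report$owls$d_h_nm))
  }
  if (!is.null(report$qcm)) {
    lines <- c(lines,
      sprintf("- QCM dry coverage: %.3g mg m^-2 (H = %.2g, overtones %s)",
              report$qcm$dry_coverage_mg_m2, report$qcm$hydration,
              paste(report$qcm$overtones_used, collapse = ", ")))
  }
  if (!is.null(report$zeta)) {
    lines <- c(lines, sprintf("- zeta potential: %.3g mV", report$zeta$zeta_mV))
  }
  writeLines(lines, path)
  invisible(path)
}
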