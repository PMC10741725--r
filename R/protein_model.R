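#' Protein specification
#'
#' The molecule's identity card: everything the geometry and packing
#' calculations need. Units follow bench conventions: molar mass in g mol^-1,
#' density in g cm^-3, cross-section area in nm^2.
#'
#' @param name Protein name (free text).
#' @param molar_mass Molar mass in g mol^-1; must be positive.
#' @param density Effective (dry) protein density in g cm^-3. Default 1.35,
#'   the typical value for compact globular proteins.
#' @param cross_section_area Average cross-section area of the molecule on the
#'   surface, nm^2; optional, required only by [max_jamming_coverage()].
#' @param sequence Optional amino-acid sequence in one-letter code (the 20
#'   canonical residues only), used by [titration_charge()].
#' @return An object of class `protein_spec`.
#' @examples
#' fgf21 <- protein_spec("FGF 21", molar_mass = 19400, cross_section_area = 17)
#' @export
protein_spec <- function(name, molar_mass, density = 1.35,
                         cross_section_area = NULL, sequence = NULL) {
  .check_positive(molar_mass, "molar_mass")
  .check_positive(density, "density")
  if (!is.null(cross_section_area)) {
    .check_positive(cross_section_area, "cross_section_area")
  }
  if (!is.null(sequence)) {
    sequence <- .check_sequence(sequence)
  }
  structure(
    list(name = as.character(name)[1], molar_mass = molar_mass,
         density = density, cross_section_area = cross_section_area,
         sequence = sequence),
    class = "protein_spec")
}

.AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.check_sequence <- function(sequence) {
  sequence <- toupper(gsub("[[:space:]]", "", as.character(sequence)[1]))
  letters <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(letters), .AA_LETTERS)
  if (length(bad) > 0L) {
    stop("sequence contains non-canonical residue letter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sequence
}

#' @export
print.protein_spec <- function(x, ...) {
  cat(sprintf("<protein_spec> %s\n", x$name))
  cat(sprintf("  molar mass: %g g mol^-1, density: %g g cm^-3\n",
              x$molar_mass, x$density))
  if (!is.null(x$cross_section_area)) {
    cat(sprintf("  cross-section area: %g nm^2\n", x$cross_section_area))
  }
  if (!is.null(x$sequence)) {
    cat(sprintf("  sequence: %d residues\n", nchar(x$sequence)))
  }
  invisible(x)
}

#' Molecular volume from molar mass and density
#'
#' Volume of a single molecule, `v1 = Mw / (N_Av * rho_p)`, converted to nm^3.
#' For a 19,400 g mol^-1 globular protein at 1.35 g cm^-3 this gives 23.9 nm^3.
#'
#' @param spec A [protein_spec()], or a molar mass in g mol^-1 when `density`
#'   is given explicitly.
#' @param density Protein density in g cm^-3; taken from `spec` when that is a
#'   `protein_spec`.
#' @return Molecular volume in nm^3.
#' @examples
#' molecular_volume(protein_spec("FGF 21", 19400))
#' @export
molecular_volume <- function(spec, density = NULL) {
  if (inherits(spec, "protein_spec")) {
    mw <- spec$molar_mass
    rho <- spec$density
  } else {
    mw <- spec
    rho <- density
    if (is.null(rho)) stop("density must be supplied", call. = FALSE)
  }
  .check_positive(mw, "molar_mass")
  .check_positive(rho, "density")
  # g mol^-1 / (mol^-1 * g cm^-3) = cm^3; 1 cm^3 = 1e21 nm^3
  mw / (.N_AV * rho) * 1e21
}

#' Equivalent-sphere diameter of a molecule
#'
#' Diameter of the sphere with the same volume, `d1 = (6 v1 / pi)^(1/3)`.
#'
#' @param volume Molecular volume in nm^3.
#' @return Diameter in nm.
#' @examples
#' equivalent_sphere_diameter(23.9) # 3.57 nm
#' @export
equivalent_sphere_diameter <- function(volume) {
  .check_positive(volume, "volume")
  (6 * volume / pi)^(1 / 3)
}

#' Hydrodynamic diameter of a dimer of touching spheres
#'
#' The hydrodynamic diameter of a doublet of two equal touching spheres is
#' 1.39 times that of the monomer.
#'
#' @param monomer_diameter Monomer hydrodynamic diameter, nm.
#' @return Dimer hydrodynamic diameter, nm.
#' @examples
#' dimer_hydrodynamic_diameter(3.57) # ~5.0 nm
#' @export
dimer_hydrodynamic_diameter <- function(monomer_diameter) {
  .check_positive(monomer_diameter, "monomer_diameter")
  .DIMER_HYDRO_FACTOR * monomer_diameter
}

#' Maximum (jamming-limited) mass coverage
#'
#' Monolayer mass coverage at the random sequential adsorption jamming limit,
#' `Gamma_mx = Mw * theta / (N_Av * Sg)`, with `Sg` the average molecular
#' cross-section area. The default `theta = 0.547` is the hard-disk jamming
#' coverage, which [estimate_jamming_coverage()] reproduces by simulation.
#'
#' @param spec A [protein_spec()] with `cross_section_area` set.
#' @param theta Dimensionless surface coverage, in `[0, 1]`.
#' @return Mass coverage in mg m^-2; linear in `theta`.
#' @examples
#' max_jamming_coverage(protein_spec("FGF 21", 19400, cross_section_area = 17))
#' @export
max_jamming_coverage <- function(spec, theta = .THETA_RSA_DISKS) {
  if (!inherits(spec, "protein_spec")) {
    stop("spec must be a protein_spec", call. = FALSE)
  }
  if (is.null(spec$cross_section_area)) {
    stop("cross_section_area is not set in the protein_spec; ",
         "it is required for the jamming coverage", call. = FALSE)
  }
  if (!is.numeric(theta) || any(theta < 0) || any(theta > 1)) {
    stop("theta must lie in [0, 1]", call. = FALSE)
  }
  # g mol^-1 / (mol^-1 * nm^2) = g nm^-2 = 1e21 mg m^-2
  spec$molar_mass * theta / (.N_AV * spec$cross_section_area) * 1e21
}

#' Geometry and packing report for a protein
#'
#' Convenience wrapper evaluating molecular volume, equivalent-sphere and
#' dimer diameters, and (when the cross-section area is available) the maximum
#' jamming coverage.
#'
#' @inheritParams max_jamming_coverage
#' @return An object of class `geometry_report`: a list with `volume` (nm^3),
#'   `equivalent_diameter` (nm), `dimer_diameter` (nm) and `max_coverage`
#'   (mg m^-2, `NA` when no cross-section area is set).
#' @examples
#' geometry_report(protein_spec("FGF 21", 19400, cross_section_area = 17))
#' @export
geometry_report <- function(spec, theta = .THETA_RSA_DISKS) {
  v <- molecular_volume(spec)
  d1 <- equivalent_sphere_diameter(v)
  gmx <- if (is.null(spec$cross_section_area)) NA_real_ else
    max_jamming_coverage(spec, theta)
  structure(
    list(protein = spec$name, volume = v, equivalent_diameter = d1,
         dimer_diameter = dimer_hydrodynamic_diameter(d1),
         max_coverage = gmx, theta = theta),
    class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf("<geometry_report> %s\n", x$protein))
  cat(sprintf("  molecular volume:      %.1f nm^3\n", x$volume))
  cat(sprintf("  equivalent diameter:   %.2f nm\n", x$equivalent_diameter))
  cat(sprintf("  dimer hydrodynamic d:  %.2g nm\n", x$dimer_diameter))
  if (is.finite(x$max_coverage)) {
    cat(sprintf("  max coverage (theta=%.3f): %.2g mg m^-2\n",
                x$theta, x$max_coverage))
  }
  invisible(x)
}

#' Serialize a geometry report to JSON
#'
#' @param report A [geometry_report()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geometry_report <- function(report, path) {
  out <- list(
    protein = report$protein,
    volume_nm3 = report$volume,
    equivalent_diameter_nm = report$equivalent_diameter,
    dimer_diameter_nm = report$dimer_diameter,
    max_coverage_mg_m2 = report$max_coverage,
    theta = report$theta)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
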