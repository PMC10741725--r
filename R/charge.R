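#' Charge-versus-pH quadratic
#'
#' Empirical description of a protein's nominal charge as a function of pH,
#' `Q_p(pH) = c0 - c1 * pH + pH^2`, with the quadratic coefficient fixed at 1.
#' The polynomial is a local fit; outside `ph_range` it is extrapolation and
#' evaluation emits a warning.
#'
#' @param c0,c1 Polynomial coefficients (dimensionless).
#' @param ph_range Validity range of the fit, a length-2 increasing vector of
#'   pH values. Default `c(4, 8)`.
#' @return An object of class `charge_polynomial`.
#' @examples
#' fgf21_q <- charge_polynomial(55.9, 15.9)
#' nominal_charge(fgf21_q, 4) # 8.3 e
#' @export
charge_polynomial <- function(c0, c1, ph_range = c(4, 8)) {
  stopifnot(is.numeric(c0), is.numeric(c1), length(c0) == 1L, length(c1) == 1L)
  if (length(ph_range) != 2L || ph_range[1] >= ph_range[2]) {
    stop("ph_range must be an increasing pair of pH values", call. = FALSE)
  }
  structure(list(c0 = c0, c1 = c1, ph_range = as.numeric(ph_range)),
            class = "charge_polynomial")
}

#' @export
print.charge_polynomial <- function(x, ...) {
  cat(sprintf("<charge_polynomial> Q(pH) = %.4g - %.4g pH + pH^2 (valid pH %g-%g)\n",
              x$c0, x$c1, x$ph_range[1], x$ph_range[2]))
  if (!is.null(attr(x, "r_squared"))) {
    cat(sprintf("  fitted, R^2 = %.6f\n", attr(x, "r_squared")))
  }
  invisible(x)
}

#' Nominal charge at a given pH
#'
#' Evaluates the charge polynomial, in elementary charge units. Values
#' requested outside the polynomial's validity range are returned with a
#' warning, since the quadratic is a local fit that diverges from titration
#' behaviour far from its fitting window.
#'
#' @param poly A [charge_polynomial()].
#' @param ph pH value(s) at which to evaluate.
#' @return Nominal charge in elementary charges (vectorized over `ph`).
#' @export
nominal_charge <- function(poly, ph) {
  stopifnot(inherits(poly, "charge_polynomial"), is.numeric(ph))
  outside <- ph < poly$ph_range[1] | ph > poly$ph_range[2]
  if (any(outside)) {
    warning(sprintf("pH outside the polynomial validity range [%g, %g]; extrapolating",
                    poly$ph_range[1], poly$ph_range[2]), call. = FALSE)
  }
  poly$c0 - poly$c1 * ph + ph^2
}

#' Isoelectric point of the charge polynomial
#'
#' The pH at which the nominal charge crosses zero, taken as the smaller root
#' of `pH^2 - c1 * pH + c0 = 0`. The smaller root sits on the descending
#' (physical) branch of the charge curve; the larger one lies on the
#' non-physical ascending branch outside the validity range.
#'
#' @param poly A [charge_polynomial()].
#' @return The isoelectric point (pH units).
#' @examples
#' isoelectric_point(charge_polynomial(55.9, 15.9)) # 5.25
#' @export
isoelectric_point <- function(poly) {
  stopifnot(inherits(poly, "charge_polynomial"))
  disc <- poly$c1^2 - 4 * poly$c0
  if (disc < 0) {
    stop("no isoelectric point in model: the charge polynomial has no real root",
         call. = FALSE)
  }
  (poly$c1 - sqrt(disc)) / 2
}

#' Fit the charge polynomial to (pH, charge) data
#'
#' Least-squares estimate of `(c0, c1)` in `Q = c0 - c1 * pH + pH^2` with the
#' quadratic coefficient fixed at exactly 1: `Q - pH^2` is regressed on pH.
#' The returned object carries the coefficient of determination of the full
#' model as attribute `r_squared`, together with standard errors of the two
#' estimated coefficients (`se_c0`, `se_c1`).
#'
#' @param ph Numeric vector of pH values (at least 2 distinct).
#' @param charge Numeric vector of nominal charges, same length.
#' @param ph_range Validity range recorded on the result; defaults to the data
#'   range.
#' @return A [charge_polynomial()] with fit diagnostics attached.
#' @export
fit_charge_polynomial <- function(ph, charge, ph_range = range(ph)) {
  if (length(ph) != length(charge)) {
    stop("ph and charge must have the same length", call. = FALSE)
  }
  if (length(ph) < 2L || length(unique(ph)) < 2L) {
    stop("need at least 2 points with distinct pH to fit the charge polynomial",
         call. = FALSE)
  }
  fit <- .ols_line(ph, charge - ph^2)
  poly <- charge_polynomial(fit$intercept, -fit$slope, ph_range = ph_range)
  fitted_q <- poly$c0 - poly$c1 * ph + ph^2
  ss_res <- sum((charge - fitted_q)^2)
  ss_tot <- sum((charge - mean(charge))^2)
  attr(poly, "r_squared") <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  attr(poly, "se_c0") <- fit$stderr_intercept
  attr(poly, "se_c1") <- fit$stderr_slope
  poly
}

# Intrinsic pKa values for the ionizable groups of the Henderson-Hasselbalch
# null model. Any standard set is acceptable here: the model carries no
# structural pKa shifts by design.
.DEFAULT_PKA <- c(D = 3.65, E = 4.25, C = 8.5, Y = 10.0, H = 6.0,
                  K = 10.5, R = 12.5, Nterm = 9.0, Cterm = 3.1)

#' Default intrinsic pKa table
#'
#' Named vector of intrinsic pKa values for the ionizable side chains
#' (D, E, C, Y, H, K, R) and the chain termini (`Nterm`, `Cterm`), used by
#' [titration_charge()]. Override entries by passing a modified copy.
#'
#' @return Named numeric vector of pKa values.
#' @export
default_pka_table <- function() .DEFAULT_PKA

.CATIONIC <- c("K", "R", "H")
.ANIONIC <- c("D", "E", "C", "Y")

#' Sequence-based titration charge (Henderson-Hasselbalch null model)
#'
#' Net charge of a protein at a given pH from its sequence alone, summing
#' Henderson-Hasselbalch occupancies of the ionizable groups with intrinsic
#' (structure-free) pKa values: cationic groups (K, R, H, N-terminus)
#' contribute `+1/(1 + 10^(pH - pKa))`, anionic groups (D, E, C, Y,
#' C-terminus) contribute `-1/(1 + 10^(pKa - pH))`. This is a null model that
#' ignores all structural pKa shifts; it is monotone non-increasing in pH.
#'
#' @param sequence Amino-acid sequence in one-letter code (20 canonical
#'   residues), or a [protein_spec()] carrying one.
#' @param ph pH value(s); vectorized.
#' @param pka_table Named pKa vector in the format of [default_pka_table()].
#' @param include_termini Include the N/C terminal groups? Default `TRUE`.
#' @return Net charge in elementary charges, one value per element of `ph`.
#' @examples
#' titration_charge("DKE", 7)
#' @export
titration_charge <- function(sequence, ph, pka_table = default_pka_table(),
                             include_termini = TRUE) {
  if (inherits(sequence, "protein_spec")) {
    sequence <- sequence$sequence
    if (is.null(sequence)) stop("protein_spec has no sequence", call. = FALSE)
  }
  sequence <- .check_sequence(sequence)
  letters <- strsplit(sequence, "")[[1]]
  missing_pka <- setdiff(c(.CATIONIC, .ANIONIC, if (include_termini) c("Nterm", "Cterm")),
                         names(pka_table))
  if (length(missing_pka) > 0L) {
    stop("pka_table is missing entries for: ", paste(missing_pka, collapse = ", "),
         call. = FALSE)
  }
  cation_pka <- pka_table[letters[letters %in% .CATIONIC]]
  anion_pka <- pka_table[letters[letters %in% .ANIONIC]]
  if (include_termini) {
    cation_pka <- c(cation_pka, pka_table["Nterm"])
    anion_pka <- c(anion_pka, pka_table["Cterm"])
  }
  vapply(ph, function(p) {
    pos <- sum(1 / (1 + 10^(p - cation_pka)))
    neg <- sum(1 / (1 + 10^(anion_pka - p)))
    pos - neg
  }, numeric(1))
}

#' Tabulate a charge curve
#'
#' Evaluates [nominal_charge()] on a pH grid and returns a two-column data
#' frame, the same shape written by [write_charge_curve()].
#'
#' @param poly A [charge_polynomial()].
#' @param ph pH grid; default: 0.1-spaced over the validity range.
#' @return `data.frame(ph, charge)`.
#' @export
charge_curve <- function(poly, ph = seq(poly$ph_range[1], poly$ph_range[2], by = 0.1)) {
  data.frame(ph = ph, charge = nominal_charge(poly, ph))
}

#' Write a charge curve as two-column CSV
#'
#' @param curve A data frame with columns `ph` and `charge` (see
#'   [charge_curve()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_charge_curve <- function(curve, path) {
  stopifnot(all(c("ph", "charge") %in% names(curve)))
  write.csv(curve[c("ph", "charge")], path, row.names = FALSE)
  invisible(path)
}

#' Read a single sequence from a FASTA file
#'
#' Thin wrapper around \pkg{seqinr}'s FASTA reader returning one amino-acid
#' sequence as an upper-case string. A multi-record file is an error unless
#' `id` picks out the intended record.
#'
#' @param path FASTA file path.
#' @param id Optional record identifier to select from a multi-record file.
#' @return Amino-acid sequence string.
#' @export
read_fasta_sequence <- function(path, id = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  if (!requireNamespace("seqinr", quietly = TRUE)) {
    stop("the seqinr package is required to read FASTA files", call. = FALSE)
  }
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  if (is.null(id)) {
    if (length(recs) != 1L) {
      stop(sprintf("FASTA file has %d records; pass id= to select one",
                   length(recs)), call. = FALSE)
    }
    rec <- recs[[1]]
  } else {
    if (!id %in% names(recs)) {
      stop(sprintf("record '%s' not found in %s", id, path), call. = FALSE)
    }
    rec <- recs[[id]]
  }
  .check_sequence(as.character(rec))
}
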