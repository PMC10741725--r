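# Charge-vs-pH quadratic, isoelectric point, fitting, and the
# Henderson-Hasselbalch titration null model.

fgf21_poly <- charge_polynomial(55.9, 15.9)

test_that("nominal charge evaluates the quadratic in elementary charges", {
  expect_equal(nominal_charge(fgf21_poly, 4), 8.3, tolerance = 1e-12)
  expect_equal(round(nominal_charge(fgf21_poly, 4)), 8)
  expect_equal(nominal_charge(fgf21_poly, 8), -7.3, tolerance = 1e-12)
  expect_equal(nominal_charge(fgf21_poly, isoelectric_point(fgf21_poly)), 0,
               tolerance = 1e-9)
  expect_warning(nominal_charge(fgf21_poly, 10), "outside")
})

test_that("isoelectric point is the smaller quadratic root", {
  expect_equal(isoelectric_point(fgf21_poly), (15.9 - sqrt(15.9^2 - 4 * 55.9)) / 2,
               tolerance = 1e-12)
  expect_equal(round(isoelectric_point(fgf21_poly), 1), 5.2)
  # (pH - 2)(pH - 3) = pH^2 - 5 pH + 6
  expect_equal(isoelectric_point(charge_polynomial(6, 5)), 2.0, tolerance = 1e-12)
  expect_error(isoelectric_point(charge_polynomial(100, 10)), "no isoelectric point")
})

test_that("charge at the isoelectric point vanishes for random polynomials", {
  set.seed(7)
  for (i in 1:25) {
    c1 <- runif(1, 5, 25)
    c0 <- runif(1, 0.1, c1^2 / 4 - 0.1) # ensures a real root
    poly <- charge_polynomial(c0, c1, ph_range = c(0, 14))
    expect_equal(nominal_charge(poly, isoelectric_point(poly)), 0, tolerance = 1e-9)
  }
})

test_that("polynomial fit recovers coefficients exactly from noiseless data", {
  ph <- seq(4, 8, by = 0.5)
  q <- nominal_charge(fgf21_poly, ph)
  fit <- fit_charge_polynomial(ph, q)
  expect_equal(fit$c0, 55.9, tolerance = 1e-9)
  expect_equal(fit$c1, 15.9, tolerance = 1e-9)
  expect_equal(attr(fit, "r_squared"), 1, tolerance = 1e-9)
})

test_that("polynomial fit recovers random coefficients from noiseless data", {
  set.seed(11)
  ph <- seq(3, 9, length.out = 13)
  for (i in 1:20) {
    c0 <- runif(1, 10, 80)
    c1 <- runif(1, 5, 25)
    truth <- charge_polynomial(c0, c1, ph_range = c(3, 9))
    fit <- fit_charge_polynomial(ph, nominal_charge(truth, ph))
    expect_equal(fit$c0, c0, tolerance = 1e-9)
    expect_equal(fit$c1, c1, tolerance = 1e-9)
  }
})

test_that("polynomial fit on noisy data is unbiased within 3 standard errors", {
  set.seed(42)
  ph <- seq(4, 8, length.out = 50)
  q <- nominal_charge(fgf21_poly, ph) + rnorm(50, sd = 0.2)
  fit <- fit_charge_polynomial(ph, q)
  expect_lt(abs(fit$c0 - 55.9), 3 * attr(fit, "se_c0"))
  expect_lt(abs(fit$c1 - 15.9), 3 * attr(fit, "se_c1"))
})

test_that("degenerate fits are rejected", {
  expect_error(fit_charge_polynomial(5, 2), "at least 2")
  expect_error(fit_charge_polynomial(c(5, 5), c(1, 2)), "distinct")
})

test_that("titration charge matches the single-residue hand calculation", {
  # lone aspartate, termini off: -1/(1 + 10^(3.65 - 7))
  expect_equal(titration_charge("D", 7, include_termini = FALSE),
               -1 / (1 + 10^(3.65 - 7)), tolerance = 1e-12)
})

test_that("bare termini cancel at the midpoint of their pKa values", {
  pka <- default_pka_table()
  mid <- (pka[["Nterm"]] + pka[["Cterm"]]) / 2
  expect_equal(titration_charge("G", mid), 0, tolerance = 1e-12)
})

test_that("titration charge is non-increasing in pH with the right limits", {
  seqs <- c("MHKDERKYCD", "KKKK", "DDEE", "ACDEFGHIKLMNPQRSTVWY")
  grid <- seq(-2, 16, by = 0.25)
  for (s in seqs) {
    q <- titration_charge(s, grid)
    expect_true(all(diff(q) <= 1e-12))
    n_cat <- sum(strsplit(s, "")[[1]] %in% c("K", "R", "H")) + 1 # + N-terminus
    expect_equal(titration_charge(s, -20), n_cat, tolerance = 1e-6)
    expect_gt(titration_charge(s, 0), titration_charge(s, 14))
  }
})

test_that("titration rejects unknown residues and incomplete pKa tables", {
  expect_error(titration_charge("ADZ", 7), "non-canonical")
  expect_error(titration_charge("AD", 7, pka_table = c(D = 3.65)), "missing entries")
})

test_that("FASTA reading returns a single validated sequence", {
  path <- system.file("extdata", "synthetic_peptide.fasta", package = "adsorbkin")
  expect_identical(read_fasta_sequence(path), "MHKDERKYCD")
  multi <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDE", ">b", "KRH"), multi)
  expect_error(read_fasta_sequence(multi), "2 records")
  expect_identical(read_fasta_sequence(multi, id = "b"), "KRH")
})

test_that("charge curves serialize to two-column CSV", {
  curve <- charge_curve(fgf21_poly)
  expect_named(curve, c("ph", "charge"))
  path <- tempfile(fileext = ".csv")
  write_charge_curve(curve, path)
  back <- read.csv(path)
  expect_equal(back$charge, curve$charge, tolerance = 1e-9)
})
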