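# QCM-D: Sauerbrey conversion, hydration correction, per-overtone plateau
# analysis, CSV dialects.

test_that("Sauerbrey coverage is linear in shift and inverse overtone", {
  expect_equal(sauerbrey_coverage(0, 3), 0)
  expect_equal(sauerbrey_coverage(-27.1, 3), 0.177 * 27.1 / 3, tolerance = 1e-12)
  expect_equal(sauerbrey_coverage(-27.1, 3), 1.5989, tolerance = 1e-4)
  expect_equal(sauerbrey_coverage(-54.2, 3), 2 * sauerbrey_coverage(-27.1, 3),
               tolerance = 1e-12)
  g3 <- sauerbrey_coverage(-27.1, 3)
  g9 <- sauerbrey_coverage(-27.1, 9)
  expect_equal(g9, g3 / 3, tolerance = 1e-12)
})

test_that("positive shifts flag mass loss; invalid overtones error", {
  expect_warning(g <- sauerbrey_coverage(5, 3), "mass loss")
  expect_lt(g, 0)
  expect_error(sauerbrey_coverage(-1, 4), "odd")
  expect_error(sauerbrey_coverage(-1, -3), "odd")
})

test_that("Sauerbrey constant derives from quartz properties", {
  c5 <- sauerbrey_constant()
  expect_equal(c5, sqrt(2648 * 2.947e10) / (2 * 25e12) * 1e6, tolerance = 1e-12)
  expect_equal(round(c5, 3), 0.177)
  c10 <- sauerbrey_constant(qcm_constants(fundamental_frequency = 1e7))
  expect_equal(c10, c5 / 4, tolerance = 1e-12)
  expect_equal(c10, 0.04417, tolerance = 1e-4)
})

test_that("hydration correction behaves at its limits and round-trips", {
  expect_equal(dry_coverage(1.6, 0.5), 0.8, tolerance = 1e-12)
  expect_equal(dry_coverage(1.6, 0), 1.6)
  expect_equal(dry_coverage(1.6, 1), 0)
  expect_error(dry_coverage(1.6, 1.2), "hydration")
  for (h in c(0, 0.25, 0.5, 0.9, 0.99)) {
    expect_equal(dry_coverage(0.8 / (1 - h), h), 0.8, tolerance = 1e-12)
  }
})

# Build a trace whose post-rinse wet plateaus are exactly the requested
# values (flat post-rinse segment), used for the reported-plateau check.
make_plateau_trace <- function(wet_by_overtone, overtones, c_q = 0.177) {
  t <- seq(0, 3000, by = 1)
  rinse <- 1500
  shifts <- vapply(seq_along(overtones), function(i) {
    n <- overtones[i]
    wet_ads <- wet_by_overtone[i] * 1.2 # higher pre-rinse plateau
    wet <- pmin(wet_ads, wet_ads * t / 600)
    wet[t >= rinse] <- wet_by_overtone[i]
    -n * wet / c_q
  }, numeric(length(t)))
  qcm_trace(t, shifts, overtones, rinse_start = rinse)
}

test_that("reported post-rinse plateaus average to the dry coverage", {
  tr <- make_plateau_trace(c(1.7, 1.5), c(3, 11))
  res <- analyze_qcm_trace(tr, qcm_constants(hydration = 0.5))
  expect_equal(unname(res$wet_coverage_per_overtone["n3"]), 1.7, tolerance = 1e-9)
  expect_equal(unname(res$wet_coverage_per_overtone["n11"]), 1.5, tolerance = 1e-9)
  expect_equal(res$dry_coverage, 0.8, tolerance = 1e-9)
  # degenerate single-overtone subset
  res3 <- analyze_qcm_trace(tr, qcm_constants(hydration = 0.5), overtones = 3)
  expect_equal(res3$dry_coverage, 1.7 * 0.5, tolerance = 1e-9)
})

test_that("missing overtones produce an informative error", {
  tr <- make_plateau_trace(c(1.7, 1.5), c(3, 11))
  expect_error(analyze_qcm_trace(tr, overtones = c(3, 7)), "available: 3, 11")
})

test_that("zero-noise generation inverts exactly for every overtone", {
  tr <- generate_qcm_trace(hydration = 0.5, noise_sd = 0, slope = 2.2e-3,
                           plateau = 1.0, irreversible = 0.8)
  res <- analyze_qcm_trace(tr, qcm_constants(hydration = 0.5),
                           overtones = tr$overtones)
  # all overtones imply the same wet coverage (zero dispersion)
  expect_lt(diff(range(res$wet_coverage_per_overtone)), 1e-9)
  expect_equal(res$dry_coverage, 0.8, tolerance = 1e-6)
})

test_that("noisy generation recovers the dry plateau within 2%", {
  tr <- generate_qcm_trace(hydration = 0.5, overtones = c(3, 11), noise_sd = 0.2,
                           seed = 13, slope = 2.2e-3, plateau = 1.0,
                           irreversible = 0.8)
  res <- analyze_qcm_trace(tr, qcm_constants(hydration = 0.5))
  expect_lt(abs(res$dry_coverage - 0.8) / 0.8, 0.02)
  expect_lte(res$dry_coverage, mean(res$wet_coverage_per_overtone))
})

test_that("QCM traces round-trip through both CSV dialects", {
  tr <- generate_qcm_trace(noise_sd = 0.1, seed = 7, overtones = c(3, 5, 11))
  for (fmt in c("wide", "long")) {
    path <- tempfile(fileext = ".csv")
    write_qcm_trace(tr, path, format = fmt)
    back <- read_qcm_trace(path)
    expect_equal(back$overtones, tr$overtones)
    expect_equal(unname(back$shifts), unname(tr$shifts), tolerance = 1e-9)
    expect_equal(back$rinse_start, tr$rinse_start)
  }
})

test_that("qcm_trace constructor validates overtones and shapes", {
  expect_error(qcm_trace(0:10, matrix(0, 11, 1), 4), "odd")
  expect_error(qcm_trace(0:10, matrix(0, 5, 1), 3), "row")
  expect_error(qcm_trace(0:10, matrix(0, 11, 2), 3), "column")
})
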