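# Synthetic-data generators: inverse-pair identities at zero noise, seeded
# reproducibility, and noise structure.

test_that("generated adsorption traces have the prescribed slope and plateau", {
  for (shape in c("linear", "exponential")) {
    tr <- generate_owls_trace(slope = 5e-3, plateau = 1.0, noise_sd = 0,
                              dt = 0.5, shape = shape)
    d0 <- (tr$coverage[2] - tr$coverage[1]) / (tr$times[2] - tr$times[1])
    expect_equal(d0, 5e-3, tolerance = 2e-3)
    # the exponential shape approaches its plateau only asymptotically, so
    # at zero noise its tail is flagged as (infinitesimally) still rising
    p <- if (shape == "linear") {
      plateau_coverage(tr, "adsorption")
    } else {
      expect_warning(plateau_coverage(tr, "adsorption"), "rising")
      suppressWarnings(plateau_coverage(tr, "adsorption"))
    }
    expect_equal(p$mean, 1.0, tolerance = if (shape == "linear") 1e-9 else 1e-2)
  }
})

test_that("zero desorption rate freezes the trace after the rinse", {
  tr <- generate_owls_trace(slope = 5e-3, plateau = 1.0, irreversible = 0.5,
                            desorption_rate = 0, noise_sd = 0)
  post <- tr$coverage[tr$times >= tr$rinse_start]
  expect_lt(diff(range(post)), 1e-12)
  expect_equal(post[1], 1.0, tolerance = 1e-9)
})

test_that("generator parameter validation", {
  expect_error(generate_owls_trace(irreversible = 2, plateau = 1), "irreversible")
  expect_error(generate_owls_trace(slope = -1), "slope")
})

test_that("generators are bit-reproducible given a seed", {
  a <- generate_owls_trace(noise_sd = 0.01, seed = 9)
  b <- generate_owls_trace(noise_sd = 0.01, seed = 9)
  expect_identical(a$coverage, b$coverage)
  qa <- generate_qcm_trace(noise_sd = 0.2, seed = 9)
  qb <- generate_qcm_trace(noise_sd = 0.2, seed = 9)
  expect_identical(qa$shifts, qb$shifts)
  da <- generate_dls_series(sd = 0.15, seed = 9)
  db <- generate_dls_series(sd = 0.15, seed = 9)
  expect_identical(da$diameter_nm, db$diameter_nm)
  sa <- generate_streaming_potential(noise_sd = 1e-6, seed = 9)
  sb <- generate_streaming_potential(noise_sd = 1e-6, seed = 9)
  expect_identical(sa$streaming_potentials, sb$streaming_potentials)
})

test_that("each generator is the exact inverse of its analyzer at zero noise", {
  # flow-cell trace -> slope/plateau/irreversible
  tr <- generate_owls_trace(slope = 2.2e-3, plateau = 1.0, irreversible = 0.8,
                            noise_sd = 0)
  expect_equal(fit_initial_slope(tr)$slope, 2.2e-3, tolerance = 1e-9)
  expect_equal(irreversible_coverage(tr)$mean, 0.8, tolerance = 1e-6)
  # QCM trace -> dry coverage
  qtr <- generate_qcm_trace(hydration = 0.5, noise_sd = 0, irreversible = 0.8)
  expect_equal(analyze_qcm_trace(qtr, qcm_constants(hydration = 0.5))$dry_coverage,
               0.8, tolerance = 1e-6)
  # DLS series -> population means
  dls <- generate_dls_series(sd = 0)
  means <- tapply(dls$diameter_nm, dls$population, mean)
  expect_equal(as.numeric(means), c(3.7, 5.4), tolerance = 1e-12)
  # streaming potentials -> zeta
  sp <- generate_streaming_potential(zeta = 20, noise_sd = 0)
  expect_equal(zeta_from_streaming(sp)$zeta_mV, 20, tolerance = 1e-9)
})

test_that("DLS populations are stationary with recoverable means", {
  dls <- generate_dls_series(diameters = c(3.7, 5.4), sd = 0.15, seed = 21)
  for (p in 1:2) {
    sub <- dls[dls$population == p, ]
    se <- 0.15 / sqrt(nrow(sub))
    expect_lt(abs(mean(sub$diameter_nm) - c(3.7, 5.4)[p]), 3 * se)
    fit <- lm(diameter_nm ~ time_min, data = sub)
    slope_se <- sqrt(diag(stats::vcov(fit)))[[2]]
    expect_lt(abs(coef(fit)[2]), 3 * slope_se) # no trend
  }
})

test_that("generator noise is additive iid Gaussian", {
  clean <- generate_owls_trace(noise_sd = 0, dt = 1, duration = 3600)
  noisy <- generate_owls_trace(noise_sd = 0.02, dt = 1, duration = 3600, seed = 33)
  resid <- noisy$coverage - clean$coverage
  expect_equal(sd(resid), 0.02, tolerance = 0.1)
  expect_gt(stats::shapiro.test(resid[1:3000])$p.value, 1e-3)
  expect_lt(abs(mean(resid)), 3 * 0.02 / sqrt(length(resid)))
  # independence across overtones: residual correlation near zero
  qn <- generate_qcm_trace(noise_sd = 0.5, seed = 14, overtones = c(3, 5))
  q0 <- generate_qcm_trace(noise_sd = 0, overtones = c(3, 5))
  r1 <- qn$shifts[, 1] - q0$shifts[, 1]
  r2 <- qn$shifts[, 2] - q0$shifts[, 2]
  expect_lt(abs(stats::cor(r1, r2)), 0.1)
})
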