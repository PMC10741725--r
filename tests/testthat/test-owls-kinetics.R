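# Flow-cell kinetics: initial-slope extraction, transport-limited model,
# hydrodynamic-diameter inference by the direct and calibration routes,
# plateau and irreversible-coverage extraction.

cond298 <- solution_conditions(temperature = 298, viscosity = 8.9e-4)

test_that("initial slope is recovered exactly from noiseless traces", {
  for (s in c(2.2e-3, 5.5e-3)) {
    tr <- generate_owls_trace(slope = s, plateau = 1.0, noise_sd = 0)
    fit <- fit_initial_slope(tr)
    expect_equal(fit$slope, s, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("initial slope survives realistic noise within 5%", {
  tr <- generate_owls_trace(slope = 2.2e-3, plateau = 1.0, noise_sd = 0.005,
                            seed = 19)
  fit <- fit_initial_slope(tr)
  expect_lt(abs(fit$slope - 2.2e-3) / 2.2e-3, 0.05)
})

test_that("slope fitting demands enough samples", {
  tr <- kinetic_trace(seq(0, 1000, by = 200), seq(0, 1, length.out = 6),
                      bulk_concentration = 2, flow_rate = 1.1e-3)
  expect_error(fit_initial_slope(tr), "samples")
})

test_that("transport-limited coverage is linear in time and concentration", {
  g <- transport_limited_coverage(100, k_c0 = 2, diffusion = 1e-10,
                                  flow_rate = 1.1e-3, concentration = 2)
  expect_equal(transport_limited_coverage(0, 2, 1e-10, 1.1e-3, 2), 0)
  expect_equal(transport_limited_coverage(200, 2, 1e-10, 1.1e-3, 2), 2 * g,
               tolerance = 1e-12)
  expect_equal(transport_limited_coverage(100, 2, 1e-10, 1.1e-3, 4), 2 * g,
               tolerance = 1e-12)
  expect_error(transport_limited_coverage(-1, 2, 1e-10, 1.1e-3, 2), "non-negative")
})

test_that("forward model and slope inversion close the loop", {
  k_c0 <- 0.05
  D <- diffusion_coefficient(5.0, cond298)
  slope <- transport_limited_coverage(1, k_c0, D, 1.1e-3, 2)
  expect_equal(dh_from_slope(slope, 1.1e-3, 2, k_c0 = k_c0, cond = cond298), 5.0,
               tolerance = 1e-9)
})

test_that("direct route requires the mass-transfer constant", {
  expect_error(dh_from_slope(2.2e-3, 1.1e-3, 2), "dh_calibrated")
})

test_that("direct and calibration routes agree for a consistent cell constant", {
  set.seed(23)
  for (i in 1:20) {
    k_c0 <- runif(1, 0.01, 1)
    d_ref <- runif(1, 2, 12)
    q_ref <- runif(1, 5e-4, 5e-3)
    c_ref <- runif(1, 1, 10)
    s_ref <- k_c0 * diffusion_coefficient(d_ref, cond298)^(2 / 3) *
      q_ref^(1 / 3) * c_ref
    ref <- calibration_reference(d_ref, s_ref, q_ref, c_ref)
    s_exp <- runif(1, 5e-4, 5e-3)
    q_exp <- runif(1, 5e-4, 5e-3)
    c_exp <- runif(1, 1, 10)
    expect_equal(dh_calibrated(s_exp, q_exp, c_exp, ref),
                 dh_from_slope(s_exp, q_exp, c_exp, k_c0 = k_c0, cond = cond298),
                 tolerance = 1e-9)
  }
})

test_that("slope power law: D scales as slope^(3/2), d_H inversely", {
  k_c0 <- 0.1
  # scaling the slope by 2^(-2/3) halves D and therefore doubles d_H
  d1 <- dh_from_slope(1e-3, 1.1e-3, 2, k_c0 = k_c0, cond = cond298)
  d2 <- dh_from_slope(1e-3 * 2^(-2 / 3), 1.1e-3, 2, k_c0 = k_c0, cond = cond298)
  expect_equal(d2, 2 * d1, tolerance = 1e-9)
  # monotone decreasing in the slope, diverging as slope -> 0+
  expect_gt(dh_from_slope(1e-5, 1.1e-3, 2, k_c0 = k_c0, cond = cond298), d1)
})

test_that("calibration route reproduces the worked protein/albumin example", {
  d <- dh_calibrated(2.2e-3, flow_rate = 1.1e-3, concentration = 2,
                     ref = hsa_reference())
  expect_equal(d, 4.9749, tolerance = 1e-4)
  expect_equal(signif(d, 2), 5.0)
})

test_that("calibration route is exact under self-calibration and unit rescaling", {
  ref <- hsa_reference()
  expect_equal(dh_calibrated(ref$slope0, ref$flow_rate0, ref$concentration0, ref),
               ref$d_h0, tolerance = 1e-12)
  d0 <- dh_calibrated(2.2e-3, 1.1e-3, 2, ref)
  # common rescaling of slope, flow and concentration units cancels
  ref2 <- calibration_reference(ref$d_h0, ref$slope0 * 1e3,
                                ref$flow_rate0 * 60, ref$concentration0 * 1e-3)
  expect_equal(dh_calibrated(2.2e-3 * 1e3, 1.1e-3 * 60, 2e-3, ref2), d0,
               tolerance = 1e-12)
  # doubling concentration at fixed slope scales d_H by 2^(3/2)
  expect_equal(dh_calibrated(2.2e-3, 1.1e-3, 4, ref), d0 * 2^(3 / 2),
               tolerance = 1e-12)
})

test_that("plateau extraction averages the tail window", {
  t <- seq(0, 1000, by = 1)
  flat <- kinetic_trace(t, rep(0.8, length(t)), 2, 1.1e-3)
  p <- plateau_coverage(flat, "adsorption")
  expect_equal(p$mean, 0.8, tolerance = 1e-12)
  expect_equal(p$sd, 0, tolerance = 1e-12)
  tr <- generate_owls_trace(slope = 5e-3, plateau = 1.0, noise_sd = 0.01, seed = 5)
  expect_equal(plateau_coverage(tr, "adsorption")$mean, 1.0, tolerance = 0.01)
})

test_that("a still-rising tail is flagged", {
  t <- seq(0, 1000, by = 1)
  ramp <- kinetic_trace(t, 1e-3 * t + rnorm(length(t), sd = 1e-4), 2, 1.1e-3)
  expect_warning(p <- plateau_coverage(ramp, "adsorption"), "rising")
  expect_true(p$rising)
})

test_that("irreversible coverage recovers the generator's retained fraction", {
  for (g_irr in c(0.8, 0.2)) {
    tr <- generate_owls_trace(slope = 2.2e-3, plateau = 1.0, irreversible = g_irr,
                              noise_sd = 0.01, seed = 31)
    expect_equal(irreversible_coverage(tr)$mean, g_irr, tolerance = 0.01)
  }
  no_rinse <- kinetic_trace(0:100, rep(0.5, 101), 2, 1.1e-3)
  expect_error(irreversible_coverage(no_rinse), "rinse")
  # zero desorption: post-rinse plateau equals the adsorption plateau
  tr0 <- generate_owls_trace(slope = 2e-3, plateau = 1.0, irreversible = 1.0,
                             desorption_rate = 0, noise_sd = 0)
  expect_equal(irreversible_coverage(tr0)$mean,
               plateau_coverage(tr0, "adsorption")$mean, tolerance = 1e-9)
})

test_that("irreversible coverage never exceeds the adsorption plateau", {
  set.seed(57)
  for (i in 1:10) {
    plateau <- runif(1, 0.5, 2)
    frac <- runif(1) # desorbed fraction in [0, 1]
    tr <- generate_owls_trace(slope = 5e-3, plateau = plateau,
                              irreversible = plateau * (1 - frac), noise_sd = 0)
    expect_lte(irreversible_coverage(tr)$mean,
               plateau_coverage(tr, "adsorption")$mean + 1e-9)
  }
})

test_that("full loop recovers slope, plateau and retained coverage within 5%", {
  truth <- list(slope = 2.2e-3, plateau = 1.0, irreversible = 0.8)
  tr <- generate_owls_trace(slope = truth$slope, plateau = truth$plateau,
                            irreversible = truth$irreversible,
                            noise_sd = 0.01, seed = 101)
  fit <- fit_initial_slope(tr)
  expect_lt(abs(fit$slope - truth$slope) / truth$slope, 0.05)
  expect_lt(abs(plateau_coverage(tr, "adsorption")$mean - truth$plateau) /
              truth$plateau, 0.05)
  expect_lt(abs(irreversible_coverage(tr)$mean - truth$irreversible) /
              truth$irreversible, 0.05)
})

test_that("kinetic traces round-trip through CSV with their sidecar", {
  tr <- generate_owls_trace(noise_sd = 0.01, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_kinetic_trace(tr, path)
  back <- read_kinetic_trace(path)
  expect_equal(back$coverage, tr$coverage, tolerance = 1e-9)
  expect_equal(back$rinse_start, tr$rinse_start)
  expect_equal(back$bulk_concentration, tr$bulk_concentration)
  # explicit arguments override the sidecar
  back2 <- read_kinetic_trace(path, bulk_concentration = 5)
  expect_equal(back2$bulk_concentration, 5)
})

test_that("trace constructor enforces its invariants", {
  expect_error(kinetic_trace(c(0, 1, 1), c(0, 0, 0), 2, 1e-3), "increasing")
  expect_error(kinetic_trace(0:2, c(0, NA, 0), 2, 1e-3), "finite")
  expect_error(kinetic_trace(0:2, c(0, 0, 0), 2, 1e-3, adsorption_start = 5,
                             rinse_start = 1), "rinse_start")
})

test_that("trace analysis report carries slope, plateaus and diameter", {
  tr <- generate_owls_trace(slope = 2.2e-3, plateau = 1.0, irreversible = 0.8,
                            noise_sd = 0.005, seed = 77)
  rep <- analyze_owls_trace(tr, ref = hsa_reference())
  expect_equal(rep$d_h_route, "calibration")
  expect_equal(rep$d_h, 5.0, tolerance = 0.1)
  expect_equal(rep$irreversible$mean, 0.8, tolerance = 0.01)
  path <- tempfile(fileext = ".json")
  write_owls_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$d_h_nm, rep$d_h, tolerance = 1e-9)
})
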