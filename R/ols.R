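# Closed-form simple linear regression. Equivalent to lm(y ~ x) but with
# standard errors computed directly, so zero-residual (exact) fits do not
# trip summary.lm's perfect-fit warning; exact fits are routine here (clean
# synthetic traces, noiseless calibration lines).
.ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) stop("regressor has no variation", call. = FALSE)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  ss_res <- sum(res^2)
  ss_tot <- sum((y - my)^2)
  s2 <- if (n > 2) ss_res / (n - 2) else NA_real_
  list(slope = slope, intercept = intercept,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       stderr_slope = sqrt(s2 / sxx),
       stderr_intercept = sqrt(s2 * (1 / n + mx^2 / sxx)),
       n = n)
}
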