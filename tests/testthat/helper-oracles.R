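# Brute-force Poisson lambda estimator: numerically maximise the binomial
# log-likelihood of observing `p` positives among `t` partitions when the
# positive probability is 1 - exp(-lambda). Independent of the closed form.
oracle_lambda <- function(p, t, upper = 25) {
  if (p == 0) {
    return(0)
  }
  stats::optimize(
    function(l) stats::dbinom(p, t, 1 - exp(-l), log = TRUE),
    interval = c(1e-12, upper), maximum = TRUE, tol = 1e-10
  )$maximum
}

# Ordinary least squares by direct normal equations (oracle for the
# unit-weight calibration fit).
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}

# One full coverage experiment: calibrate on n_cal pure reference pairs and
# measure the fraction of n_new new pure samples inside the 95% PI.
coverage_experiment <- function(n_cal = 72, n_new = 2000, cv = 0.10) {
  cal <- simulate_calibration(n_cal, c(1e3, 1e5), cv)
  m <- fit_calibration(cal, variance_power = 2)
  new <- simulate_calibration(n_new, c(1e3, 1e5), cv)
  pi <- prediction_interval(m, new$ce, level = 0.95)
  mean(new$cm >= pi$lCe & new$cm <= pi$uCe)
}
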