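test_that("a perfect line is recovered exactly", {
  pts <- data.frame(ce = 10^seq(3, 5, length.out = 10))
  pts$cm <- pts$ce
  m <- suppressWarnings(fit_calibration(pts)) # exact data: perfect-fit note
  expect_equal(m$slope, 1, tolerance = 1e-10)
  expect_equal(m$intercept, 0, tolerance = 1e-6)
  expect_lt(m$sigma2, 1e-15)
  expect_equal(m$dof, 8L)

  # zero-noise limit: interval collapses onto the fitted line
  pi <- prediction_interval(m, c(2e3, 5e4))
  expect_equal(pi$lCe, pi$fit, tolerance = 1e-5)
  expect_equal(pi$uCe, pi$fit, tolerance = 1e-5)
})

test_that("unit weights reproduce ordinary least squares exactly", {
  set.seed(31)
  ce <- 10^runif(40, 3, 5)
  cm <- 50 + 1.1 * ce + rnorm(40, 0, 500)
  m <- fit_calibration(data.frame(ce = ce, cm = cm), variance_power = 0)
  cf <- oracle_ols(ce, cm)
  expect_equal(m$intercept, cf[1], tolerance = 1e-9)
  expect_equal(m$slope, cf[2], tolerance = 1e-9)
})

test_that("through-origin fit on collinear points returns the exact ratio", {
  pts <- data.frame(ce = c(1000, 4000, 9000), cm = c(1138, 4552, 10242))
  m <- suppressWarnings(
    fit_calibration(pts, through_origin = TRUE)
  )
  expect_equal(m$slope, 1.138, tolerance = 1e-12)
  expect_equal(m$intercept, 0)
  expect_equal(m$dof, 2L)
})

test_that("slope is recovered within its confidence interval", {
  # multiplicative-noise calibration around slope 1.138
  set.seed(144)
  ce <- 10^runif(144, 3, 5)
  cm <- 1.138 * ce * (1 + rnorm(144, 0, 0.1))
  m <- fit_calibration(data.frame(ce = ce, cm = cm))
  se_slope <- sqrt(m$coefficient_covariance[2, 2])
  expect_lt(abs(m$slope - 1.138), qt(0.975, m$dof) * se_slope)

  # unbiased data recovers slope 1 within Monte-Carlo error
  set.seed(145)
  slopes <- replicate(40, {
    ce <- 10^runif(72, 3, 5)
    cm <- ce * (1 + rnorm(72, 0, 0.1))
    fit_calibration(data.frame(ce = ce, cm = cm))$slope
  })
  expect_lt(abs(mean(slopes) - 1), 3 * sd(slopes) / sqrt(40))
})

test_that("degenerate calibration inputs are rejected or warned about", {
  expect_error(fit_calibration(data.frame(ce = c(1, 2), cm = c(1, 2))),
    "at least 3")
  expect_error(
    fit_calibration(data.frame(ce = rep(10, 6), cm = 1:6)),
    "identical"
  )
  few <- data.frame(ce = c(10, 12, 14, 16))
  few$cm <- few$ce * c(1.01, 0.99, 1.02, 0.98)
  expect_warning(expect_warning(fit_calibration(few), "fewer than 5"),
    "order of magnitude")
  narrow <- data.frame(ce = seq(100, 500, length.out = 8))
  narrow$cm <- narrow$ce * (1 + c(0.01, -0.01, 0.02, -0.02, 0.01, 0, -0.01, 0.02))
  expect_warning(fit_calibration(narrow), "order of magnitude")
  m <- suppressWarnings(fit_calibration(data.frame(
    ce = 10^seq(3, 5, length.out = 8),
    cm = 10^seq(3, 5, length.out = 8)
  )))
  expect_error(prediction_interval(m, -5), "ce")
})

test_that("constant-CV interval half-width scales linearly in ce", {
  set.seed(9)
  ce <- 10^runif(100, 3, 5)
  cm <- ce * (1 + rnorm(100, 0, 0.1))
  m <- fit_calibration(data.frame(ce = ce, cm = cm))
  pi <- prediction_interval(m, c(1e4, 2e4))
  half <- (pi$uCe - pi$lCe) / 2
  # with gamma = 2 and negligible line variance, half-width doubles with ce
  expect_equal(half[2] / half[1], 2, tolerance = 0.02)
  # ordering and monotone width
  pi_all <- prediction_interval(m, 10^seq(3, 5, length.out = 25))
  expect_true(all(pi_all$lCe < pi_all$fit & pi_all$fit < pi_all$uCe))
  expect_true(all(diff(pi_all$uCe - pi_all$lCe) > 0))
})

test_that("empirical variance power recovers the generating exponent", {
  set.seed(21)
  ce <- 10^runif(300, 3, 5)
  cm <- ce + rnorm(300, 0, sqrt(0.01 * ce^2))
  m <- fit_calibration(data.frame(ce = ce, cm = cm),
    variance_power = "estimate")
  expect_lt(abs(m$variance_power - 2), 0.5)
})

test_that("prediction-interval coverage is close to nominal", {
  set.seed(61)
  covs <- replicate(8, coverage_experiment(n_cal = 72, n_new = 500))
  expect_lt(abs(mean(covs) - 0.95), 0.02)
})

test_that("lower bound below zero is clamped and flagged", {
  # wide noise at small ce pushes the lower bound negative
  set.seed(8)
  ce <- 10^runif(30, 1, 3)
  cm <- ce * (1 + rnorm(30, 0, 0.6))
  cm[cm < 0] <- 0.1
  m <- fit_calibration(data.frame(ce = ce, cm = cm))
  pi <- prediction_interval(m, 10)
  expect_true(pi$below_range)
  expect_gt(pi$lCe, 0)
})

test_that("model serialisation round-trips through JSON", {
  set.seed(3)
  ce <- 10^runif(20, 3, 5)
  cm <- ce * (1 + rnorm(20, 0, 0.1))
  m <- fit_calibration(data.frame(ce = ce, cm = cm))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(m, path, provenance = list(species = "Crocus sativus"))
  m2 <- read_calibration(path)
  expect_equal(m2$slope, m$slope)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$sigma2, m$sigma2)
  expect_equal(m2$coefficient_covariance, m$coefficient_covariance)
  expect_equal(m2$dof, m$dof)
  pi1 <- prediction_interval(m, 1e4)
  pi2 <- prediction_interval(m2, 1e4)
  expect_equal(pi2$lCe, pi1$lCe)
  expect_equal(pi2$uCe, pi1$uCe)
  expect_error(read_calibration(system.file("extdata", "species.csv",
    package = "dnaccounting")))
})
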