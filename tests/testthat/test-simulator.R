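test_that("fluorometry noise is multiplicative, unbiased and averaged", {
  cfg0 <- simulation_config(fluorometry_cv = 0)
  expect_equal(simulate_fluorometry(42.03, cfg0), 42.03)
  expect_equal(simulate_fluorometry(0, simulation_config()), 0)

  set.seed(22)
  cfg <- simulation_config(fluorometry_cv = 0.05, fluorometry_reads = 4)
  reps <- replicate(1e4, simulate_fluorometry(42.03, cfg))
  expect_lt(abs(mean(reps) / 42.03 - 1), 0.005)
  # averaging four reads cuts the CV roughly in half
  expect_lt(sd(reps) / mean(reps), 0.05 / sqrt(4) * 1.1)
})

test_that("simulated reactions match the forecast partition occupancy", {
  cfg0 <- simulation_config(
    fluorometry_cv = 0, pipetting_cv = 0, n_droplets = 15000
  )
  set.seed(33)
  expect_equal(simulate_reaction(0, 10, cfg0)$positives, 0L)

  # 127 copies/ng x 10 ng -> lambda 0.053975, ~788 positives expected
  pos <- replicate(300, simulate_reaction(127, 10, cfg0)$positives)
  lam_true <- 127 * 10 * 0.00085 / 20
  expect_equal(lam_true, 0.053975)
  expect_lt(abs(mean(pos) - 15000 * (1 - exp(-lam_true))), 3 * sd(pos) / sqrt(300))
  expect_lt(abs(mean(pos) - 788), 10)

  # round-trip at 1e5 droplets: estimated lambda recovers the truth
  cfgL <- simulation_config(
    fluorometry_cv = 0, pipetting_cv = 0, n_droplets = 1e5
  )
  dc <- simulate_reaction(127, 100, cfgL)
  lam_t <- attr(dc, "truth")$lambda_true
  est <- estimate_lambda(dc)
  se <- sqrt(exp(lam_t) / 1e5) # binomial error mapped through -ln
  expect_lt(abs(est$lam - lam_t), 4 * se)

  expect_warning(
    simulate_reaction(127, 2e4, simulation_config(fluorometry_cv = 0)),
    "saturation"
  )
})

test_that("admixture dilutes the target by the extractability-weighted fraction", {
  s <- saffron_params()
  cfg0 <- simulation_config(fluorometry_cv = 0, pipetting_cv = 0,
    n_droplets = 1e5)
  set.seed(44)

  # w = 0 reduces to the pure simulation
  dc0 <- simulate_admixture(0, 1, s, 10, cfg0)
  expect_equal(attr(dc0, "truth")$lambda_true, 127.0648 * 10 * 0.00085 / 20,
    tolerance = 1e-4)

  # w = 0.5, r = 1 halves the target fraction
  dc1 <- simulate_admixture(0.5, 1, s, 10, cfg0)
  expect_equal(
    attr(dc1, "truth")$lambda_true,
    attr(dc0, "truth")$lambda_true / 2,
    tolerance = 1e-12
  )

  # 5% of a high-yield adulterant (r = 20) already halves the template
  f <- (1 - 0.05) / ((1 - 0.05) + 0.05 * 20)
  expect_equal(f, 0.487, tolerance = 1e-3)
  dc2 <- simulate_admixture(0.05, 20, s, 10, cfg0)
  expect_equal(attr(dc2, "truth")$lambda_true,
    f * attr(dc0, "truth")$lambda_true,
    tolerance = 1e-12)

  # total adulteration with no target -> all-negative wells
  dc3 <- simulate_admixture(1, 1, s, 10, cfg0)
  expect_equal(dc3$positives, 0L)
})

test_that("market population recovers its configured mean ratio", {
  set.seed(55)
  cfg <- simulation_config()
  one <- simulate_market(1, 143,
    population_cv = 0,
    cfg = simulation_config(fluorometry_cv = 0, pipetting_cv = 0)
  )
  expect_equal(one$truth$true_ratio, 143)

  sim <- simulate_market(1000, 143, 0.28, cfg)
  se <- 143 * 0.28 / sqrt(1000)
  expect_lt(abs(mean(sim$truth$true_ratio) - 143), 2.5 * se)
  expect_true(all(sim$truth$true_ratio >= 0))
  expect_equal(nrow(sim$droplets), 2000L)
  # duplicate wells share the sample's single fluorometric determination
  ng <- tapply(sim$droplets$dna_ng, sim$droplets$sample_id, function(x) {
    length(unique(x))
  })
  expect_true(all(ng == 1L))
})

test_that("measured signal falls with admixture fraction and extractability", {
  set.seed(66)
  cfg <- simulation_config()
  s <- saffron_params()

  # mean measured ratio (copies per nominal ng) over replicate reactions
  mean_ratio <- function(w, r, nrep = 60) {
    mean(replicate(nrep, {
      dc <- simulate_admixture(w, r, s, 10, cfg)
      measured_copies(estimate_lambda(dc)) / 10
    }))
  }

  # strictly decreasing in w for both a high- and a low-yield adulterant
  w_grid <- c(0, 0.05, 0.10, 0.20, 0.30)
  fast <- vapply(w_grid, mean_ratio, numeric(1), r = 20)
  slow <- vapply(w_grid, mean_ratio, numeric(1), r = 0.3)
  expect_true(all(diff(fast) < 0))
  expect_true(all(diff(slow) < 0))
  # strictly decreasing in r at fixed w, and fast-yield drops further
  pr <- vapply(c(0.3, 1, 5, 20), function(r) mean_ratio(0.10, r), numeric(1))
  expect_true(all(diff(pr) < 0))
  expect_lt(fast[3] / fast[1], slow[3] / slow[1])
})

test_that("identical seeds give identical simulations", {
  run <- function() {
    cfg <- simulation_config(seed = 99L)
    simulate_market(5, 143, 0.2, cfg)
  }
  expect_identical(run(), run())
})
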