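#' Simulation configuration
#'
#' Parameters of the synthetic ddPCR experiment generator. Defaults mirror a
#' routine droplet workflow on concentrated plant extracts: ~15,000 accepted
#' droplets per well at the QX200 partition geometry, fluorometric DNA
#' quantification as the mean of four reads with 5% per-read CV, 3%
#' pipetting CV, ~0.5% rain, and 5-15 ng template per reaction.
#'
#' @param seed Integer seed; every stochastic generator in the package draws
#'   from the R session RNG, so set it via [set.seed()] or pass it here to
#'   have the constructor set it for you (`NA` leaves the RNG untouched).
#' @param n_droplets Accepted droplets per well.
#' @param partition A [partition_config()].
#' @param fluorometry_cv Per-read coefficient of variation of the
#'   fluorometric concentration measurement.
#' @param fluorometry_reads Reads averaged per sample.
#' @param pipetting_cv CV of the dispensed template volume.
#' @param rain_fraction Fraction of droplets with intermediate amplitude.
#' @param dna_ng_range Length-2 numeric: range of template mass per reaction.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = NA_integer_,
                              n_droplets = 15000L,
                              partition = partition_config(),
                              fluorometry_cv = 0.05,
                              fluorometry_reads = 4L,
                              pipetting_cv = 0.03,
                              rain_fraction = 0.005,
                              dna_ng_range = c(5, 15)) {
  stopifnot(
    inherits(partition, "partition_config"),
    n_droplets >= 1, fluorometry_cv >= 0, fluorometry_reads >= 1,
    pipetting_cv >= 0, rain_fraction >= 0, rain_fraction < 1,
    length(dna_ng_range) == 2L, dna_ng_range[1] > 0,
    dna_ng_range[1] <= dna_ng_range[2]
  )
  if (!is.na(seed)) set.seed(as.integer(seed))
  structure(
    list(
      seed = seed,
      n_droplets = as.integer(n_droplets),
      partition = partition,
      fluorometry_cv = fluorometry_cv,
      fluorometry_reads = as.integer(fluorometry_reads),
      pipetting_cv = pipetting_cv,
      rain_fraction = rain_fraction,
      dna_ng_range = as.numeric(dna_ng_range)
    ),
    class = "simulation_config"
  )
}

# Multiplicative lognormal noise with unit mean and the given CV.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a fluorometric DNA concentration measurement
#'
#' Emulates fluorometric quantification as the mean of several reads, each
#' carrying multiplicative lognormal noise (unit mean, CV
#' `cfg$fluorometry_cv`) around the true concentration, so the averaged
#' estimate is unbiased with CV reduced by the square root of the number of
#' reads.
#'
#' @param true_ng_per_ul True concentration (>= 0); vectorised.
#' @param cfg A [simulation_config()].
#' @return Measured concentrations, same length as input.
#' @export
simulate_fluorometry <- function(true_ng_per_ul, cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  true_ng_per_ul <- as.numeric(true_ng_per_ul)
  if (any(true_ng_per_ul < 0)) stop("concentration must be >= 0", call. = FALSE)
  vapply(true_ng_per_ul, function(x) {
    if (x == 0) {
      return(0)
    }
    mean(x * rlnorm_cv(cfg$fluorometry_reads, cfg$fluorometry_cv))
  }, numeric(1))
}

#' Simulate one ddPCR reaction
#'
#' Inverts the copies-per-reaction relation to obtain the true mean copies
#' per partition `lambda = copies * Vp / Vs`, applies multiplicative
#' pipetting noise to the dispensed template mass, and draws the positive
#' count from `Binomial(n_droplets, 1 - exp(-lambda))` (Poisson partition
#' occupancy). The returned record carries the fluorometry-measured template
#' mass, not the truth, so downstream copy forecasting inherits realistic
#' quantification error.
#'
#' @param true_copies_per_ng True target copies per ng of this template.
#' @param dna_ng Nominal template mass dispensed into the reaction (> 0).
#' @param cfg A [simulation_config()].
#' @param sample_id,well_id Labels for the returned record.
#' @return A [droplet_count()] row, plus attribute `truth` (list with
#'   `lambda_true`, `dna_ng_true`, `copies_true`).
#' @export
simulate_reaction <- function(true_copies_per_ng, dna_ng,
                              cfg = simulation_config(),
                              sample_id = "sim", well_id = "W01") {
  stopifnot(
    inherits(cfg, "simulation_config"),
    true_copies_per_ng >= 0, dna_ng > 0
  )
  dna_true <- dna_ng * rlnorm_cv(1, cfg$pipetting_cv)
  copies <- true_copies_per_ng * dna_true
  lambda_true <- copies * cfg$partition$partition_volume_ul /
    cfg$partition$sample_volume_ul
  if (lambda_true >= log(cfg$n_droplets)) {
    warning(
      sprintf(
        "true lambda %.2f approaches saturation; expect all-positive wells",
        lambda_true
      ),
      call. = FALSE
    )
  }
  positives <- stats::rbinom(1, cfg$n_droplets, 1 - exp(-lambda_true))
  measured_ng <- simulate_fluorometry(dna_ng, cfg)
  out <- droplet_count(
    well_id = well_id, sample_id = sample_id,
    positives = positives, total = cfg$n_droplets, dna_ng = measured_ng
  )
  attr(out, "truth") <- list(
    lambda_true = lambda_true, dna_ng_true = dna_true, copies_true = copies
  )
  out
}

#' Simulate a ddPCR reaction on an admixed sample
#'
#' Models a weight fraction `w` of adulterant mixed into authentic material.
#' The adulterant carries no target sequence (the method's core assumption);
#' it affects the measurement only by diluting the target-bearing template.
#' With extractability ratio `r` (adulterant DNA yield per mg over authentic
#' yield per mg), the target-bearing fraction of the extracted template is
#' \deqn{f = \frac{1 - w}{(1 - w) + w r}}
#' so the effective copies/ng of the extract is `f` times the pure value.
#' Adulterants that yield DNA more efficiently than the authentic species
#' (`r > 1`, e.g. safflower in saffron) depress the purity much faster than
#' poorly extractable ones (`r < 1`).
#'
#' @param w_adulterant Adulterant mass fraction, w/w in \[0, 1\].
#' @param extractability_ratio Ratio `r` (> 0).
#' @param params [species_genome_params()] of the authentic species.
#' @param dna_ng Nominal template mass (> 0).
#' @param cfg A [simulation_config()].
#' @param sample_id,well_id Labels.
#' @return A [droplet_count()] row (see [simulate_reaction()]).
#' @export
simulate_admixture <- function(w_adulterant, extractability_ratio, params,
                               dna_ng, cfg = simulation_config(),
                               sample_id = "admix", well_id = "W01") {
  stopifnot(
    w_adulterant >= 0, w_adulterant <= 1, extractability_ratio > 0,
    inherits(params, "species_genome_params")
  )
  w <- w_adulterant
  r <- extractability_ratio
  f <- if (w >= 1) 0 else (1 - w) / ((1 - w) + w * r)
  simulate_reaction(
    true_copies_per_ng = f * copies_per_ng(params),
    dna_ng = dna_ng, cfg = cfg,
    sample_id = sample_id, well_id = well_id
  )
}

#' Simulate a market population of samples
#'
#' Draws each sample's true copies-per-ng ratio from a normal population
#' truncated at zero (re-drawing negatives), emulating the biological and
#' processing variation among authentic commercial samples, then simulates
#' replicate wells per sample with template mass uniform over
#' `cfg$dna_ng_range`.
#'
#' @param n_samples Number of samples (>= 1).
#' @param population_mean_cpn Population mean copies/ng.
#' @param population_cv Population CV of the true ratio (>= 0).
#' @param cfg A [simulation_config()].
#' @param replicates Wells per sample; default 2 (duplicate analysis).
#' @param sample_prefix Prefix for generated sample ids.
#' @return List with `droplets` (droplet-dialect data frame, one row per
#'   well), `samples` (sample sheet: `sample_id`, `dna_ng`), and `truth`
#'   (ground-truth sidecar: `sample_id`, `true_ratio`, `true_lambda`,
#'   `dna_ng_nominal`).
#' @export
simulate_market <- function(n_samples, population_mean_cpn,
                            population_cv = 0,
                            cfg = simulation_config(),
                            replicates = 2L,
                            sample_prefix = "S") {
  stopifnot(
    n_samples >= 1, population_mean_cpn >= 0, population_cv >= 0,
    replicates >= 1
  )
  sd_cpn <- population_mean_cpn * population_cv
  true_cpn <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    repeat {
      v <- stats::rnorm(1, population_mean_cpn, sd_cpn)
      if (v >= 0) break
    }
    true_cpn[i] <- v
  }
  dna_ng <- stats::runif(n_samples, cfg$dna_ng_range[1], cfg$dna_ng_range[2])
  ids <- sprintf("%s%04d", sample_prefix, seq_len(n_samples))

  rows <- vector("list", n_samples * replicates)
  lam_true <- numeric(n_samples)
  meas_ng <- numeric(n_samples)
  k <- 0L
  for (i in seq_len(n_samples)) {
    for (j in seq_len(replicates)) {
      k <- k + 1L
      rec <- simulate_reaction(
        true_copies_per_ng = true_cpn[i], dna_ng = dna_ng[i], cfg = cfg,
        sample_id = ids[i], well_id = sprintf("%s_W%02d", ids[i], j)
      )
      rows[[k]] <- as.data.frame(rec)
      lam_true[i] <- attr(rec, "truth")$lambda_true
    }
    # one fluorometric determination per sample, shared by its wells
    meas_ng[i] <- rows[[k]]$dna_ng
  }
  droplets <- do.call(rbind, rows)
  for (i in seq_len(n_samples)) {
    droplets$dna_ng[droplets$sample_id == ids[i]] <- meas_ng[i]
  }
  rownames(droplets) <- NULL
  list(
    droplets = droplets,
    samples = data.frame(
      sample_id = ids, dna_ng = meas_ng,
      stringsAsFactors = FALSE
    ),
    truth = data.frame(
      sample_id = ids, true_ratio = true_cpn,
      true_lambda = lam_true, dna_ng_nominal = dna_ng,
      stringsAsFactors = FALSE
    )
  )
}

#' Simulate a calibration set of pure reference samples
#'
#' Reference samples spanning a wide expected-copy range (log-spaced), each
#' measured in replicate wells that are pooled downstream. Multiplicative
#' noise of the stated CV acts on the true copy number of each sample
#' (lumping pipetting and quantification error), on top of binomial droplet
#' partitioning, which generates exactly the variance-growing-with-signal
#' structure the weighted calibration fit expects.
#'
#' @param n_samples Number of reference samples.
#' @param ce_range Length-2: range of expected copies to span (log-spaced).
#' @param cv Multiplicative CV of the true copy number; default 0.10.
#' @param cfg A [simulation_config()].
#' @param replicates Wells per sample; default 2.
#' @return Data frame of calibration points: `sample_id`, `ce` (nominal
#'   expected copies), `cm` (pooled measured copies).
#' @export
simulate_calibration <- function(n_samples = 72,
                                 ce_range = c(1e3, 1e5),
                                 cv = 0.10,
                                 cfg = simulation_config(),
                                 replicates = 2L) {
  stopifnot(
    n_samples >= 2, length(ce_range) == 2L, ce_range[1] > 0,
    ce_range[2] > ce_range[1], cv >= 0, replicates >= 1
  )
  ce <- exp(seq(log(ce_range[1]), log(ce_range[2]), length.out = n_samples))
  Vs <- cfg$partition$sample_volume_ul
  Vp <- cfg$partition$partition_volume_ul
  cm <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    true_copies <- ce[i] * rlnorm_cv(1, cv)
    lambda_true <- true_copies * Vp / Vs
    pos <- stats::rbinom(replicates, cfg$n_droplets, 1 - exp(-lambda_true))
    pooled_lam <- -log(1 - sum(pos) / (replicates * cfg$n_droplets))
    cm[i] <- pooled_lam * Vs / Vp
  }
  data.frame(
    sample_id = sprintf("CAL%03d", seq_len(n_samples)),
    ce = ce, cm = cm, stringsAsFactors = FALSE
  )
}

#' Simulate droplet fluorescence amplitudes
#'
#' Two Gaussian amplitude clusters (negative and positive) plus a small
#' uniform band of intermediate "rain" droplets; intended as input for the
#' minimal threshold caller.
#'
#' @param n_positive,n_negative Cluster sizes.
#' @param neg_mean,pos_mean Cluster centres; spreads are 5% of the centre.
#' @param rain_fraction Fraction of all droplets re-assigned to the rain
#'   band between the clusters.
#' @return List with `amplitudes` and the ground-truth `n_positive` (rain
#'   droplets excluded from the positive count).
#' @export
simulate_amplitudes <- function(n_positive, n_negative,
                                neg_mean = 1000, pos_mean = 9000,
                                rain_fraction = 0) {
  stopifnot(n_positive >= 0, n_negative >= 0, rain_fraction >= 0, rain_fraction < 1)
  n <- n_positive + n_negative
  n_rain <- round(rain_fraction * n)
  amp <- c(
    stats::rnorm(n_negative, neg_mean, 0.05 * neg_mean),
    stats::rnorm(n_positive, pos_mean, 0.05 * pos_mean),
    stats::runif(n_rain, neg_mean + 3 * 0.05 * neg_mean, pos_mean - 3 * 0.05 * pos_mean)
  )
  list(amplitudes = sample(amp), n_positive = n_positive)
}
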