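#' Droplet partition geometry
#'
#' Volumes converting the mean copies-per-partition (lambda) into copies per
#' reaction: `cm = lambda * Vs / Vp`. Defaults are the QX200 droplet
#' geometry: partition volume 0.00085 uL, sample volume 20 uL.
#'
#' @param partition_volume_ul Single-partition volume Vp in microliters (> 0).
#' @param sample_volume_ul Reaction volume Vs in microliters (> 0); must
#'   exceed the partition volume.
#' @return An object of class `partition_config`.
#' @export
partition_config <- function(partition_volume_ul = 0.00085,
                             sample_volume_ul = 20) {
  stopifnot(
    is.numeric(partition_volume_ul), partition_volume_ul > 0,
    is.numeric(sample_volume_ul), sample_volume_ul > 0
  )
  if (sample_volume_ul / partition_volume_ul <= 1) {
    stop("sample volume must exceed partition volume", call. = FALSE)
  }
  structure(
    list(
      partition_volume_ul = partition_volume_ul,
      sample_volume_ul = sample_volume_ul
    ),
    class = "partition_config"
  )
}

#' Per-well droplet counts
#'
#' One validated record per ddPCR well: positive and total accepted
#' partitions plus the template mass loaded into the reaction.
#'
#' @param well_id Well label.
#' @param sample_id Sample the well belongs to.
#' @param positives Number of positive partitions (0 <= positives <= total).
#' @param total Total accepted partitions (> 0).
#' @param dna_ng Template DNA mass in the reaction, ng (>= 0).
#' @return A one-row data frame of class `droplet_count`.
#' @export
droplet_count <- function(well_id, sample_id, positives, total, dna_ng) {
  positives <- as.integer(positives)
  total <- as.integer(total)
  dna_ng <- as.numeric(dna_ng)
  if (is.na(total) || total <= 0L) stop("'total' must be > 0", call. = FALSE)
  if (is.na(positives) || positives < 0L || positives > total) {
    stop("'positives' must satisfy 0 <= positives <= total", call. = FALSE)
  }
  if (is.na(dna_ng) || dna_ng < 0) stop("'dna_ng' must be >= 0", call. = FALSE)
  structure(
    data.frame(
      well_id = as.character(well_id),
      sample_id = as.character(sample_id),
      positives = positives,
      total = total,
      dna_ng = dna_ng,
      stringsAsFactors = FALSE
    ),
    class = c("droplet_count", "data.frame")
  )
}

#' Estimate the mean copies per partition (lambda)
#'
#' Poisson maximum-likelihood estimate from partition counts:
#' `lambda = -ln((total - positives) / total)`, the standard digital-PCR
#' estimator. The confidence interval propagates the binomial uncertainty of
#' the negative-partition fraction through the log transform
#' (normal approximation on the negative fraction, adequate for the >= 10^4
#' partitions typical of droplet platforms), clipped at 0. A well with every
#' partition positive is flagged `saturated`: lambda is unbounded and the
#' sample must be diluted, never imputed.
#'
#' @param count A [droplet_count()] record (or any list/row with `positives`
#'   and `total`).
#' @param confidence Confidence level in (0, 1); default 0.95.
#' @return A list of class `lambda_estimate` with elements `lam`, `ci_low`,
#'   `ci_high` (`Inf` when the negative count is too small for a finite upper
#'   bound), and `saturated`.
#' @examples
#' estimate_lambda(droplet_count("A01", "s1", 10068, 20000, 10))
#' @export
estimate_lambda <- function(count, confidence = 0.95) {
  stopifnot(confidence > 0, confidence < 1)
  p <- as.integer(count$positives)
  t <- as.integer(count$total)
  if (t <= 0L || p < 0L || p > t) {
    stop("invalid droplet count: need 0 <= positives <= total, total > 0",
      call. = FALSE
    )
  }
  if (p == t) {
    return(structure(
      list(lam = NA_real_, ci_low = NA_real_, ci_high = Inf, saturated = TRUE),
      class = "lambda_estimate"
    ))
  }
  q <- (t - p) / t # negative fraction
  lam <- -log(q)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  se <- sqrt(q * (1 - q) / t)
  q_hi <- min(q + z * se, 1)
  q_lo <- q - z * se
  ci_low <- max(-log(q_hi), 0)
  ci_high <- if (q_lo <= 0) Inf else -log(q_lo)
  structure(
    list(lam = lam, ci_low = ci_low, ci_high = ci_high, saturated = FALSE),
    class = "lambda_estimate"
  )
}

#' @export
print.lambda_estimate <- function(x, ...) {
  if (x$saturated) {
    cat("<lambda_estimate> saturated (all partitions positive)\n")
  } else {
    cat(sprintf(
      "<lambda_estimate> lambda = %.5f [%.5f, %s]\n",
      x$lam, x$ci_low,
      if (is.finite(x$ci_high)) sprintf("%.5f", x$ci_high) else "Inf"
    ))
  }
  invisible(x)
}

#' Convert lambda to measured copies per reaction
#'
#' `cm = lambda * Vs / Vp`: the mean copies per partition scaled by the
#' number of partition volumes in the reaction.
#'
#' @param lam Mean copies per partition (>= 0, finite); vectorised. A
#'   [estimate_lambda()] result may be passed directly.
#' @param cfg A [partition_config()]; defaults to the QX200 geometry.
#' @return Measured copies in the reaction, `cm`.
#' @examples
#' measured_copies(0.7) # ~16471 copies at QX200 geometry
#' @export
measured_copies <- function(lam, cfg = partition_config()) {
  stopifnot(inherits(cfg, "partition_config"))
  if (inherits(lam, "lambda_estimate")) {
    if (isTRUE(lam$saturated)) {
      stop("lambda is saturated (all partitions positive): dilute the sample",
        call. = FALSE
      )
    }
    lam <- lam$lam
  }
  lam <- as.numeric(lam)
  if (any(!is.finite(lam)) || any(lam < 0)) {
    stop("'lam' must be finite and >= 0 (saturated wells cannot be quantified)",
      call. = FALSE
    )
  }
  lam * cfg$sample_volume_ul / cfg$partition_volume_ul
}

#' Threshold-based droplet calling
#'
#' Minimal amplitude thresholding: a droplet is positive when its
#' fluorescence amplitude is strictly greater than the threshold. With
#' `threshold = "auto"` the threshold is the midpoint between the two
#' cluster centres of a 2-means split of the amplitudes; when the split does
#' not separate two modes (centre gap below twice the pooled within-cluster
#' spread) the well is called all-negative with a warning. This is a
#' deliberately simple caller for plumbing and simulated data; it is not a
#' rain-aware production caller.
#'
#' @param amplitudes Numeric vector of droplet fluorescence amplitudes
#'   (>= 100 droplets).
#' @param threshold Numeric threshold, or `"auto"`.
#' @return A list with `positives`, `total` and the `threshold` used.
#' @export
call_droplets <- function(amplitudes, threshold = "auto") {
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) < 100L) {
    stop("need at least 100 droplets to call a well", call. = FALSE)
  }
  if (identical(threshold, "auto")) {
    if (diff(range(amplitudes)) == 0) {
      warning(
        "amplitude distribution looks unimodal; calling all droplets negative",
        call. = FALSE
      )
      return(list(
        positives = 0L, total = length(amplitudes),
        threshold = Inf
      ))
    }
    km <- suppressWarnings(
      stats::kmeans(amplitudes, centers = range(amplitudes), iter.max = 50)
    )
    centres <- sort(km$centers[, 1])
    spread <- sqrt(sum(km$withinss) / length(amplitudes))
    if (diff(centres) < 4 * spread || diff(centres) == 0) {
      warning(
        "amplitude distribution looks unimodal; calling all droplets negative",
        call. = FALSE
      )
      return(list(
        positives = 0L, total = length(amplitudes),
        threshold = Inf
      ))
    }
    threshold <- mean(centres)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  list(
    positives = sum(amplitudes > threshold),
    total = length(amplitudes),
    threshold = threshold
  )
}

#' Pool replicate wells of one sample
#'
#' Sums positives and totals over replicate wells so that the pooled lambda
#' is the maximum-likelihood estimate under the joint Poisson model; this is
#' preferred over averaging per-well lambda estimates. The pooled record
#' carries the mean template mass of the wells.
#'
#' @param counts A `droplet_count` data frame (one or more rows, one sample).
#' @return A single pooled [droplet_count()] row.
#' @export
merge_replicates <- function(counts) {
  counts <- as.data.frame(counts)
  if (nrow(counts) == 0L) stop("no wells to merge", call. = FALSE)
  ids <- unique(counts$sample_id)
  if (length(ids) != 1L) {
    stop(
      sprintf(
        "cannot pool wells from different samples: %s",
        paste(ids, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  if (any(counts$positives == counts$total)) {
    stop("cannot pool saturated wells (all partitions positive)",
      call. = FALSE
    )
  }
  droplet_count(
    well_id = paste(counts$well_id, collapse = "+"),
    sample_id = ids,
    positives = sum(counts$positives),
    total = sum(counts$total),
    dna_ng = mean(counts$dna_ng)
  )
}

#' Measured copies for every sample in a droplet table
#'
#' Convenience wrapper: pools replicate wells per sample, estimates lambda
#' and converts to measured copies per reaction.
#'
#' @param droplets Data frame in the droplet dialect (columns `well_id`,
#'   `sample_id`, `positives`, `total`, `dna_ng`).
#' @param cfg A [partition_config()].
#' @return Data frame with one row per sample: `sample_id`, `dna_ng`,
#'   `positives`, `total`, `lambda`, `cm`.
#' @export
quantify_samples <- function(droplets, cfg = partition_config()) {
  droplets <- as.data.frame(droplets)
  pieces <- lapply(split(droplets, droplets$sample_id), function(d) {
    pooled <- merge_replicates(d)
    est <- estimate_lambda(pooled)
    data.frame(
      sample_id = pooled$sample_id,
      dna_ng = pooled$dna_ng,
      positives = pooled$positives,
      total = pooled$total,
      lambda = est$lam,
      cm = measured_copies(est, cfg),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$sample_id), , drop = FALSE]
}
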