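#' Percent dPCR purity of a sample
#'
#' The screening statistic: a sample whose measured copies `cm` fall inside
#' the calibration prediction interval at its expected copies `ce` is
#' indistinguishable from pure reference material and gets purity 1. Outside
#' the interval the purity is the ratio of `cm` to the violated prediction
#' bound, so the value expresses how far outside the interval the
#' measurement lies:
#' below the interval `purity = cm / lCe` (< 1), above it
#' `purity = cm / uCe` (> 1) by default, which is continuous at the upper
#' bound. `upper_denominator = "lCe"` divides by the lower bound instead;
#' either choice gives a value > 1 and the same classification.
#'
#' @param cm Measured copies (>= 0); vectorised.
#' @param ce Expected copies (> 0); same length as `cm` (or scalar).
#' @param model A fitted [fit_calibration()] model.
#' @param level Prediction level; default 0.95.
#' @param upper_denominator `"uCe"` (default, continuous) or `"lCe"` for the
#'   above-interval branch.
#' @param sample_id Optional sample labels.
#' @return Data frame of class `purity_result` with columns `sample_id`,
#'   `cm`, `ce`, `lCe`, `uCe`, `purity` (fraction; 1 = pure), `category`
#'   (`"non_suspicious"` / `"suspicious"`), `tier`, `below_range`. Purity is
#'   `NA` for samples whose lower bound had to be clamped (below the
#'   quantification range).
#' @examples
#' pts <- data.frame(ce = 10^seq(3, 5, length.out = 12))
#' pts$cm <- pts$ce * (1 + stats::rnorm(12, 0, 0.05))
#' m <- fit_calibration(pts)
#' percent_purity(cm = 5000, ce = 10000, model = m)
#' @export
percent_purity <- function(cm, ce, model, level = 0.95,
                           upper_denominator = c("uCe", "lCe"),
                           sample_id = NULL) {
  upper_denominator <- match.arg(upper_denominator)
  cm <- as.numeric(cm)
  ce <- as.numeric(ce)
  if (length(ce) == 1L) ce <- rep(ce, length(cm))
  if (length(cm) != length(ce)) {
    stop("'cm' and 'ce' must have the same length", call. = FALSE)
  }
  if (any(!is.finite(cm)) || any(cm < 0)) {
    stop("'cm' must be finite and >= 0", call. = FALSE)
  }
  pi <- prediction_interval(model, ce, level = level)
  purity <- ifelse(
    cm < pi$lCe, cm / pi$lCe,
    ifelse(cm > pi$uCe,
      cm / if (upper_denominator == "uCe") pi$uCe else pi$lCe,
      1
    )
  )
  purity[pi$below_range] <- NA_real_
  cls <- classify(purity)
  tier <- ifelse(!is.na(purity) & purity == 1 & cm >= pi$lCe & cm <= pi$uCe,
    "within_interval", cls$tier
  )
  if (is.null(sample_id)) sample_id <- as.character(seq_along(cm))
  structure(
    data.frame(
      sample_id = as.character(sample_id),
      cm = cm, ce = ce, lCe = pi$lCe, uCe = pi$uCe,
      purity = purity,
      category = cls$category,
      tier = tier,
      below_range = pi$below_range,
      stringsAsFactors = FALSE
    ),
    class = c("purity_result", "data.frame")
  )
}

#' Classify a purity value against the acceptance band
#'
#' Samples with purity in the inclusive band \[0.80, 1.20\] are
#' `non_suspicious`; everything else is `suspicious` and referred for
#' confirmatory analysis. The tier refines the suspicious side: purities in
#' \[0.70, 0.80) or above 1.20 form the high band (mild deviations, in
#' practice mostly within-genus variation), purities below 0.70 the low band
#' (where genuine adulteration concentrates).
#'
#' @param purity Numeric vector of purity fractions (1 = pure); `NA` allowed.
#' @return Data frame with columns `purity`, `category`, `tier`.
#' @examples
#' classify(c(1, 0.95, 0.75, 0.5, 1.25))
#' @export
classify <- function(purity) {
  purity <- as.numeric(purity)
  category <- ifelse(is.na(purity), NA_character_,
    ifelse(purity >= 0.80 & purity <= 1.20, "non_suspicious", "suspicious")
  )
  tier <- ifelse(is.na(purity), NA_character_,
    ifelse(purity >= 0.80 & purity <= 1.20, "within_acceptance",
      ifelse(purity >= 0.70, "high_band", "low_band")
    )
  )
  data.frame(
    purity = purity, category = category, tier = tier,
    stringsAsFactors = FALSE
  )
}

#' Population screening rule on the copies-per-ng ratio
#'
#' Simplified decision rule obtained by dropping the constant terms from the
#' copy-forecast and copy-measurement equations: the ratio of measured
#' copies to template mass (copies/ng) of authentic samples is approximately
#' normal across the market, and new samples are screened against
#' `mean +/- z * sd` (default z = 1.96, covering 95% of the authentic
#' population). The rule must be parameterised from in-house authentic
#' samples; no default market values are assumed.
#'
#' @param mean_cpn Population mean of the copies-per-ng ratio.
#' @param sd_cpn Population standard deviation (> 0).
#' @param z Coverage multiplier; default 1.96.
#' @return An object of class `population_rule` with `low` and `high` bounds.
#' @examples
#' population_rule(143, 40) # bounds ~64.6 and ~221.4 copies/ng
#' @export
population_rule <- function(mean_cpn, sd_cpn, z = 1.96) {
  stopifnot(is.numeric(mean_cpn), is.numeric(sd_cpn), is.numeric(z))
  if (sd_cpn <= 0) stop("'sd_cpn' must be > 0", call. = FALSE)
  if (z < 0) stop("'z' must be >= 0", call. = FALSE)
  structure(
    list(
      mean_cpn = mean_cpn, sd_cpn = sd_cpn, z = z,
      low = mean_cpn - z * sd_cpn, high = mean_cpn + z * sd_cpn
    ),
    class = "population_rule"
  )
}

#' @export
print.population_rule <- function(x, ...) {
  cat(sprintf(
    "<population_rule> %.4g +/- %.3g * %.4g copies/ng -> [%.4g, %.4g]\n",
    x$mean_cpn, x$z, x$sd_cpn, x$low, x$high
  ))
  invisible(x)
}

#' Screen samples by their copies-per-ng ratio
#'
#' @param cm Measured copies (>= 0); vectorised.
#' @param dna_ng Template mass in the reaction, ng (> 0).
#' @param rule A [population_rule()].
#' @return Data frame with `ratio` (copies/ng) and `pass` (logical,
#'   inclusive bounds).
#' @examples
#' screen_by_ratio(1430, 10, population_rule(143, 40))
#' @export
screen_by_ratio <- function(cm, dna_ng, rule) {
  stopifnot(inherits(rule, "population_rule"))
  cm <- as.numeric(cm)
  dna_ng <- as.numeric(dna_ng)
  if (length(dna_ng) == 1L) dna_ng <- rep(dna_ng, length(cm))
  if (any(!is.finite(dna_ng)) || any(dna_ng <= 0)) {
    stop("'dna_ng' must be finite and > 0", call. = FALSE)
  }
  ratio <- cm / dna_ng
  data.frame(ratio = ratio, pass = ratio >= rule$low & ratio <= rule$high)
}
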