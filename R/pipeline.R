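#' Build a calibration model from droplet data
#'
#' Full calibration stage: pools replicate wells per sample, estimates
#' lambda, converts to measured copies, forecasts expected copies from each
#' sample's template mass and the species genome parameters, and fits the
#' weighted calibration line.
#'
#' @param droplets Droplet-dialect data frame (see [read_droplet_csv()]).
#' @param params [species_genome_params()] of the reference species.
#' @param cfg A [partition_config()].
#' @param ... Passed to [fit_calibration()] (`variance_power`,
#'   `through_origin`).
#' @return A `calibration_model`; the calibration points are attached as
#'   attribute `points`.
#' @export
calibrate_samples <- function(droplets, params, cfg = partition_config(),
                              ...) {
  q <- quantify_samples(droplets, cfg)
  pts <- data.frame(
    sample_id = q$sample_id,
    ce = expected_copies(q$dna_ng, params),
    cm = q$cm,
    stringsAsFactors = FALSE
  )
  model <- fit_calibration(pts, ...)
  attr(model, "points") <- pts
  model
}

#' Screen samples against a calibration model
#'
#' Full screening stage: quantifies each sample (replicates pooled),
#' forecasts its expected copies, computes percent purity against the
#' model's prediction interval and classifies it; optionally also applies a
#' copies-per-ng [population_rule()].
#'
#' @param droplets Droplet-dialect data frame.
#' @param model A fitted [fit_calibration()] model.
#' @param params [species_genome_params()] of the declared species.
#' @param cfg A [partition_config()].
#' @param level Prediction level; default 0.95.
#' @param rule Optional [population_rule()]; adds `ratio` and `ratio_pass`
#'   columns.
#' @return A [percent_purity()] result data frame (plus ratio columns when a
#'   rule is given).
#' @export
screen_samples <- function(droplets, model, params,
                           cfg = partition_config(), level = 0.95,
                           rule = NULL) {
  q <- quantify_samples(droplets, cfg)
  ce <- expected_copies(q$dna_ng, params)
  res <- percent_purity(
    cm = q$cm, ce = ce, model = model, level = level,
    sample_id = q$sample_id
  )
  if (!is.null(rule)) {
    sr <- screen_by_ratio(q$cm, q$dna_ng, rule)
    res$ratio <- sr$ratio
    res$ratio_pass <- sr$pass
  }
  res
}
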