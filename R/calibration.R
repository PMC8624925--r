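#' Fit the measured-vs-expected calibration curve by weighted least squares
#'
#' Regresses measured copies `cm` on expected copies `ce` over pure reference
#' samples. Replicate measurements of dilution series show strongly
#' non-constant residual variance (the spread grows with the copy number), so
#' the fit uses weighted least squares with weights `1/ce^gamma`. The default
#' `gamma = 2` corresponds to a constant coefficient of variation, the
#' natural error structure when the dominant noise sources (pipetting,
#' fluorometric quantification) are multiplicative. `gamma` can be set by the
#' user or estimated empirically from the data (`variance_power =
#' "estimate"`: the log squared OLS residuals are regressed on `log(ce)`).
#'
#' @param points Data frame with columns `ce` (> 0) and `cm` (>= 0);
#'   optionally `sample_id`.
#' @param variance_power Exponent gamma in `Var(cm | ce) = sigma^2 * ce^gamma`,
#'   or `"estimate"` for the two-stage empirical estimate. Default 2.
#' @param through_origin Force a zero intercept. Default `FALSE`: the
#'   intercept absorbs any constant offset in the measurement chain.
#' @return An object of class `calibration_model`: list with `intercept`,
#'   `slope`, `variance_power`, `sigma2` (weighted residual variance),
#'   `dof`, `coefficient_covariance`, `n_points`, `through_origin`.
#' @examples
#' pts <- data.frame(ce = 10^seq(3, 5, length.out = 10))
#' pts$cm <- pts$ce
#' fit_calibration(pts)
#' @export
fit_calibration <- function(points, variance_power = 2,
                            through_origin = FALSE) {
  points <- as.data.frame(points)
  if (!all(c("ce", "cm") %in% names(points))) {
    stop("calibration points need columns 'ce' and 'cm'", call. = FALSE)
  }
  ce <- as.numeric(points$ce)
  cm <- as.numeric(points$cm)
  if (any(!is.finite(ce)) || any(ce <= 0)) {
    stop("all 'ce' must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(cm)) || any(cm < 0)) {
    stop("all 'cm' must be finite and >= 0", call. = FALSE)
  }
  n <- length(ce)
  if (n < 3L) stop("need at least 3 calibration points", call. = FALSE)
  if (length(unique(ce)) == 1L) {
    stop("all 'ce' identical: calibration line is unidentifiable",
      call. = FALSE
    )
  }
  if (n < 5L) {
    warning("fewer than 5 calibration points; fit will be unstable",
      call. = FALSE
    )
  }
  if (max(ce) / min(ce) < 10) {
    warning("'ce' values span less than one order of magnitude",
      call. = FALSE
    )
  }

  if (identical(variance_power, "estimate")) {
    ols <- if (through_origin) stats::lm(cm ~ 0 + ce) else stats::lm(cm ~ ce)
    r2 <- stats::residuals(ols)^2
    keep <- r2 > 0
    if (sum(keep) < 3L) {
      variance_power <- 2
    } else {
      vfit <- stats::lm(log(r2[keep]) ~ log(ce[keep]))
      variance_power <- unname(stats::coef(vfit)[2])
    }
  }
  gamma <- as.numeric(variance_power)
  if (!is.finite(gamma)) stop("invalid variance power", call. = FALSE)

  w <- 1 / ce^gamma
  fit <- if (through_origin) {
    stats::lm(cm ~ 0 + ce, weights = w)
  } else {
    stats::lm(cm ~ ce, weights = w)
  }
  cf <- stats::coef(fit)
  dof <- stats::df.residual(fit)
  if (dof <= 0L) stop("no residual degrees of freedom", call. = FALSE)
  sigma2 <- sum(w * stats::residuals(fit)^2) / dof
  V <- stats::vcov(fit)

  structure(
    list(
      intercept = if (through_origin) 0 else unname(cf[1]),
      slope = unname(cf[if (through_origin) 1 else 2]),
      variance_power = gamma,
      sigma2 = sigma2,
      dof = as.integer(dof),
      coefficient_covariance = unname(as.matrix(V)),
      n_points = n,
      through_origin = isTRUE(through_origin)
    ),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<calibration_model> cm = %.4g + %.4f * ce  (n = %d, dof = %d)\n",
      "  variance model: sigma2 * ce^%.3g, sigma2 = %.4g%s\n"
    ),
    x$intercept, x$slope, x$n_points, x$dof,
    x$variance_power, x$sigma2,
    if (x$through_origin) ", through origin" else ""
  ))
  invisible(x)
}

#' Prediction interval for a future pure measurement
#'
#' Range expected to contain a stated fraction (default 95%) of future
#' measured-copy values from pure material at expected copies `ce`:
#' \deqn{\hat{y}(c_e) \pm t_{1-\alpha/2,\,dof}
#'   \sqrt{\hat\sigma^2 c_e^\gamma + \mathrm{Var}(\hat{y}(c_e))}}
#' using Student-t quantiles at the model's residual degrees of freedom.
#' A lower bound that falls at or below zero (possible at very small `ce`)
#' is clamped to a tiny positive value and the point flagged below the
#' quantification range, since the purity statistic divides by the lower
#' bound.
#'
#' @param model A fitted [fit_calibration()] model.
#' @param ce Expected copies (> 0); vectorised.
#' @param level Prediction level in (0, 1); default 0.95.
#' @return Data frame with columns `ce`, `fit`, `lCe`, `uCe`,
#'   `below_range` (logical: lower bound clamped).
#' @export
prediction_interval <- function(model, ce, level = 0.95) {
  stopifnot(inherits(model, "calibration_model"), level > 0, level < 1)
  ce <- as.numeric(ce)
  if (any(!is.finite(ce)) || any(ce <= 0)) {
    stop("'ce' must be finite and > 0", call. = FALSE)
  }
  yhat <- model$intercept + model$slope * ce
  V <- model$coefficient_covariance
  var_line <- if (model$through_origin) {
    V[1, 1] * ce^2
  } else {
    V[1, 1] + 2 * V[1, 2] * ce + V[2, 2] * ce^2
  }
  var_pred <- model$sigma2 * ce^model$variance_power + var_line
  half <- stats::qt(1 - (1 - level) / 2, df = model$dof) * sqrt(var_pred)
  lCe <- yhat - half
  uCe <- yhat + half
  below <- lCe <= 0
  lCe[below] <- .Machine$double.eps * pmax(1, abs(yhat[below]))
  data.frame(ce = ce, fit = yhat, lCe = lCe, uCe = uCe, below_range = below)
}

#' Write a calibration model to a JSON text file
#'
#' Serialises every fitted quantity (coefficients, variance power, sigma^2,
#' coefficient covariance, degrees of freedom) plus optional provenance
#' metadata so a screening run can be reproduced from the file alone.
#'
#' @param model A [fit_calibration()] model.
#' @param path Output path.
#' @param provenance Optional named list (e.g. input file hash, species)
#'   stored verbatim.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(model, path, provenance = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- list(
    format = "dnaccounting/calibration",
    version = 1L,
    intercept = model$intercept,
    slope = model$slope,
    variance_power = model$variance_power,
    sigma2 = model$sigma2,
    dof = model$dof,
    coefficient_covariance = model$coefficient_covariance,
    n_points = model$n_points,
    through_origin = model$through_origin,
    provenance = provenance
  )
  jsonlite::write_json(obj, path,
    auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE
  )
  invisible(path)
}

#' Read a calibration model from a JSON text file
#'
#' @param path Path written by [write_calibration()].
#' @return A `calibration_model` object.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "dnaccounting/calibration")) {
    stop(sprintf("'%s' is not a calibration model file", path), call. = FALSE)
  }
  structure(
    list(
      intercept = as.numeric(obj$intercept),
      slope = as.numeric(obj$slope),
      variance_power = as.numeric(obj$variance_power),
      sigma2 = as.numeric(obj$sigma2),
      dof = as.integer(obj$dof),
      coefficient_covariance = matrix(
        as.numeric(obj$coefficient_covariance),
        nrow = nrow(as.matrix(obj$coefficient_covariance))
      ),
      n_points = as.integer(obj$n_points),
      through_origin = isTRUE(obj$through_origin)
    ),
    class = "calibration_model"
  )
}
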