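#' Effect-size summary of a ratio-scale measurement vector
#'
#' An `effect_summary` holds the (location, dispersion) pair that the rxCOV
#' metric consumes: arithmetic mean and sample standard deviation under the
#' `"moment"` estimator, or median and interquartile range under the
#' `"robust"` estimator.
#'
#' @param location Location statistic (mean or median). Must be finite and
#'   non-negative; a zero location is legal here but rejected later by
#'   [rxcov()], which requires strictly positive inputs.
#' @param dispersion Dispersion statistic (sd or IQR), finite and
#'   non-negative.
#' @param estimator `"moment"` or `"robust"`.
#' @param n Number of observations summarized.
#' @return An object of class `effect_summary`.
#' @seealso [effect_stats()] to compute a summary from raw values.
#' @export
effect_summary <- function(location, dispersion, estimator = c("moment", "robust"), n = NA_integer_) {
  estimator <- match.arg(estimator)
  if (!is.numeric(location) || length(location) != 1L || !is.finite(location)) {
    stop_validation("`location` must be a single finite number")
  }
  if (!is.numeric(dispersion) || length(dispersion) != 1L || !is.finite(dispersion)) {
    stop_validation("`dispersion` must be a single finite number")
  }
  if (location < 0) stop_validation("`location` must be non-negative (ratio-scale variable)")
  if (dispersion < 0) stop_validation("`dispersion` must be non-negative")
  structure(
    list(location = location, dispersion = dispersion,
         estimator = estimator, n = as.integer(n)),
    class = "effect_summary"
  )
}

#' Summarize a measurement vector into location and dispersion
#'
#' Computes the effect-size pair fed to [rxcov()]. The `"moment"` estimator
#' returns the arithmetic mean and the sample standard deviation (n - 1
#' denominator). The `"robust"` estimator, intended for skewed data, returns
#' the median and the interquartile range Q3 - Q1, with quantiles computed by
#' linear interpolation between order statistics (`type = 7`).
#'
#' @param values Numeric vector, length >= 2, all finite.
#' @param estimator `"moment"` (default) or `"robust"`.
#' @return An [effect_summary()].
#' @examples
#' effect_stats(c(1, 2, 3))                 # mean 2, sd 1
#' effect_stats(c(1, 2, 3, 4, 100), "robust")  # median 3, IQR 2
#' @export
effect_stats <- function(values, estimator = c("moment", "robust")) {
  estimator <- match.arg(estimator)
  if (!is.numeric(values)) stop_validation("`values` must be numeric")
  if (anyNA(values) || any(!is.finite(values))) {
    stop_validation("`values` must be finite and non-missing")
  }
  if (length(values) < 2L) {
    stop_insufficient("at least 2 values are required to estimate a dispersion")
  }
  if (estimator == "moment") {
    loc <- mean(values)
    disp <- stats::sd(values)
  } else {
    loc <- stats::median(values)
    q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
    disp <- q[2] - q[1]
  }
  effect_summary(loc, disp, estimator, n = length(values))
}

#' @export
print.effect_summary <- function(x, ...) {
  lab <- if (x$estimator == "moment") c("mean", "sd") else c("median", "IQR")
  cat(sprintf("effect_summary (%s): %s = %g, %s = %g, n = %d\n",
              x$estimator, lab[1], x$location, lab[2], x$dispersion, x$n))
  invisible(x)
}

is_effect_summary <- function(x) inherits(x, "effect_summary")
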