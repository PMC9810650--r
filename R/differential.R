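#' Paired differential expression Z = |X - Y|
#'
#' For paired samples measured in both groups, the differential expression is
#' the elementwise absolute difference, equivalently (by the lattice identity)
#' `max(x, y) - min(x, y)`.
#'
#' @param x,y Numeric vectors of aligned, non-negative expression values
#'   (same samples, same order).
#' @param estimator Estimator passed to [effect_stats()] for the summary.
#' @return A list of class `rxcov_differential` with elements `z_values`,
#'   `summary` (an [effect_summary()]) and `mode = "paired"`.
#' @export
paired_differential <- function(x, y, estimator = c("moment", "robust")) {
  estimator <- match.arg(estimator)
  if (length(x) != length(y)) {
    stop_pairing(sprintf("paired groups must have equal length (got %d and %d)",
                         length(x), length(y)))
  }
  check_measurements(x, "x")
  check_measurements(y, "y")
  z <- abs(x - y)
  structure(
    list(z_values = z, summary = effect_stats(z, estimator), mode = "paired"),
    class = "rxcov_differential"
  )
}

#' Unpaired differential expression from group summaries
#'
#' When the two groups are independent, Z is redefined at the summary level:
#' the location is `|mu_X - mu_Y|` and the dispersion combines in quadrature,
#' `sqrt(sigma_X^2 + sigma_Y^2)`. In robust mode the same quadrature rule is
#' applied to the two IQRs; this is an extension by analogy with the moment
#' formula (see the methods vignette).
#'
#' @param summary_x,summary_y [effect_summary()] objects for the two groups,
#'   computed with the same estimator.
#' @return A list of class `rxcov_differential` with `z_values = NULL`,
#'   `summary` and `mode = "unpaired"`.
#' @export
unpaired_differential <- function(summary_x, summary_y) {
  if (!is_effect_summary(summary_x) || !is_effect_summary(summary_y)) {
    stop_validation("`summary_x` and `summary_y` must be effect_summary objects")
  }
  if (summary_x$estimator != summary_y$estimator) {
    stop_validation("both summaries must use the same estimator")
  }
  loc <- abs(summary_x$location - summary_y$location)
  if (loc == 0) {
    stop_degenerate("mu_Z is degenerate: group locations are identical (mu_X = mu_Y)")
  }
  disp <- sqrt(summary_x$dispersion^2 + summary_y$dispersion^2)
  n <- summary_x$n + summary_y$n
  structure(
    list(z_values = NULL,
         summary = effect_summary(loc, disp, summary_x$estimator, n = n),
         mode = "unpaired"),
    class = "rxcov_differential"
  )
}

#' Assay noise from repeat aliquot measurements
#'
#' The assay-associated noise of one group is the elementwise absolute
#' difference between the primary measurement and its repeat on a second
#' aliquot of the same sample: `N = |X - X'|`.
#'
#' @param primary,repeats Numeric vectors of aligned measurements (same
#'   samples, same order).
#' @return Numeric vector of non-negative noise realizations.
#' @export
noise_from_repeats <- function(primary, repeats) {
  if (length(primary) != length(repeats)) {
    stop_pairing(sprintf(
      "aliquot vectors must be aligned sample-by-sample (got lengths %d and %d)",
      length(primary), length(repeats)))
  }
  check_measurements(primary, "primary")
  check_measurements(repeats, "repeats")
  abs(primary - repeats)
}

#' Combine the two groups' noise into the worst-case noise variable
#'
#' The metric uses a single worst-case noise variable N = max(N_X, N_Y).
#' Three realizations are offered:
#' \describe{
#'   \item{`elementwise_max`}{`max(nx[i], ny[i])` for aligned groups of equal
#'     size (the simulation default).}
#'   \item{`cross_product_max`}{exact enumeration of `max(nx[i], ny[j])` over
#'     all i x j pairs — a faithful estimator of the distribution of the max
#'     of two independent noise variables, usable for unequal group sizes
#'     (the default for unpaired batch analysis).}
#'   \item{`single_group`}{one group's noise used alone (`ny` ignored).}
#' }
#'
#' @param nx,ny Numeric vectors of non-negative noise realizations. `ny` may
#'   be omitted in `single_group` mode.
#' @param mode Combination mode, see above.
#' @return A list of class `noise_variable` with `n_values` and
#'   `combine_mode`.
#' @export
combine_noise <- function(nx, ny = NULL,
                          mode = c("elementwise_max", "cross_product_max", "single_group")) {
  mode <- match.arg(mode)
  if (length(nx) == 0L) stop_validation("`nx` must be non-empty")
  check_measurements(nx, "nx")
  if (any(nx < 0)) stop_validation("noise values must be non-negative")
  if (mode != "single_group") {
    if (is.null(ny) || length(ny) == 0L) stop_validation("`ny` must be non-empty")
    check_measurements(ny, "ny")
    if (any(ny < 0)) stop_validation("noise values must be non-negative")
  }
  n_values <- switch(mode,
    elementwise_max = {
      if (length(nx) != length(ny)) {
        stop_validation("elementwise_max requires equal-length noise vectors")
      }
      pmax(nx, ny)
    },
    cross_product_max = as.vector(outer(nx, ny, pmax)),
    single_group = nx
  )
  structure(list(n_values = n_values, combine_mode = mode), class = "noise_variable")
}

#' Normalize expression values by tissue weight
#'
#' Divides each measured value by the weight of the tissue sample it came
#' from, removing variation due to biopsy size.
#'
#' @param values Numeric vector of non-negative measurements.
#' @param weights Numeric vector of strictly positive weights, same length.
#' @return `values / weights`.
#' @export
normalize_by_weight <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop_validation("`values` and `weights` must have equal length")
  }
  check_measurements(values, "values")
  if (!is.numeric(weights) || anyNA(weights) || any(!is.finite(weights))) {
    stop_validation("`weights` must be finite and non-missing")
  }
  if (any(weights <= 0)) {
    stop_validation(sprintf("weights must be strictly positive (offending positions: %s)",
                            paste(which(weights <= 0), collapse = ", ")))
  }
  values / weights
}

check_measurements <- function(x, name) {
  if (!is.numeric(x)) stop_validation(sprintf("`%s` must be numeric", name))
  if (anyNA(x) || any(!is.finite(x))) {
    stop_validation(sprintf("`%s` must be finite and non-missing", name))
  }
  invisible(x)
}
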