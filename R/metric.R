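#' Log-ratio function of relative change
#'
#' The generic building block of the fidelity metric:
#' `f(m_z, m_n) = log10(m_z / m_n)` for two positive effect-size measures.
#' It is zero iff the measures are equal, positive iff `m_z > m_n`, strictly
#' increasing in `m_z` for fixed `m_n`, and invariant under a common positive
#' rescaling of both arguments (hence independent of measurement units).
#'
#' @param m_z,m_n Strictly positive effect-size measures (vectorized).
#' @return `log10(m_z / m_n)`.
#' @export
relative_change <- function(m_z, m_n) {
  if (!is.numeric(m_z) || !is.numeric(m_n)) stop_domain("arguments must be numeric")
  if (anyNA(m_z) || anyNA(m_n) || any(!is.finite(m_z)) || any(!is.finite(m_n))) {
    stop_domain("arguments must be finite")
  }
  if (any(m_z <= 0) || any(m_n <= 0)) {
    stop_domain("relative change requires strictly positive arguments")
  }
  log10(m_z / m_n)
}

# Core evaluation on the four statistics, written in the ratio-of-cross-COV
# form log10((sigma_z/mu_n) / (sigma_n/mu_z)); the mean/dispersion terms are
# computed separately so additivity is a checkable identity, not a tautology.
rxcov_core <- function(mu_z, mu_n, sigma_z, sigma_n) {
  log10((sigma_z / mu_n) / (sigma_n / mu_z))
}

#' rxCOV: ratio of cross coefficients of variation
#'
#' The fidelity metric for differential analyte expression Z against
#' assay-associated noise N:
#' \deqn{rxCOV(Z, N) = \log_{10}\frac{\sigma_Z/\mu_N}{\sigma_N/\mu_Z}
#'       = \log_{10}\frac{\mu_Z}{\mu_N} + \log_{10}\frac{\sigma_Z}{\sigma_N}.}
#' Each dispersion is standardized by the *other* variable's location — the
#' "cross" in the name. `rxcov > 0` means the differential expression
#' dominates the noise on both first- and second-order effect size combined:
#' the analyte has high fidelity. `rxcov <= 0` means the noise dominates and
#' the analyte has low fidelity (any p-value computed there is suspect).
#'
#' All four statistics must be strictly positive; a zero is reported as a
#' degenerate-input error naming the offending statistic rather than being
#' silently floored, because perturbing a fidelity metric defeats its
#' purpose. Batch callers catch the condition and carry a status instead
#' (see [rxcov_table()]).
#'
#' @param summary_z [effect_summary()] of the differential expression Z.
#' @param summary_n [effect_summary()] of the noise variable N.
#' @return An object of class `rxcov_result` with fields `mu_z`, `mu_n`,
#'   `sigma_z`, `sigma_n`, `mean_term`, `dispersion_term`, `rxcov`,
#'   `fidelity` (`"high"` iff `rxcov > 0`) and `estimator`.
#' @examples
#' sz <- effect_summary(5, 3)
#' sn <- effect_summary(2, 1)
#' rxcov(sz, sn)  # log10(7.5) ~ 0.875, high fidelity
#' @export
rxcov <- function(summary_z, summary_n) {
  if (!is_effect_summary(summary_z) || !is_effect_summary(summary_n)) {
    stop_validation("`summary_z` and `summary_n` must be effect_summary objects")
  }
  stats4 <- c(mu_z = summary_z$location, mu_n = summary_n$location,
              sigma_z = summary_z$dispersion, sigma_n = summary_n$dispersion)
  bad <- names(stats4)[stats4 <= 0]
  if (length(bad) > 0L) {
    stop_degenerate(sprintf("degenerate input: %s must be strictly positive (got %s)",
                            paste(bad, collapse = ", "),
                            paste(signif(stats4[bad], 6), collapse = ", ")))
  }
  value <- rxcov_core(stats4[["mu_z"]], stats4[["mu_n"]],
                      stats4[["sigma_z"]], stats4[["sigma_n"]])
  mean_term <- relative_change(stats4[["mu_z"]], stats4[["mu_n"]])
  dispersion_term <- relative_change(stats4[["sigma_z"]], stats4[["sigma_n"]])
  structure(
    list(mu_z = stats4[["mu_z"]], mu_n = stats4[["mu_n"]],
         sigma_z = stats4[["sigma_z"]], sigma_n = stats4[["sigma_n"]],
         mean_term = mean_term, dispersion_term = dispersion_term,
         rxcov = value,
         fidelity = if (value > 0) "high" else "low",
         estimator = summary_z$estimator),
    class = "rxcov_result"
  )
}

#' @export
print.rxcov_result <- function(x, ...) {
  cat(sprintf("rxCOV = %.4f  (mean term %.4f + dispersion term %.4f)\n",
              x$rxcov, x$mean_term, x$dispersion_term))
  cat(sprintf("  mu_Z = %g, sigma_Z = %g, mu_N = %g, sigma_N = %g  [%s]\n",
              x$mu_z, x$sigma_z, x$mu_n, x$sigma_n, x$estimator))
  cat(sprintf("  fidelity: %s\n", x$fidelity))
  invisible(x)
}

#' Sensitivity of rxCOV to the paired vs unpaired assumption
#'
#' Moving from the paired to the unpaired form of Z can only lower the
#' location (`d_mu <= 0`) and raise the dispersion (`d_sigma >= 0`). The
#' resulting change in the metric depends only on the relative deviations:
#' \deqn{\Delta rxCOV = \log_{10}(1 + \Delta\mu_Z/\mu_Z) +
#'       \log_{10}(1 + \Delta\sigma_Z/\sigma_Z).}
#'
#' @param rel_dmu Relative deviation of the location, `> -1` (vectorized).
#' @param rel_dsigma Relative deviation of the dispersion, `> -1`.
#' @return The change in rxCOV (log10 scale).
#' @examples
#' delta_rxcov(-0.5, 0)   # -0.30103
#' delta_rxcov(0, 0.5)    # +0.17609
#' @export
delta_rxcov <- function(rel_dmu, rel_dsigma) {
  if (!is.numeric(rel_dmu) || !is.numeric(rel_dsigma)) {
    stop_domain("arguments must be numeric")
  }
  if (any(!is.finite(rel_dmu)) || any(!is.finite(rel_dsigma))) {
    stop_domain("arguments must be finite")
  }
  if (any(1 + rel_dmu <= 0) || any(1 + rel_dsigma <= 0)) {
    stop_domain("relative deviations must be greater than -1")
  }
  log10(1 + rel_dmu) + log10(1 + rel_dsigma)
}

#' Evaluate the paired/unpaired sensitivity surface on a grid
#'
#' Tabulates [delta_rxcov()] over the rectangle
#' `[-mu_max_dev, 0] x [0, sigma_max_dev]` — location deviations are
#' non-positive and dispersion deviations non-negative by construction of the
#' unpaired form. Since the surface is monotone in each coordinate, its
#' minimum sits at `(-mu_max_dev, 0)` and its maximum at
#' `(0, sigma_max_dev)`.
#'
#' @param mu_max_dev Largest relative location deviation, in (0, 1).
#'   Default 0.5 (50%).
#' @param sigma_max_dev Largest relative dispersion deviation, > 0.
#'   Default 0.5.
#' @param step Grid step, > 0 and no larger than either range. Default 0.01.
#' @return An object of class `delta_grid`: `rel_dmu`, `rel_dsigma`,
#'   `surface` (matrix, rows = rel_dmu), `min_value`, `max_value`.
#' @export
delta_grid <- function(mu_max_dev = 0.5, sigma_max_dev = 0.5, step = 0.01) {
  if (!is.numeric(mu_max_dev) || length(mu_max_dev) != 1L ||
      mu_max_dev <= 0 || mu_max_dev >= 1) {
    stop_validation("`mu_max_dev` must lie in (0, 1)")
  }
  if (!is.numeric(sigma_max_dev) || length(sigma_max_dev) != 1L || sigma_max_dev <= 0) {
    stop_validation("`sigma_max_dev` must be positive")
  }
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    stop_validation("`step` must be positive")
  }
  if (step > mu_max_dev || step > sigma_max_dev) {
    stop_validation("`step` must not exceed either deviation range")
  }
  rel_dmu <- rev(seq(0, mu_max_dev, by = step)) * -1  # -mu_max_dev ... 0
  rel_dsigma <- seq(0, sigma_max_dev, by = step)
  surface <- outer(rel_dmu, rel_dsigma, delta_rxcov)
  dimnames(surface) <- list(format(rel_dmu), format(rel_dsigma))
  structure(
    list(rel_dmu = rel_dmu, rel_dsigma = rel_dsigma, surface = surface,
         min_value = min(surface), max_value = max(surface)),
    class = "delta_grid"
  )
}

#' @export
print.delta_grid <- function(x, ...) {
  cat(sprintf("delta_rxcov grid: %d x %d points, dmu/mu in [%g, 0], dsigma/sigma in [0, %g]\n",
              length(x$rel_dmu), length(x$rel_dsigma),
              min(x$rel_dmu), max(x$rel_dsigma)))
  cat(sprintf("  range: [%.5f, %.5f]\n", x$min_value, x$max_value))
  invisible(x)
}
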