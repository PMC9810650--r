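#' Inject scaled noise into a clean signal
#'
#' The additive noise model `d = s + gamma * n`: `gamma` scales a base noise
#' profile to sweep assay-noise severity without changing the signal. At
#' `gamma = 0` the data equal the clean signal.
#'
#' @param s Clean signal vector.
#' @param noise Base noise vector, same length.
#' @param gamma Non-negative scalar noise multiplier.
#' @return `s + gamma * noise` (unclipped; callers forming observed
#'   expressions clip at zero and log the count).
#' @export
apply_noise <- function(s, noise, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma < 0) {
    stop_domain("`gamma` must be a single non-negative number")
  }
  if (length(s) != length(noise)) {
    stop_validation("`s` and `noise` must have equal length")
  }
  s + gamma * noise
}

#' Simulate a measurement and its repeat aliquot, with replicate averaging
#'
#' Produces the pair (d, d') for one group: each is the average of
#' `r_replicates` independent noisy realizations of the same clean signal,
#' and the two use independent noise draws — exactly the structure of a
#' primary measurement and its repeat on a second aliquot. Averaging R
#' replicates shrinks the effective noise standard deviation by sqrt(R).
#'
#' @param s Clean signal vector.
#' @param gamma Noise multiplier, `>= 0`.
#' @param noise_sampler Function of `n` returning `n` i.i.d. base-noise
#'   draws (e.g. from [generate_scenario()]).
#' @param r_replicates Number of independent replicates averaged, `>= 1`.
#' @return A list with `d` and `d_repeat`.
#' @export
simulate_aliquot_pair <- function(s, gamma, noise_sampler, r_replicates = 1L) {
  if (!is.numeric(r_replicates) || length(r_replicates) != 1L || r_replicates < 1) {
    stop_config("`r_replicates` must be at least 1")
  }
  r <- as.integer(r_replicates)
  n <- length(s)
  avg_noisy <- function() {
    acc <- numeric(n)
    for (i in seq_len(r)) acc <- acc + apply_noise(s, noise_sampler(n), gamma)
    acc / r
  }
  list(d = avg_noisy(), d_repeat = avg_noisy())
}

#' Two-sided two-group p-value
#'
#' @param d_x,d_y Group measurement vectors, each of length `>= 2`.
#' @param test `"welch_t"` (default), `"student_t"` or `"mann_whitney"`.
#' @return Two-sided p-value. If both groups are exactly constant the t
#'   statistic is undefined; the function returns 1 when the means agree and
#'   0 otherwise.
#' @export
pvalue_two_group <- function(d_x, d_y, test = c("welch_t", "student_t", "mann_whitney")) {
  test <- match.arg(test)
  if (length(d_x) < 2L || length(d_y) < 2L) {
    stop_insufficient("each group needs at least 2 values for a two-group test")
  }
  check_measurements(d_x, "d_x")
  check_measurements(d_y, "d_y")
  if (test == "mann_whitney") {
    return(suppressWarnings(
      stats::wilcox.test(d_x, d_y, alternative = "two.sided", exact = FALSE)$p.value))
  }
  if (stats::var(d_x) == 0 && stats::var(d_y) == 0) {
    return(if (mean(d_x) == mean(d_y)) 1 else 0)
  }
  stats::t.test(d_x, d_y, var.equal = (test == "student_t"),
                alternative = "two.sided")$p.value
}

#' Scan rxCOV and the p-value across noise levels
#'
#' The central in-silico experiment: for each gamma on a strictly increasing
#' positive grid, noisy data `d_X`, `d_Y` and their repeat aliquots are built
#' from the scenario's fixed clean signals (only the noise varies with
#' gamma), clipped at zero; Z is the paired absolute difference of the two
#' groups' primary measurements; N is the elementwise maximum of the two
#' groups' repeat-aliquot differences; rxCOV and a two-group p-value are
#' recorded. gamma = 0 is excluded because the metric diverges as the noise
#' vanishes.
#'
#' The zero crossing of the rxCOV track (`gamma_star`) is the
#' experiment-specific low-fidelity threshold; the crossing of the p-value
#' track at `alpha` (`gamma_sig`) locates where reported significance
#' changes. Points where `pvalue < alpha` but `rxcov <= 0` are flagged
#' `spurious`: the noise dominates and the significance is an artifact.
#'
#' @param sc An [scenario()].
#' @param gamma_grid Strictly increasing vector of positive noise
#'   multipliers.
#' @param r_replicates Replicates averaged per measurement (see
#'   [simulate_aliquot_pair()]).
#' @param test Significance test, see [pvalue_two_group()].
#' @param alpha Significance level in (0, 1).
#' @param k_smooth Number of independent noise realizations averaged per
#'   gamma for the rxCOV and p-value tracks (default 1; > 1 tames small-n
#'   jitter).
#' @param estimator Estimator for the summaries.
#' @param noise_draw `"redraw"` (fresh noise at every gamma, default) or
#'   `"fixed"` (one base draw scaled across the whole grid).
#' @return An object of class `gamma_scan`: `scan` (data.frame with columns
#'   `gamma`, `rxcov`, `mean_term`, `dispersion_term`, `pvalue`, `fidelity`,
#'   `spurious`, `status`), `gamma_star`, `gamma_sig`, `recrossings`,
#'   `n_replicates`, `k_smooth`, `test`, `alpha`, `seed`, `n_clipped`.
#' @export
gamma_scan <- function(sc, gamma_grid, r_replicates = 1L,
                       test = c("welch_t", "student_t", "mann_whitney"),
                       alpha = 0.05, k_smooth = 1L,
                       estimator = c("moment", "robust"),
                       noise_draw = c("redraw", "fixed")) {
  test <- match.arg(test)
  estimator <- match.arg(estimator)
  noise_draw <- match.arg(noise_draw)
  if (!is.numeric(gamma_grid) || length(gamma_grid) < 1L ||
      any(gamma_grid <= 0) || any(diff(gamma_grid) <= 0)) {
    stop_validation("`gamma_grid` must be strictly increasing and positive (gamma = 0 excluded)")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_validation("`alpha` must lie in (0, 1)")
  }
  if (!is.numeric(k_smooth) || length(k_smooth) != 1L || k_smooth < 1) {
    stop_config("`k_smooth` must be at least 1")
  }
  k_smooth <- as.integer(k_smooth)
  gen <- generate_scenario(sc)
  n <- sc$n_per_group
  r <- as.integer(r_replicates)
  n_clipped <- gen$n_clipped

  # In fixed-draw mode one base noise realization (enough for a full gamma
  # evaluation at every smoothing pass) is drawn up front and replayed,
  # scaled, at each gamma.
  if (noise_draw == "fixed") {
    need <- n * r * 2L * k_smooth  # per group: d and d_repeat, k passes
    fixed_x <- gen$draw_noise_x(need)
    fixed_y <- gen$draw_noise_y(need)
  }

  m <- length(gamma_grid)
  rx <- mt <- dt <- pv <- rep(NA_real_, m)
  status <- rep("ok", m)

  for (gi in seq_len(m)) {
    gamma <- gamma_grid[gi]
    if (noise_draw == "fixed") {
      pos_x <- 0L; pos_y <- 0L
      sampler_x <- function(mm) { out <- fixed_x[pos_x + seq_len(mm)]; pos_x <<- pos_x + mm; out }
      sampler_y <- function(mm) { out <- fixed_y[pos_y + seq_len(mm)]; pos_y <<- pos_y + mm; out }
    } else {
      sampler_x <- gen$draw_noise_x
      sampler_y <- gen$draw_noise_y
    }
    rx_k <- mt_k <- dt_k <- pv_k <- rep(NA_real_, k_smooth)
    stat_k <- character(k_smooth)
    for (k in seq_len(k_smooth)) {
      dx <- simulate_aliquot_pair(gen$s_x, gamma, sampler_x, r)
      dy <- simulate_aliquot_pair(gen$s_y, gamma, sampler_y, r)
      vals <- c(dx$d, dx$d_repeat, dy$d, dy$d_repeat)
      n_clipped <- n_clipped + sum(vals < 0)
      dx <- lapply(dx, pmax, 0)
      dy <- lapply(dy, pmax, 0)
      pv_k[k] <- pvalue_two_group(dx$d, dy$d, test)
      res <- tryCatch({
        z <- paired_differential(dx$d, dy$d, estimator)
        nv <- combine_noise(noise_from_repeats(dx$d, dx$d_repeat),
                            noise_from_repeats(dy$d, dy$d_repeat),
                            "elementwise_max")
        rxcov(z$summary, effect_stats(nv$n_values, estimator))
      }, rxcov_error = function(e) e)
      if (inherits(res, "rxcov_result")) {
        rx_k[k] <- res$rxcov; mt_k[k] <- res$mean_term; dt_k[k] <- res$dispersion_term
        stat_k[k] <- "ok"
      } else {
        all_zero_noise <- grepl("mu_n|sigma_n", conditionMessage(res))
        stat_k[k] <- if (all_zero_noise && gamma_scan_noise_free(dx, dy)) {
          "noise_free"
        } else {
          paste0("degenerate: ", conditionMessage(res))
        }
      }
    }
    ok <- stat_k == "ok"
    if (any(ok)) {
      rx[gi] <- mean(rx_k[ok]); mt[gi] <- mean(mt_k[ok]); dt[gi] <- mean(dt_k[ok])
      pv[gi] <- mean(pv_k[ok])
      status[gi] <- "ok"
    } else {
      pv[gi] <- mean(pv_k)
      status[gi] <- stat_k[1]
    }
  }

  fidelity <- ifelse(is.na(rx), NA_character_, ifelse(rx > 0, "high", "low"))
  spurious <- !is.na(rx) & !is.na(pv) & pv < alpha & rx <= 0
  gamma_star <- if (sum(is.finite(rx)) >= 2L) {
    find_zero_crossing(gamma_grid, rx)
  } else NA_real_
  gamma_sig <- if (sum(is.finite(pv)) >= 2L) {
    find_significance_crossing(gamma_grid, pv, alpha)
  } else NA_real_
  structure(
    list(scan = data.frame(gamma = gamma_grid, rxcov = rx, mean_term = mt,
                           dispersion_term = dt, pvalue = pv,
                           fidelity = fidelity, spurious = spurious,
                           status = status, stringsAsFactors = FALSE),
         gamma_star = gamma_star,
         gamma_sig = gamma_sig,
         recrossings = attr(gamma_star, "recrossings"),
         n_replicates = r, k_smooth = k_smooth, test = test, alpha = alpha,
         seed = sc$seed, n_clipped = n_clipped),
    class = "gamma_scan"
  )
}

gamma_scan_noise_free <- function(dx, dy) {
  all(dx$d == dx$d_repeat) && all(dy$d == dy$d_repeat)
}

#' @export
print.gamma_scan <- function(x, ...) {
  cat(sprintf("gamma_scan: %d points in [%g, %g], R = %d, k = %d, seed = %d\n",
              nrow(x$scan), min(x$scan$gamma), max(x$scan$gamma),
              x$n_replicates, x$k_smooth, x$seed))
  cat(sprintf("  gamma_star (rxCOV = 0): %s\n",
              if (is.na(x$gamma_star)) "not crossed" else format(x$gamma_star)))
  cat(sprintf("  gamma_sig  (p = %g):    %s\n", x$alpha,
              if (is.na(x$gamma_sig)) "not crossed" else format(x$gamma_sig)))
  if (any(x$scan$spurious, na.rm = TRUE)) {
    cat(sprintf("  %d point(s) flagged spurious (significant p but rxCOV <= 0)\n",
                sum(x$scan$spurious, na.rm = TRUE)))
  }
  invisible(x)
}

#' Locate the downward zero crossing of a track
#'
#' Finds the first pair of consecutive valid points with `track[i] > 0` and
#' `track[i+1] <= 0` and returns the linearly interpolated crossing abscissa;
#' an exact zero at a grid point returns that point. Later downward
#' re-crossings, if any, are attached as the `recrossings` attribute and
#' reported with a warning. Missing points are skipped.
#'
#' @param grid Increasing abscissa vector.
#' @param track Track values (may contain `NA`).
#' @return The crossing location, or `NA_real_` if the track never crosses
#'   zero downward.
#' @export
find_zero_crossing <- function(grid, track) {
  if (length(grid) != length(track)) stop_validation("`grid` and `track` must have equal length")
  keep <- !is.na(track) & is.finite(track)
  g <- grid[keep]; v <- track[keep]
  if (length(g) < 2L) stop_insufficient("need at least 2 valid points to locate a crossing")
  hits <- numeric(0)
  for (i in seq_len(length(g) - 1L)) {
    if (v[i] > 0 && v[i + 1L] <= 0) {
      hit <- if (v[i + 1L] == 0) g[i + 1L] else {
        g[i] + (g[i + 1L] - g[i]) * v[i] / (v[i] - v[i + 1L])
      }
      hits <- c(hits, hit)
    }
  }
  if (length(hits) == 0L) return(NA_real_)
  out <- hits[1]
  if (length(hits) > 1L) {
    warn_rxcov(sprintf("track re-crosses zero %d time(s) after the first crossing",
                       length(hits) - 1L))
    attr(out, "recrossings") <- hits[-1]
  }
  out
}

#' Locate the upward crossing of a p-value track at a significance level
#'
#' Finds the first pair of consecutive valid points with `p[i] < alpha` and
#' `p[i+1] >= alpha` and returns the linearly interpolated crossing.
#'
#' @param grid Increasing abscissa vector.
#' @param pvalues P-value track (may contain `NA`).
#' @param alpha Significance level in (0, 1).
#' @return The crossing location, or `NA_real_` if the track stays on one
#'   side of `alpha`.
#' @export
find_significance_crossing <- function(grid, pvalues, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_validation("`alpha` must lie in (0, 1)")
  }
  if (length(grid) != length(pvalues)) stop_validation("`grid` and `pvalues` must have equal length")
  keep <- !is.na(pvalues) & is.finite(pvalues)
  g <- grid[keep]; p <- pvalues[keep]
  if (length(g) < 2L) stop_insufficient("need at least 2 valid points to locate a crossing")
  for (i in seq_len(length(g) - 1L)) {
    if (p[i] < alpha && p[i + 1L] >= alpha) {
      return(g[i] + (g[i + 1L] - g[i]) * (alpha - p[i]) / (p[i + 1L] - p[i]))
    }
  }
  NA_real_
}
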