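#' Effect of replicate averaging on the fidelity threshold
#'
#' Runs [gamma_scan()] once per replicate count R, each scan re-seeded from
#' the same scenario seed so the clean signals are common, and collects the
#' zero-crossing threshold `gamma_star` per R together with per-point
#' sufficiency verdicts (`rxcov > 0`). Averaging R replicates divides the
#' effective noise scale by sqrt(R), so the threshold shifts right
#' approximately as sqrt(R) — the quantitative signature of the improved
#' signal-to-noise ratio.
#'
#' @param sc An [scenario()].
#' @param gamma_grid Strictly increasing positive grid.
#' @param replicate_counts Sorted vector of replicate counts, all `>= 1`.
#' @param ... Passed to [gamma_scan()].
#' @return An object of class `replicate_study`: `replicate_counts`,
#'   `gamma_star_by_r` (named numeric), `scans` (list of `gamma_scan`
#'   objects) and `sufficiency` (data.frame of gamma, r, rxcov, sufficient).
#' @export
replicate_study <- function(sc, gamma_grid, replicate_counts, ...) {
  if (!is.numeric(replicate_counts) || length(replicate_counts) < 1L ||
      any(replicate_counts < 1) || is.unsorted(replicate_counts, strictly = TRUE)) {
    stop_config("`replicate_counts` must be a sorted vector of counts >= 1")
  }
  replicate_counts <- as.integer(replicate_counts)
  scans <- lapply(replicate_counts, function(r) {
    gamma_scan(sc, gamma_grid, r_replicates = r, ...)
  })
  names(scans) <- paste0("R", replicate_counts)
  gamma_star_by_r <- vapply(scans, function(s) as.numeric(s$gamma_star), numeric(1))
  names(gamma_star_by_r) <- replicate_counts
  sufficiency <- do.call(rbind, lapply(seq_along(scans), function(i) {
    s <- scans[[i]]$scan
    data.frame(gamma = s$gamma, r = replicate_counts[i], rxcov = s$rxcov,
               sufficient = !is.na(s$rxcov) & s$rxcov > 0)
  }))
  rownames(sufficiency) <- NULL
  structure(
    list(replicate_counts = replicate_counts,
         gamma_star_by_r = gamma_star_by_r,
         scans = scans, sufficiency = sufficiency),
    class = "replicate_study"
  )
}

#' @export
print.replicate_study <- function(x, ...) {
  cat("replicate_study: gamma_star by replicate count\n")
  for (i in seq_along(x$replicate_counts)) {
    cat(sprintf("  R = %d: gamma_star = %s\n", x$replicate_counts[i],
                format(x$gamma_star_by_r[i])))
  }
  invisible(x)
}

#' Minimal number of replicates with high-fidelity rxCOV
#'
#' Applies the sufficiency rule for replicate averaging: average replicates
#' 1..R cumulatively, recompute rxCOV, and return the smallest R at which
#' `rxcov > 0`. If no available R is sufficient the verdict is explicit, not
#' an error — more replicates are required.
#'
#' @param table Long-format measurement table containing a `replicate`
#'   column (see [read_measurements()]); replicate indices must start at 1.
#' @param group_a,group_b Group labels.
#' @param ... Passed to [rxcov_table()] (mode, estimator, noise_mode).
#' @return A data.frame with one row per analyte: `analyte`,
#'   `sufficient_r` (`NA` when insufficient), `verdict`
#'   (`"sufficient"` / `"insufficient at max R"` / a status), and
#'   `max_r`. The per-R rxCOV track is attached as attribute `"by_r"`.
#' @export
replicate_sufficiency <- function(table, group_a, group_b, ...) {
  table <- validate_measurement_frame(table)
  reps <- sort(unique(as.integer(table$replicate)))
  if (length(reps) < 1L || reps[1] != 1L || any(diff(reps) != 1L)) {
    stop_validation("`replicate` indices must be consecutive integers starting at 1")
  }
  tracks <- list()
  for (r_max in reps) {
    sub <- table[table$replicate <= r_max, , drop = FALSE]
    agg <- stats::aggregate(value ~ sample_id + group + analyte + aliquot,
                            data = sub, FUN = mean)
    res <- suppressWarnings(rxcov_table(agg, group_a, group_b, ...))
    tracks[[as.character(r_max)]] <- data.frame(
      analyte = res$analyte, r = r_max, rxcov = res$rxcov,
      fidelity = res$fidelity, status = res$status, stringsAsFactors = FALSE)
  }
  by_r <- do.call(rbind, tracks)
  rownames(by_r) <- NULL
  analytes <- unique(by_r$analyte)
  out <- do.call(rbind, lapply(analytes, function(a) {
    tr <- by_r[by_r$analyte == a, , drop = FALSE]
    ok <- tr$status %in% c("ok", "noise_free") &
      (tr$status == "noise_free" | (!is.na(tr$rxcov) & tr$rxcov > 0))
    if (any(ok)) {
      data.frame(analyte = a, sufficient_r = min(tr$r[ok]),
                 verdict = "sufficient", max_r = max(reps),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(analyte = a, sufficient_r = NA_integer_,
                 verdict = "insufficient at max R", max_r = max(reps),
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(out) <- NULL
  attr(out, "by_r") <- by_r
  out
}
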