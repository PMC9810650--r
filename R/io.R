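#' Read a long-format measurement table from CSV
#'
#' Expected header: `sample_id, group, analyte, aliquot, value` with optional
#' `replicate` (defaults to 1) and `weight` columns. UTF-8, '.' decimal
#' separator. Rows with missing values are dropped with a logged count,
#' never imputed; duplicate keys, negative values and malformed aliquot
#' indices are validation errors listing the offending rows.
#'
#' @param path Path to a CSV file.
#' @param normalize_weight If `TRUE`, divide `value` by the `weight` column
#'   (which must then be present and strictly positive), removing variation
#'   due to sample size such as tissue biopsy weight.
#' @return A validated data.frame of class `measurement_table`.
#' @export
read_measurements <- function(path, normalize_weight = FALSE) {
  if (!file.exists(path)) stop_validation(sprintf("input file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  table <- validate_measurement_frame(raw)
  if (normalize_weight) {
    if (!"weight" %in% names(table)) {
      stop_validation("weight normalization requested but `weight` column is absent")
    }
    if (anyNA(table$weight)) stop_validation("`weight` contains missing values")
    table$value <- normalize_by_weight(table$value, table$weight)
  }
  class(table) <- c("measurement_table", "data.frame")
  table
}

#' Write a per-analyte rxCOV results table to CSV
#'
#' Floats are rendered with 6 significant digits so that identical runs
#' produce byte-identical files.
#'
#' @param results Data.frame from [rxcov_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rxcov_results <- function(results, path) {
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a gamma-scan track and its threshold summary to CSV
#'
#' @param scan A `gamma_scan` object.
#' @param scan_path Path for the per-gamma track CSV.
#' @param summary_path Optional path for the one-row threshold summary
#'   (gamma_star, gamma_sig, n_replicates, k_smooth, seed).
#' @return `scan_path`, invisibly.
#' @export
write_gamma_scan <- function(scan, scan_path, summary_path = NULL) {
  track <- scan$scan
  num <- vapply(track, is.numeric, logical(1))
  track[num] <- lapply(track[num], function(x) signif(x, 6))
  utils::write.csv(track, scan_path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(summary_path)) {
    summ <- data.frame(gamma_star = signif(as.numeric(scan$gamma_star), 6),
                       gamma_sig = signif(as.numeric(scan$gamma_sig), 6),
                       n_replicates = scan$n_replicates,
                       k_smooth = scan$k_smooth,
                       test = scan$test, alpha = scan$alpha,
                       seed = scan$seed, n_clipped = scan$n_clipped)
    utils::write.csv(summ, summary_path, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(scan_path)
}

#' Read a simulation configuration file (YAML)
#'
#' Recognized keys: `n_per_group`, `seed`, `signal_x`, `signal_y`,
#' `noise_x`, `noise_y` (each a mapping with `family`, `location`, `scale`),
#' `gamma` (`min`, `max`, `count`, `spacing: linear|log`), `r_replicates`
#' (scalar or list), `k_smooth`, `test`, `alpha`, `n_analytes`.
#' Missing distribution keys fall back to the canonical scenario defaults.
#'
#' @param path Path to a YAML config.
#' @return A list with `scenario` ([scenario()]), `gamma_grid`,
#'   `r_replicates`, `k_smooth`, `test`, `alpha`, `n_analytes`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("config file not found: %s", path))
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_config(sprintf("cannot parse config: %s",
                                                          conditionMessage(e))))
  if (!is.list(cfg)) stop_config("config must be a YAML mapping")
  get_dist <- function(key, default) {
    if (is.null(cfg[[key]])) return(default)
    d <- cfg[[key]]
    for (f in c("family", "location", "scale")) {
      if (is.null(d[[f]])) stop_config(sprintf("config key `%s` is missing field `%s`", key, f))
    }
    tryCatch(dist_spec(d$family, d$location, d$scale),
             rxcov_config_error = function(e) {
               stop_config(sprintf("config key `%s`: %s", key, conditionMessage(e)))
             })
  }
  sc <- scenario(
    n_per_group = cfg$n_per_group %||% 12,
    dist_sx = get_dist("signal_x", dist_spec("normal", 10, 2)),
    dist_sy = get_dist("signal_y", dist_spec("normal", 12.5, 2)),
    dist_noise_x = get_dist("noise_x", dist_spec("normal", 0, 1)),
    dist_noise_y = get_dist("noise_y", dist_spec("normal", 0, 1)),
    seed = cfg$seed %||% 1L
  )
  g <- cfg$gamma %||% list(min = 0.25, max = 8, count = 32, spacing = "linear")
  for (f in c("min", "max", "count")) {
    if (is.null(g[[f]])) stop_config(sprintf("config key `gamma` is missing field `%s`", f))
  }
  spacing <- g$spacing %||% "linear"
  if (!spacing %in% c("linear", "log")) {
    stop_config("config key `gamma.spacing` must be `linear` or `log`")
  }
  if (g$min <= 0 || g$max <= g$min || g$count < 2) {
    stop_config("config key `gamma` requires 0 < min < max and count >= 2")
  }
  gamma_grid <- if (spacing == "linear") {
    seq(g$min, g$max, length.out = g$count)
  } else {
    exp(seq(log(g$min), log(g$max), length.out = g$count))
  }
  list(scenario = sc,
       gamma_grid = gamma_grid,
       r_replicates = as.integer(unlist(cfg$r_replicates %||% 1L)),
       k_smooth = as.integer(cfg$k_smooth %||% 1L),
       test = cfg$test %||% "welch_t",
       alpha = cfg$alpha %||% 0.05,
       n_analytes = as.integer(cfg$n_analytes %||% 6L))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Generate a synthetic multiplexed measurement table
#'
#' Draws a complete long-format fixture from the simulation model: for each
#' analyte, fresh clean signals and noise are drawn from the scenario
#' distributions, every sample is measured on two aliquots (independent
#' noise), optionally for several independent replicates, and observed
#' expressions are clipped at zero. The output is a drop-in input for
#' [rxcov_table()] / [read_measurements()], so the whole pipeline is
#' testable without any external data.
#'
#' @param sc An [scenario()]; its seed fixes the whole table.
#' @param gamma Noise multiplier applied to every measurement.
#' @param n_analytes Number of analytes drawn independently.
#' @param r_replicates Number of independent replicate sets.
#' @param group_labels Character vector of the two group labels.
#' @return A data.frame of class `measurement_table` with columns
#'   `sample_id`, `group`, `analyte`, `aliquot`, `replicate`, `value`.
#' @export
make_fixture <- function(sc, gamma, n_analytes = 6L, r_replicates = 1L,
                         group_labels = c("A", "B")) {
  if (!inherits(sc, "rxcov_scenario")) stop_config("`sc` must be an rxcov scenario")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0) {
    stop_domain("`gamma` must be a single non-negative number")
  }
  if (n_analytes < 1L) stop_config("`n_analytes` must be at least 1")
  if (r_replicates < 1L) stop_config("`r_replicates` must be at least 1")
  if (length(group_labels) != 2L) stop_config("`group_labels` must have length 2")
  set.seed(sc$seed)
  n <- sc$n_per_group
  ids_a <- sprintf("%s%02d", group_labels[1], seq_len(n))
  ids_b <- sprintf("%s%02d", group_labels[2], seq_len(n))
  rows <- vector("list", n_analytes)
  for (a in seq_len(n_analytes)) {
    analyte <- sprintf("analyte_%02d", a)
    s_x <- pmax(draw_dist(sc$dist_sx, n), 0)
    s_y <- pmax(draw_dist(sc$dist_sy, n), 0)
    blocks <- list()
    for (r in seq_len(r_replicates)) {
      for (al in 1:2) {
        d_x <- pmax(apply_noise(s_x, draw_dist(sc$dist_noise_x, n), gamma), 0)
        d_y <- pmax(apply_noise(s_y, draw_dist(sc$dist_noise_y, n), gamma), 0)
        blocks[[length(blocks) + 1L]] <- data.frame(
          sample_id = c(ids_a, ids_b),
          group = rep(group_labels, each = n),
          analyte = analyte, aliquot = al, replicate = r,
          value = c(d_x, d_y), stringsAsFactors = FALSE)
      }
    }
    rows[[a]] <- do.call(rbind, blocks)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("measurement_table", "data.frame")
  out
}

#' Write a measurement table to CSV (6 significant digits)
#'
#' @param table A measurement table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  out <- as.data.frame(table)
  out$value <- signif(out$value, 6)
  if ("weight" %in% names(out)) out$weight <- signif(out$weight, 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a run manifest alongside an output file
#'
#' Records the command, its arguments, package version, seed and MD5 digests
#' of the input files — enough to re-run the command bit-identically (the
#' timestamp is informational and excluded from reproducibility checks).
#'
#' @param path Manifest path (JSON).
#' @param command Command name.
#' @param args Named list of arguments as run.
#' @param seed Seed in effect, if any.
#' @param inputs Character vector of input file paths to digest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, args = list(), seed = NULL, inputs = character(0)) {
  digests <- if (length(inputs) > 0) {
    d <- tools::md5sum(inputs)
    as.list(stats::setNames(unname(d), basename(inputs)))
  } else NULL
  manifest <- list(
    command = command,
    version = as.character(utils::packageVersion("rxcov")),
    seed = seed,
    args = args,
    input_md5 = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}
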