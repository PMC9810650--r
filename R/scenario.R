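#' Distribution specification for scenario components
#'
#' @param family `"normal"` or `"lognormal"`.
#' @param location Mean (normal) or meanlog (lognormal).
#' @param scale Standard deviation (normal) or sdlog (lognormal); `>= 0`
#'   (zero scale gives a degenerate point mass, useful for noise-free
#'   scenarios).
#' @return A list of class `dist_spec`.
#' @export
dist_spec <- function(family = c("normal", "lognormal"), location = 0, scale = 1) {
  if (length(family) == 1L && !family %in% c("normal", "lognormal")) {
    stop_config(sprintf("unsupported distribution family: %s", family))
  }
  family <- match.arg(family)
  if (!is.numeric(location) || length(location) != 1L || !is.finite(location)) {
    stop_config("`location` must be a single finite number")
  }
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale < 0) {
    stop_config("`scale` must be a single finite non-negative number")
  }
  structure(list(family = family, location = location, scale = scale),
            class = "dist_spec")
}

draw_dist <- function(spec, n) {
  switch(spec$family,
         normal = stats::rnorm(n, spec$location, spec$scale),
         lognormal = stats::rlnorm(n, spec$location, spec$scale))
}

#' Define a two-group simulation scenario
#'
#' A scenario bundles the clean-signal distributions of the two groups, the
#' base noise distribution of each group, the group size, and a seed. It is
#' the single source of truth for the noise-injection experiments
#' ([gamma_scan()], [replicate_study()], [make_fixture()]).
#'
#' @param n_per_group Samples per group, `>= 3`.
#' @param dist_sx,dist_sy [dist_spec()]s for the clean signals of groups X
#'   and Y.
#' @param dist_noise_x,dist_noise_y [dist_spec()]s for the base noise
#'   profiles (scaled by gamma at simulation time).
#' @param seed Integer RNG seed; fixed-seed runs are bit-reproducible.
#' @return A list of class `rxcov_scenario`.
#' @export
scenario <- function(n_per_group = 12,
                     dist_sx = dist_spec("normal", 10, 2),
                     dist_sy = dist_spec("normal", 12.5, 2),
                     dist_noise_x = dist_spec("normal", 0, 1),
                     dist_noise_y = dist_spec("normal", 0, 1),
                     seed = 1L) {
  if (!is.numeric(n_per_group) || length(n_per_group) != 1L || n_per_group < 3) {
    stop_config("`n_per_group` must be at least 3")
  }
  for (d in list(dist_sx, dist_sy, dist_noise_x, dist_noise_y)) {
    if (!inherits(d, "dist_spec")) stop_config("distributions must be dist_spec objects")
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_config("`seed` must be a single integer")
  }
  structure(
    list(n_per_group = as.integer(n_per_group),
         dist_sx = dist_sx, dist_sy = dist_sy,
         dist_noise_x = dist_noise_x, dist_noise_y = dist_noise_y,
         seed = as.integer(seed)),
    class = "rxcov_scenario"
  )
}

#' Canonical two-group cytokine scenario
#'
#' The package's reference conditions for the simulation experiments:
#' clean signals `s_X ~ Normal(10, 2)` and `s_Y ~ Normal(12.5, 2)` (a
#' separation a two-sample test detects at typical immunoassay group sizes),
#' with base noise `Normal(0, 1)` in noise scenario 1 and the slightly
#' shifted, wider `Normal(0.2, 1.1)` in noise scenario 2.
#'
#' @param noise_scenario 1 or 2.
#' @param n_per_group Samples per group (default 12).
#' @param seed RNG seed.
#' @return An [scenario()] object.
#' @export
canonical_scenario <- function(noise_scenario = 1, n_per_group = 12, seed = 1L) {
  if (!noise_scenario %in% c(1, 2)) stop_config("`noise_scenario` must be 1 or 2")
  noise <- if (noise_scenario == 1) dist_spec("normal", 0, 1) else dist_spec("normal", 0.2, 1.1)
  scenario(n_per_group = n_per_group,
           dist_sx = dist_spec("normal", 10, 2),
           dist_sy = dist_spec("normal", 12.5, 2),
           dist_noise_x = noise, dist_noise_y = noise,
           seed = seed)
}

#' Draw a scenario's clean signals and obtain its noise samplers
#'
#' Seeds the RNG with the scenario seed, draws the clean signal vectors
#' (clipped at zero — expressions are ratio-scale — with the clip count
#' recorded), and returns closures that draw i.i.d. base-noise values from
#' the scenario's noise distributions using the current RNG stream.
#'
#' @param sc An [scenario()].
#' @return A list with `s_x`, `s_y` (clean signal vectors),
#'   `draw_noise_x(n)`, `draw_noise_y(n)` (samplers) and `n_clipped`.
#' @export
generate_scenario <- function(sc) {
  if (!inherits(sc, "rxcov_scenario")) stop_config("`sc` must be an rxcov scenario")
  set.seed(sc$seed)
  n <- sc$n_per_group
  s_x <- draw_dist(sc$dist_sx, n)
  s_y <- draw_dist(sc$dist_sy, n)
  n_clipped <- sum(s_x < 0) + sum(s_y < 0)
  s_x <- pmax(s_x, 0)
  s_y <- pmax(s_y, 0)
  list(s_x = s_x, s_y = s_y,
       draw_noise_x = function(m) draw_dist(sc$dist_noise_x, m),
       draw_noise_y = function(m) draw_dist(sc$dist_noise_y, m),
       n_clipped = n_clipped)
}
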