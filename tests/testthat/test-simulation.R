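test_that("noise injection is exact arithmetic and gamma = 0 returns the signal", {
  expect_equal(apply_noise(c(10, 12), c(1, -2), 2), c(12, 8))
  s <- c(3.2, 4.5, 1.1)
  expect_identical(apply_noise(s, rnorm(3), 0), s)
  expect_error(apply_noise(s, rnorm(3), -0.1), class = "rxcov_domain_error")
  expect_error(apply_noise(s, rnorm(2), 1), class = "rxcov_validation_error")
})

test_that("scenario generation is deterministic under a fixed seed", {
  sc <- canonical_scenario(1, seed = 9L)
  g1 <- generate_scenario(sc)
  n1 <- g1$draw_noise_x(5)  # draws consume the seeded RNG stream
  g2 <- generate_scenario(sc)
  n2 <- g2$draw_noise_x(5)
  expect_identical(g1$s_x, g2$s_x)
  expect_identical(g1$s_y, g2$s_y)
  expect_identical(n1, n2)
  expect_error(scenario(n_per_group = 1), class = "rxcov_config_error")
  expect_error(dist_spec("cauchy"), class = "rxcov_config_error")
})

test_that("zero-scale noise produces identical aliquots", {
  sc <- scenario(n_per_group = 5, dist_noise_x = dist_spec("normal", 0, 0),
                 dist_noise_y = dist_spec("normal", 0, 0), seed = 2L)
  gen <- generate_scenario(sc)
  pair <- simulate_aliquot_pair(gen$s_x, 3, gen$draw_noise_x, 2)
  expect_identical(pair$d, gen$s_x)
  expect_identical(pair$d_repeat, gen$s_x)
})

test_that("replicate averaging shrinks noise variance like 1/R", {
  sc <- scenario(n_per_group = 2000, seed = 8L)
  gen <- generate_scenario(sc)
  gamma <- 2
  r <- 400
  pair <- simulate_aliquot_pair(gen$s_x, gamma, gen$draw_noise_x, r)
  v <- var(pair$d - gen$s_x)
  expect_equal(v, gamma^2 * 1 / r, tolerance = 0.15)
  expect_error(simulate_aliquot_pair(gen$s_x, 1, gen$draw_noise_x, 0),
               class = "rxcov_config_error")
})

test_that("two-group p-values behave at the extremes", {
  x <- c(1, 2, 3, 4)
  expect_equal(pvalue_two_group(x, x), 1)
  set.seed(6)
  a <- rnorm(20, 0, 1)
  b <- rnorm(20, 10, 1)  # means 10 sds apart
  expect_lt(pvalue_two_group(a, b), 1e-6)
  expect_lt(pvalue_two_group(a, b, "student_t"), 1e-6)
  expect_lt(pvalue_two_group(a, b, "mann_whitney"), 1e-6)
  expect_error(pvalue_two_group(1, c(1, 2)), class = "rxcov_insufficient_data_error")
})

test_that("zero-crossing detection interpolates and handles edge cases", {
  expect_equal(find_zero_crossing(c(0.25, 0.5, 0.75, 1), c(1, 0.5, 0, -0.5)), 0.75)
  expect_equal(as.numeric(find_zero_crossing(c(1, 2), c(0.5, -0.5))), 1.5)
  expect_true(is.na(find_zero_crossing(c(1, 2, 3), c(1, 2, 3))))
  expect_true(is.na(find_zero_crossing(c(1, 2, 3), c(-1, -2, -3))))
  # missing points are skipped
  expect_equal(as.numeric(find_zero_crossing(c(1, 2, 3, 4), c(0.5, NA, NA, -0.5))), 2.5)
  # re-crossings are reported
  expect_warning(
    out <- find_zero_crossing(c(1, 2, 3, 4), c(1, -1, 1, -1)),
    class = "rxcov_warning")
  expect_equal(as.numeric(out), 1.5)
  expect_equal(attr(out, "recrossings"), 3.5)
  expect_error(find_zero_crossing(1, 0.5), class = "rxcov_insufficient_data_error")
})

test_that("significance-crossing detection finds the first upward alpha crossing", {
  expect_equal(find_significance_crossing(c(1, 2), c(0.01, 0.10), 0.05),
               1 + 0.04 / 0.09)
  expect_true(is.na(find_significance_crossing(c(1, 2, 3), c(0.001, 0.01, 0.02))))
  expect_error(find_significance_crossing(c(1, 2), c(0.2, 0.5), alpha = 1.2),
               class = "rxcov_validation_error")
})

test_that("gamma scans are bit-identical under a fixed seed and reject bad grids", {
  sc <- canonical_scenario(1, seed = 4L)
  grid <- seq(0.5, 4, by = 0.5)
  s1 <- suppressWarnings(gamma_scan(sc, grid))
  s2 <- suppressWarnings(gamma_scan(sc, grid))
  expect_identical(s1$scan, s2$scan)
  expect_identical(s1$gamma_star, s2$gamma_star)
  expect_error(gamma_scan(sc, c(0, 1, 2)), class = "rxcov_validation_error")
  expect_error(gamma_scan(sc, c(2, 1)), class = "rxcov_validation_error")
})

test_that("fixed-draw scans scale one noise realization monotonically", {
  sc <- canonical_scenario(1, seed = 5L)
  s <- suppressWarnings(gamma_scan(sc, c(0.5, 1, 2, 4), noise_draw = "fixed"))
  # with one fixed draw, N scales exactly linearly with gamma, so the
  # dispersion and mean of N double when gamma doubles and the noise terms
  # of the metric shift by -2*log10(2) per doubling only through N
  expect_true(all(is.finite(s$scan$rxcov)))
  s2 <- suppressWarnings(gamma_scan(sc, c(0.5, 1, 2, 4), noise_draw = "fixed"))
  expect_identical(s$scan, s2$scan)
})

test_that("a noise-free scenario yields noise-free status at every gamma", {
  sc <- scenario(n_per_group = 6,
                 dist_noise_x = dist_spec("normal", 0, 0),
                 dist_noise_y = dist_spec("normal", 0, 0), seed = 3L)
  s <- gamma_scan(sc, c(1, 2))
  expect_true(all(s$scan$status == "noise_free"))
  expect_true(all(is.na(s$scan$rxcov)))
})

test_that("the rxcov track approaches the clipped noise-only asymptote at large gamma", {
  # Oracle: at gamma -> Inf, measurements become gamma * max(0, noise), so
  # Z and N depend only on the noise law; brute-force Monte Carlo gives the
  # limiting constant.
  set.seed(77)
  M <- 300000
  m0 <- function(t) pmax(0, t)
  a <- rnorm(M); b <- rnorm(M); a2 <- rnorm(M); b2 <- rnorm(M)
  z <- abs(m0(a) - m0(b))
  nv <- pmax(abs(m0(a) - m0(a2)), abs(m0(b) - m0(b2)))
  oracle <- log10((sd(z) / mean(nv)) / (sd(nv) / mean(z)))

  sc <- canonical_scenario(1, n_per_group = 2000, seed = 3L)
  s <- gamma_scan(sc, c(150, 200), k_smooth = 5)
  expect_lt(abs(s$scan$rxcov[2] - oracle), 0.05)
  expect_lt(s$scan$rxcov[2], 0)
})
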