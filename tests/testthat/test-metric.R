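test_that("relative change is a signed log10 ratio with the stated semantics", {
  expect_equal(relative_change(3, 3), 0)
  expect_equal(relative_change(10, 1), 1)
  expect_equal(relative_change(1, 10), -1)
  expect_error(relative_change(0, 1), class = "rxcov_domain_error")
  expect_error(relative_change(1, -2), class = "rxcov_domain_error")
})

test_that("rxcov evaluates the cross-COV ratio with separated terms", {
  r <- rxcov_of(5, 2, 3, 1)
  expect_equal(r$rxcov, log10(7.5))
  expect_equal(r$mean_term, log10(5 / 2))
  expect_equal(r$dispersion_term, log10(3))
  expect_identical(r$fidelity, "high")

  # equal statistics sit exactly on the threshold, classified low
  r0 <- rxcov_of(4, 4, 2, 2)
  expect_equal(r0$rxcov, 0)
  expect_identical(r0$fidelity, "low")

  # a common decade shift in Z adds two decades
  r2 <- rxcov_of(10 * 4, 4, 10 * 2, 2)
  expect_equal(r2$rxcov, 2)
})

test_that("degenerate statistics raise an error naming the offender", {
  expect_error(rxcov(effect_summary(0, 1), effect_summary(1, 1)),
               regexp = "mu_z", class = "rxcov_degenerate_error")
  expect_error(rxcov(effect_summary(1, 0), effect_summary(1, 1)),
               regexp = "sigma_z", class = "rxcov_degenerate_error")
  expect_error(rxcov(effect_summary(1, 1), effect_summary(0, 0)),
               regexp = "mu_n.*sigma_n", class = "rxcov_degenerate_error")
})

test_that("rxcov is additive in its mean and dispersion terms", {
  tuples <- random_stat_tuples(500, seed = 11L)
  for (i in seq_len(nrow(tuples))) {
    r <- with(tuples[i, ], rxcov_of(mu_z, mu_n, sigma_z, sigma_n))
    expect_lt(abs(r$rxcov - (r$mean_term + r$dispersion_term)), 1e-9)
  }
})

test_that("rxcov is invariant under a common rescaling of all measurements", {
  tuples <- random_stat_tuples(200, seed = 12L)
  for (alpha in c(1e-3, 1, 1e3)) {
    for (i in seq_len(nrow(tuples))) {
      t <- tuples[i, ]
      r1 <- rxcov_of(t$mu_z, t$mu_n, t$sigma_z, t$sigma_n)
      r2 <- rxcov_of(alpha * t$mu_z, alpha * t$mu_n,
                     alpha * t$sigma_z, alpha * t$sigma_n)
      expect_lt(abs(r1$rxcov - r2$rxcov), 1e-9)
    }
  }
})

test_that("the sign of rxcov matches the cross-COV comparison", {
  tuples <- random_stat_tuples(300, seed = 13L)
  for (i in seq_len(nrow(tuples))) {
    t <- tuples[i, ]
    r <- rxcov_of(t$mu_z, t$mu_n, t$sigma_z, t$sigma_n)
    expect_identical(r$rxcov > 0, (t$sigma_z / t$mu_n) > (t$sigma_n / t$mu_z))
    expect_identical(r$fidelity, if (r$rxcov > 0) "high" else "low")
  }
})

test_that("rxcov is monotone with hyperbolic partial slopes in each variable", {
  set.seed(14)
  pts <- matrix(runif(4 * 50, 0.5, 20), ncol = 4)
  signs <- c(mu_z = 1, mu_n = -1, sigma_z = 1, sigma_n = -1)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    names(p) <- names(signs)
    for (v in names(signs)) {
      h <- 1e-4 * p[[v]]
      up <- dn <- as.list(p)
      up[[v]] <- p[[v]] + h
      dn[[v]] <- p[[v]] - h
      f_up <- do.call(rxcov_of, up)$rxcov
      f_dn <- do.call(rxcov_of, dn)$rxcov
      slope <- (f_up - f_dn) / (2 * h)
      expect_lt(abs(slope - signs[[v]] / (p[[v]] * log(10))), 1e-6)
      # strict monotonicity in the direction of the sign
      expect_identical(f_up > f_dn, signs[[v]] > 0)
    }
  }
})

test_that("delta_rxcov matches its closed form and rejects out-of-domain input", {
  expect_equal(delta_rxcov(0, 0), 0)
  expect_equal(delta_rxcov(-0.5, 0), log10(0.5))
  expect_equal(delta_rxcov(0, 0.5), log10(1.5))
  expect_equal(delta_rxcov(-0.2, 0.3), log10(0.8) + log10(1.3))
  expect_error(delta_rxcov(-1, 0), class = "rxcov_domain_error")
  expect_error(delta_rxcov(0, -1.5), class = "rxcov_domain_error")
})

test_that("delta grid is zero at the origin, monotone, with extrema at corners", {
  g <- delta_grid(0.5, 0.5, 0.05)
  expect_equal(g$surface[length(g$rel_dmu), 1], 0)  # (0, 0) corner
  # monotone increasing along each coordinate
  expect_true(all(apply(g$surface, 2, function(col) all(diff(col) > 0))))
  expect_true(all(apply(g$surface, 1, function(row) all(diff(row) > 0))))
  expect_equal(g$min_value, g$surface[1, 1])
  expect_equal(g$max_value, g$surface[length(g$rel_dmu), length(g$rel_dsigma)])
  expect_equal(g$min_value, log10(0.5))
  expect_equal(g$max_value, log10(1.5))

  expect_error(delta_grid(1.2, 0.5, 0.01), class = "rxcov_validation_error")
  expect_error(delta_grid(0.5, 0.5, 0.6), class = "rxcov_validation_error")
  expect_error(delta_grid(0.5, -1, 0.01), class = "rxcov_validation_error")
})
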