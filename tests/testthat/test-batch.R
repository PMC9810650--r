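test_that("batch screening returns one verdict row per analyte", {
  tab <- toy_table()
  res <- rxcov_table(tab, "H", "LS")
  expect_equal(nrow(res), 2L)
  expect_setequal(res$analyte, c("IL6", "TNFa"))
  expect_true(all(res$status == "ok"))
  expect_true(all(res$fidelity %in% c("high", "low")))
  expect_equal(res$rxcov, res$mean_term + res$dispersion_term, tolerance = 1e-12)
})

test_that("batch results equal a direct brute-force evaluation on the raw table", {
  sc <- scenario(n_per_group = 10, seed = 21L)
  fx <- make_fixture(sc, gamma = 1.5, n_analytes = 4)
  res <- rxcov_table(fx, "A", "B", mode = "paired", noise_mode = "elementwise_max")
  for (a in res$analyte) {
    expect_equal(res$rxcov[res$analyte == a],
                 oracle_rxcov_from_table(fx, a, "A", "B"),
                 tolerance = 1e-12)
  }
})

test_that("an engineered high-fidelity analyte is verdicted high", {
  # Z statistics a decade above N on both terms
  n <- 8
  set.seed(33)
  y <- rnorm(n, 50, 10)
  x <- y + rnorm(n, 30, 8)          # large separation
  jitter <- rnorm(n, 0, 0.05)       # tiny assay noise
  tab <- data.frame(
    sample_id = rep(c(paste0("a", 1:n), paste0("b", 1:n)), 2),
    group = rep(rep(c("A", "B"), each = n), 2),
    analyte = "eng",
    aliquot = rep(1:2, each = 2 * n),
    value = pmax(c(x, y, x + jitter, y + jitter), 0))
  res <- rxcov_table(tab, "A", "B")
  expect_identical(res$fidelity, "high")
  expect_gt(res$rxcov, 1)
})

test_that("degenerate analytes carry a status without aborting the batch", {
  tab <- toy_table()
  const <- tab[tab$analyte == "IL6", ]
  const$analyte <- "flat"
  const$value <- 7  # constant everywhere: Z and N both degenerate
  res <- suppressWarnings(rxcov_table(rbind(tab, const), "H", "LS"))
  expect_equal(nrow(res), 3L)
  flat <- res[res$analyte == "flat", ]
  expect_match(flat$status, "degenerate|noise_free")
  expect_true(is.na(flat$rxcov))
  expect_true(all(res$status[res$analyte != "flat"] == "ok"))
})

test_that("identical aliquots yield the noise-free verdict, not a number", {
  tab <- toy_table()
  tab$value <- ave(tab$value, tab$sample_id, tab$analyte, FUN = function(v) v[1])
  res <- rxcov_table(tab, "H", "LS")
  expect_true(all(res$status == "noise_free"))
  expect_true(all(res$fidelity == "high"))
  expect_true(all(is.na(res$rxcov)))
})

test_that("missing groups and missing aliquot pairs are reported", {
  tab <- toy_table()
  expect_error(rxcov_table(tab, "H", "XX"), class = "rxcov_validation_error")
  broken <- tab[!(tab$analyte == "IL6" & tab$aliquot == 2 & tab$group == "H"), ]
  expect_warning(res <- rxcov_table(broken, "H", "LS"), class = "rxcov_warning")
  expect_match(res$status[res$analyte == "IL6"], "skipped")
  expect_identical(res$status[res$analyte == "TNFa"], "ok")
})

test_that("unpaired mode handles unequal group sizes via cross-product noise", {
  sc <- scenario(n_per_group = 16, seed = 22L)
  fx <- make_fixture(sc, gamma = 0.5, n_analytes = 2)
  # drop 4 samples from group B: 16 vs 12
  drop_ids <- sprintf("B%02d", 13:16)
  fx <- fx[!fx$sample_id %in% drop_ids, ]
  res <- rxcov_table(fx, "A", "B", mode = "unpaired")
  expect_true(all(res$status == "ok"))
  expect_equal(res$n_a, c(16L, 16L))
  expect_equal(res$n_b, c(12L, 12L))
  # oracle: summary-level Z and enumerated cross-product N
  for (a in res$analyte) {
    sub <- fx[fx$analyte == a, ]
    grab <- function(gr, al) {
      s <- sub[sub$group == gr & sub$aliquot == al, ]
      s$value[order(s$sample_id)]
    }
    x1 <- grab("A", 1); x2 <- grab("A", 2)
    y1 <- grab("B", 1); y2 <- grab("B", 2)
    mu_z <- abs(mean(x1) - mean(y1))
    sigma_z <- sqrt(var(x1) + var(y1))
    nv <- as.vector(outer(abs(x1 - x2), abs(y1 - y2), pmax))
    expected <- log10((sigma_z / mean(nv)) / (sd(nv) / mu_z))
    expect_equal(res$rxcov[res$analyte == a], expected, tolerance = 1e-12)
  }
})

test_that("robust estimator mode propagates through the batch", {
  sc <- scenario(n_per_group = 12, seed = 23L)
  fx <- make_fixture(sc, gamma = 1, n_analytes = 2)
  res <- rxcov_table(fx, "A", "B", estimator = "robust")
  expect_true(all(res$estimator == "robust"))
  expect_true(all(res$status == "ok"))
  # location of Z is the median of the paired absolute differences
  sub <- fx[fx$analyte == "analyte_01", ]
  grab <- function(gr, al) {
    s <- sub[sub$group == gr & sub$aliquot == al, ]
    s$value[order(s$sample_id)]
  }
  z <- abs(grab("A", 1) - grab("B", 1))
  expect_equal(res$mu_z[res$analyte == "analyte_01"], median(z))
})
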