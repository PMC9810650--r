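# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files are read.

# Random strictly positive four-statistic tuples for metric property tests.
random_stat_tuples <- function(n, seed = 42L) {
  set.seed(seed)
  data.frame(mu_z = rlnorm(n, 1, 1), mu_n = rlnorm(n, 0, 1),
             sigma_z = rlnorm(n, 0.5, 1), sigma_n = rlnorm(n, -0.5, 1))
}

rxcov_of <- function(mu_z, mu_n, sigma_z, sigma_n) {
  rxcov(effect_summary(mu_z, sigma_z), effect_summary(mu_n, sigma_n))
}

# Independent brute-force evaluation of the metric straight from a raw
# long-format table (pure base R, no package internals): Z as paired
# absolute differences of aliquot-1 values, N as the elementwise max of the
# two groups' repeat-aliquot differences.
oracle_rxcov_from_table <- function(tab, analyte, group_a, group_b) {
  sub <- tab[tab$analyte == analyte, ]
  grab <- function(gr, al) {
    s <- sub[sub$group == gr & sub$aliquot == al, ]
    s$value[order(s$sample_id)]
  }
  x1 <- grab(group_a, 1); x2 <- grab(group_a, 2)
  y1 <- grab(group_b, 1); y2 <- grab(group_b, 2)
  z <- abs(x1 - y1)
  nv <- pmax(abs(x1 - x2), abs(y1 - y2))
  log10((sd(z) / mean(nv)) / (sd(nv) / mean(z)))
}

# A tiny hand-assembled two-analyte table with duplicate aliquots.
toy_table <- function() {
  grid <- expand.grid(sample_i = 1:4, group = c("H", "LS"),
                      analyte = c("IL6", "TNFa"), aliquot = 1:2,
                      stringsAsFactors = FALSE)
  set.seed(5)
  base <- 10 + 2 * as.integer(grid$group == "LS") + rnorm(nrow(grid), 0, 0.3)
  data.frame(sample_id = paste0(grid$group, grid$sample_i),
             group = grid$group, analyte = grid$analyte,
             aliquot = grid$aliquot, value = pmax(base, 0),
             stringsAsFactors = FALSE)
}

write_canonical_config <- function(path, n_per_group = 12, seed = 1,
                                   gamma_max = 8, gamma_count = 32,
                                   r_replicates = "[1]") {
  writeLines(c(
    sprintf("n_per_group: %d", n_per_group),
    sprintf("seed: %d", seed),
    "signal_x: {family: normal, location: 10, scale: 2}",
    "signal_y: {family: normal, location: 12.5, scale: 2}",
    "noise_x: {family: normal, location: 0, scale: 1}",
    "noise_y: {family: normal, location: 0, scale: 1}",
    sprintf("gamma: {min: 0.25, max: %g, count: %d, spacing: linear}", gamma_max, gamma_count),
    sprintf("r_replicates: %s", r_replicates),
    "k_smooth: 1",
    "test: welch_t",
    "alpha: 0.05",
    "n_analytes: 3"), path)
  path
}
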