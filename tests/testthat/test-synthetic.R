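# Droplet-level simulator: Poisson occupancy, clone mixtures, expression.

test_that("simulators are bit-reproducible given a seed", {
  w1 <- simulate_well(1, 0.5, n_droplets = 20000, seed = 99)
  w2 <- simulate_well(1, 0.5, n_droplets = 20000, seed = 99)
  expect_identical(unclass(w1), unclass(w2))
  cfg <- simulation_config(loss_chain_model(), c(0.26, 0.07, 0.67), seed = 5)
  expect_identical(simulate_tumor(cfg)$wells, simulate_tumor(cfg)$wells)
  expect_identical(simulate_expression(cfg)$dna$n_allele1,
                   simulate_expression(cfg)$dna$n_allele1)
})

test_that("seeded simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(simulate_well(1, 1, seed = 42))
  expect_identical(runif(1), a)
})

test_that("droplet occupancy follows 1 - exp(-lambda)", {
  w0 <- simulate_well(0, 0, n_droplets = 1000, seed = 1)
  expect_equal(w0$n_negative, 1000L)
  n <- 1e5
  w <- simulate_well(1, 0, n_droplets = n, seed = 2)
  p_pos <- (w$n_double_pos + w$n_ch1_only) / n
  p_true <- 1 - exp(-1)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(p_pos - p_true), 3 * se)
})

test_that("co-encapsulation of the two targets is independent", {
  n <- 1e5
  l1 <- 0.8
  l2 <- 0.4
  w <- simulate_well(l1, l2, n_droplets = n, seed = 3)
  p_dp <- (1 - exp(-l1)) * (1 - exp(-l2))
  se <- sqrt(p_dp * (1 - p_dp) / n)
  expect_lt(abs(w$n_double_pos / n - p_dp), 3 * se)
})

test_that("empirical positive fractions converge to the Poisson curve", {
  n <- 1e6
  for (lam in c(0.1, 0.5, 1.5)) {
    w <- simulate_well(lam, 0, n_droplets = n, seed = round(100 * lam))
    p_true <- 1 - exp(-lam)
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs((w$n_double_pos + w$n_ch1_only) / n - p_true), 3 * se)
  }
})

test_that("a healthy-only tumour shows no mutation and diploid loci", {
  cfg <- simulation_config(loss_chain_model(), c(1, 0, 0), seed = 8)
  sim <- simulate_tumor(cfg)
  rep <- run_pipeline(sim$panel, cfg$clone_model, sim$wells)
  expect_equal(rep$maf$fraction, 0, tolerance = 1e-6)
  for (lid in names(rep$cn)) {
    expect_gte(rep$cn[[lid]]$ci95[2], 2)
    expect_lte(rep$cn[[lid]]$ci95[1], 2)
  }
})

test_that("simulated measurements recover the forward-model truth", {
  cfg <- simulation_config(loss_chain_model(), c(0.26, 0.07, 0.67),
                           seed = 21, n_droplets = 1e5,
                           input_copies_per_assay = 5e4)
  sim <- simulate_tumor(cfg)
  expect_equal(sim$truth$maf, 0.74 / 1.33, tolerance = 1e-9)
  expect_equal(unname(sim$truth$cn["CYSLTR2"]), 1.33)
  rep <- run_pipeline(sim$panel, cfg$clone_model, sim$wells, seed = 22)
  expect_equal(rep$maf$fraction, sim$truth$maf, tolerance = 0.01)
  expect_equal(rep$cn[["CYSLTR2"]]$cn, 1.33, tolerance = 0.03)
  expect_equal(unname(rep$composition$proportions),
               c(0.26, 0.07, 0.67), tolerance = 0.02)
})

test_that("end-to-end recovery works for the gain chain too", {
  cfg <- simulation_config(gain_chain_model(), c(0.15, 0.17, 0.68),
                           seed = 31, n_droplets = 1e5,
                           input_copies_per_assay = 5e4)
  sim <- simulate_tumor(cfg)
  rep <- run_pipeline(sim$panel, cfg$clone_model, sim$wells, seed = 32)
  truth <- c(0.15, 0.17, 0.68)
  for (p in 1:3) {
    expect_lte(rep$composition$ci95[1, p], truth[p] + 0.02)
    expect_gte(rep$composition$ci95[2, p], truth[p] - 0.02)
  }
})

test_that("expression simulation honours the allelic skew", {
  m <- gain_chain_model()  # clone II: 2 mut + 1 wt
  base <- function(skew, seed) {
    simulate_expression(simulation_config(
      m, c(0, 0, 1), seed = seed, rna_skew = skew,
      rna_depth = 2e4, dna_depth = 2e4))
  }
  # balanced skew: RNA fraction tracks the DNA fraction (2/3)
  bal <- base(0.5, 41)
  expect_equal(bal$truth$rna_fraction, bal$truth$dna_fraction)
  expect_equal(bal$truth$dna_fraction, 2 / 3, tolerance = 1e-9)
  # monoallelic expression regardless of DNA dosage
  mono <- base(1, 42)
  expect_equal(mono$truth$rna_fraction, 1)
  expect_equal(mono$rna$n_allele2, 0L)
  # skew 0.8 on (2 mut, 1 wt): expected 1.6/1.8
  sk <- base(0.8, 43)
  expect_equal(sk$truth$rna_fraction, (2 * 0.8) / (2 * 0.8 + 1 * 0.2),
               tolerance = 1e-9)
  obs <- sk$rna$n_allele1 / (sk$rna$n_allele1 + sk$rna$n_allele2)
  se <- sqrt(sk$truth$rna_fraction * (1 - sk$truth$rna_fraction) / 2e4)
  expect_lt(abs(obs - sk$truth$rna_fraction), 4 * se)
})
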