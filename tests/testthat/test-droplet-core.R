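# Measurement layer: Poisson correction, duplex quantification, allele
# fractions and copy-number ratios.

test_that("poisson_lambda recovers the closed-form occupancy", {
  expect_identical(poisson_lambda(0, 10000)$lambda_hat, 0)
  # 6321/10000 positives sits at the 1 - e^-1 point
  expect_equal(poisson_lambda(6321, 10000)$lambda_hat, 1, tolerance = 1e-3)
  # frozen: -log(0.75) evaluated independently
  expect_equal(poisson_lambda(5000, 20000)$lambda_hat, 0.2876820725,
               tolerance = 1e-9)
})

test_that("poisson_lambda intervals and units are coherent", {
  est <- poisson_lambda(5000, 20000)
  expect_lte(est$ci95[1], est$lambda_hat)
  expect_gte(est$ci95[2], est$lambda_hat)
  expect_equal(est$copies_per_ul, est$lambda_hat / (0.85e-3))
  # zero positives: point estimate 0 but a positive upper bound
  zero <- poisson_lambda(0, 10000)
  expect_identical(zero$ci95[1], 0)
  expect_gt(zero$ci95[2], 0)
  expect_gt(zero$se, 0)
})

test_that("saturated and empty wells are errors, not infinities", {
  expect_error(poisson_lambda(100, 100), class = "saturation_error")
  expect_error(poisson_lambda(0, 0), class = "empty_well_error")
  w <- droplet_well("sat", 100, 0, 0, 0)
  expect_error(duplex_quantify(w), class = "saturation_error")
})

test_that("lambda is monotone in the positive count and zero at zero", {
  n <- 5000
  lams <- vapply(seq(0, n - 1, by = 250), function(k) {
    poisson_lambda(k, n)$lambda_hat
  }, numeric(1))
  expect_identical(lams[1], 0)
  expect_true(all(diff(lams) > 0))
})

test_that("duplex channels share double-positive droplets", {
  # mutant-negative well: channel 1 empty, channel 2 quantified
  w0 <- droplet_well("neg", 0, 0, 4000, 16000)
  q0 <- duplex_quantify(w0)
  expect_identical(q0$ch1$lambda_hat, 0)
  expect_equal(q0$ch2$lambda_hat, -log(0.8), tolerance = 1e-12)
  # symmetric channels agree exactly
  w1 <- droplet_well("sym", 100, 900, 900, 18100)
  q1 <- duplex_quantify(w1)
  expect_equal(q1$ch1$lambda_hat, q1$ch2$lambda_hat)
  expect_equal(q1$ch1$lambda_hat, -log(0.95), tolerance = 1e-12)
  # channel totals: positives on ch1 = double_pos + ch1_only
  w2 <- droplet_well("gen", 123, 456, 789, 10000)
  q2 <- duplex_quantify(w2)
  expect_equal(q2$ch1$lambda_hat,
               poisson_lambda(123 + 456, n_droplets(w2))$lambda_hat)
  expect_equal(q2$ch2$lambda_hat,
               poisson_lambda(123 + 789, n_droplets(w2))$lambda_hat)
})

test_that("pooling replicate wells sums counts before correction", {
  a <- droplet_well("a", 10, 100, 200, 9690)
  b <- droplet_well("b", 20, 150, 180, 9650)
  pooled <- pool_wells(list(a, b))
  expect_equal(n_droplets(pooled), 20000)
  expect_equal(pooled$n_double_pos, 30L)
  expect_error(
    pool_wells(list(a, droplet_well("c", 1, 1, 1, 1, droplet_volume_nl = 1))),
    class = "invalid_well_error"
  )
})

test_that("allele fraction behaves at its reference points", {
  wt <- poisson_lambda(6593, 20000)  # lambda ~ 0.4
  mut0 <- poisson_lambda(0, 20000)
  f0 <- allele_fraction(mut0, wt, allele_labels = c("mut", "wt"))
  expect_identical(f0$fraction, 0)
  expect_gt(f0$ci95[2], 0)          # absence of mutant still has uncertainty
  x <- poisson_lambda(3000, 20000)
  expect_equal(allele_fraction(x, x)$fraction, 0.5)
  expect_error(allele_fraction(mut0, poisson_lambda(0, 20000)),
               class = "undefined_fraction_error")
})

test_that("allele fraction reproduces a known mutant fraction and is scale-free", {
  # lambda ratio 0.184 : 0.816 gives fraction 0.184 regardless of scale
  make <- function(lam, n = 2e5) {
    poisson_lambda(round(n * (1 - exp(-lam))), n)
  }
  for (scale in c(0.5, 1, 2)) {
    f <- allele_fraction(make(0.184 * scale), make(0.816 * scale))
    expect_equal(f$fraction, 0.184, tolerance = 2e-3)
  }
  expect_true(all(allele_fraction(make(0.184), make(0.816))$ci95 >= 0))
})

test_that("delta and bootstrap fraction intervals agree at large counts", {
  mut <- poisson_lambda(1800, 20000)
  wt <- poisson_lambda(7600, 20000)
  fd <- allele_fraction(mut, wt)
  fb <- allele_fraction(mut, wt, ci_method = "bootstrap", seed = 11)
  expect_equal(fd$fraction, fb$fraction)
  expect_equal(fd$ci95, fb$ci95, tolerance = 0.01)
  # bootstrap is reproducible under its seed
  fb2 <- allele_fraction(mut, wt, ci_method = "bootstrap", seed = 11)
  expect_identical(fb$ci95, fb2$ci95)
})

test_that("copy number is the reference-scaled ratio", {
  r <- poisson_lambda(5000, 20000)
  expect_equal(copy_number(r, r)$cn, 2)
  # lambda_t = 0.665 lambda_r -> cn 1.33 (single-copy loss in 67% of cells)
  make <- function(lam, n = 1e6) poisson_lambda(round(n * (1 - exp(-lam))), n)
  expect_equal(copy_number(make(0.665 * 0.5), make(0.5))$cn, 1.33,
               tolerance = 2e-3)
  expect_equal(copy_number(make(1.34 * 0.5), make(0.5))$cn, 2.68,
               tolerance = 2e-3)
  expect_error(copy_number(r, poisson_lambda(0, 20000)),
               class = "no_reference_error")
})

test_that("copy number CI is ordered and contains the estimate", {
  t <- poisson_lambda(3400, 20000)
  r <- poisson_lambda(5000, 20000)
  cn <- copy_number(t, r)
  expect_lte(cn$ci95[1], cn$cn)
  expect_gte(cn$ci95[2], cn$cn)
})
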