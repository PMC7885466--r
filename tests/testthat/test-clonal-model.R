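# Cell-level layer: aberrant fractions, mutant cell fraction, forward
# model, deconvolution and event ordering.

make_cn <- function(lam_ratio, n = 1e6, base = 0.5) {
  make <- function(lam) poisson_lambda(round(n * (1 - exp(-lam))), n)
  copy_number(make(lam_ratio * base), make(base))
}

test_that("aberrant fraction inverts the average copy number", {
  r <- poisson_lambda(5000, 20000)
  expect_equal(aberrant_fraction_from_cn(copy_number(r, r), "loss")$fraction, 0)
  expect_equal(aberrant_fraction_from_cn(make_cn(0.665), "loss")$fraction,
               0.67, tolerance = 5e-3)
  expect_equal(aberrant_fraction_from_cn(make_cn(1.34), "gain")$fraction,
               0.68, tolerance = 5e-3)
  # direction inconsistent with the measured copy number
  expect_error(aberrant_fraction_from_cn(make_cn(1.34), "loss"),
               class = "direction_mismatch_error")
  expect_error(aberrant_fraction_from_cn(make_cn(0.665), "gain"),
               class = "direction_mismatch_error")
})

test_that("SNP imbalance yields the aberrant-cell fraction", {
  make <- function(lam, n = 1e6) poisson_lambda(round(n * (1 - exp(-lam))), n)
  ret <- make(0.5)
  expect_equal(
    aberrant_fraction_from_snp(ret, ret, "loss")$fraction, 0)
  # affected/retained = 0.33 under loss: f = 1 - 0.33
  expect_equal(
    aberrant_fraction_from_snp(ret, make(0.33 * 0.5), "loss")$fraction,
    0.67, tolerance = 5e-3)
  # affected/retained = 1.45 under gain: f = 0.45
  expect_equal(
    aberrant_fraction_from_snp(ret, make(1.45 * 0.5), "gain")$fraction,
    0.45, tolerance = 5e-3)
  expect_error(aberrant_fraction_from_snp(ret, make(1.45 * 0.5), "loss"),
               class = "model_mismatch_error")
})

make_maf <- function(f, n = 1e6, total = 1) {
  make <- function(lam) poisson_lambda(round(n * (1 - exp(-lam))), n)
  allele_fraction(make(f * total), make((1 - f) * total),
                  allele_labels = c("mut", "wt"))
}

test_that("mutant cell fraction corrects the allele fraction for copy number", {
  # diploid heterozygous: MCF = 2 x MAF, exactly
  maf18 <- make_maf(0.18)
  expect_equal(mutant_cell_fraction(maf18)$fraction, 2 * maf18$fraction)
  expect_equal(mutant_cell_fraction(maf18)$fraction, 0.36, tolerance = 1e-3)
  # fully mutant heterozygous tumour
  expect_equal(mutant_cell_fraction(make_maf(0.5))$fraction, 1, tolerance = 2e-3)
  # gain of the mutant allele in 68% of cells, MAF 57% -> MCF ~ 0.8476
  gain <- aberrant_fraction_from_cn(make_cn(1.34), "gain")
  expect_equal(mutant_cell_fraction(make_maf(0.57), gain)$fraction, 0.8476,
               tolerance = 5e-3)
  # loss of wild type in 67%, MAF 55% -> MCF ~ 0.7315
  loss <- aberrant_fraction_from_cn(make_cn(0.665), "loss")
  expect_equal(mutant_cell_fraction(make_maf(0.55), loss)$fraction, 0.7315,
               tolerance = 5e-3)
})

test_that("inconsistent MAF and copy-number measurements are flagged", {
  # MAF 90% with only a 67% loss implies MCF ~ 1.2: impossible
  loss <- aberrant_fraction_from_cn(make_cn(0.665), "loss")
  expect_error(mutant_cell_fraction(make_maf(0.9), loss),
               class = "inconsistent_measurements_error")
  # model direction check: a gain-type correction under a loss-chain model
  gain <- aberrant_fraction_from_cn(make_cn(1.34), "gain")
  expect_error(
    mutant_cell_fraction(make_maf(0.57), gain,
                         model = loss_chain_model_1locus(),
                         mutation_locus = "CYSLTR2"),
    class = "model_mismatch_error"
  )
})

test_that("forward model averages copies over the composition", {
  m_loss <- loss_chain_model_1locus()
  # pure germline: no mutant alleles, diploid everywhere
  pure <- forward_model(m_loss, c(1, 0, 0))
  expect_equal(predicted_fraction(pure, "CYSLTR2", "mut"), 0)
  expect_equal(unname(pure$cn["CYSLTR2"]), 2)
  # loss chain at (0.26, 0.07, 0.67): MAF = 0.74/1.33, cn = 1.33
  p1 <- forward_model(m_loss, c(0.26, 0.07, 0.67))
  expect_equal(predicted_fraction(p1, "CYSLTR2", "mut"), 0.5563909774,
               tolerance = 1e-9)
  expect_equal(unname(p1$cn["CYSLTR2"]), 1.33)
  # gain chain at (0.15, 0.17, 0.68): MAF = 1.53/2.68
  p2 <- forward_model(gain_chain_model(), c(0.15, 0.17, 0.68))
  expect_equal(predicted_fraction(p2, "CYSLTR2", "mut"), 1.53 / 2.68,
               tolerance = 1e-9)
})

test_that("deconvolution solves the textbook two-population case", {
  two_pop <- clone_model(
    loci = list(locus("CYSLTR2", c("mut", "wt"))),
    populations = list(
      population("healthy", list(CYSLTR2 = c(mut = 0, wt = 2))),
      population("clone", list(CYSLTR2 = c(mut = 1, wt = 1)))
    )
  )
  obs <- data.frame(statistic = "maf", locus_id = "CYSLTR2", value = 0.25)
  w <- deconvolve(two_pop, obs, ci = FALSE)$proportions
  expect_equal(unname(w), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("deconvolution reproduces nested-clone compositions", {
  # loss chain: mutation-positive 74%, loss 67% -> (26, 7, 67)%
  obs1 <- data.frame(statistic = c("mcf", "aberrant_fraction"),
                     locus_id = "CYSLTR2", value = c(0.74, 0.67),
                     alteration = c(NA, "loss"))
  w1 <- deconvolve(loss_chain_model_1locus(), obs1, ci = FALSE)$proportions
  expect_equal(unname(w1), c(0.26, 0.07, 0.67), tolerance = 1e-9)
  # equivalent observation set via MAF + copy number
  obs1b <- data.frame(statistic = c("maf", "cn"), locus_id = "CYSLTR2",
                      value = c(0.74 / 1.33, 1.33))
  w1b <- deconvolve(loss_chain_model_1locus(), obs1b, ci = FALSE)$proportions
  expect_equal(unname(w1b), c(0.26, 0.07, 0.67), tolerance = 1e-9)
  # gain chain: mutation-positive 83%, gain 45% -> (17, 38, 45)%
  obs2 <- data.frame(statistic = c("mcf", "aberrant_fraction"),
                     locus_id = "CYSLTR2", value = c(0.83, 0.45),
                     alteration = c(NA, "gain"))
  w2 <- deconvolve(gain_chain_model(), obs2, ci = FALSE)$proportions
  expect_equal(unname(w2), c(0.17, 0.38, 0.45), tolerance = 1e-9)
})

test_that("deconvolution output lies on the simplex with matching clone sum", {
  set.seed(404)
  for (i in 1:25) {
    m <- random_chain_model()
    w_true <- random_interior_composition()
    obs <- noise_free_observations(m, w_true)
    fit <- deconvolve(m, obs, ci = FALSE)
    expect_equal(sum(fit$proportions), 1, tolerance = 1e-9)
    expect_true(all(fit$proportions >= 0))
    # clone I + clone II = mutant cell fraction (mutation defines clone I)
    expect_equal(unname(sum(fit$proportions[2:3])), obs$value[obs$statistic == "mcf"],
                 tolerance = 1e-6)
  }
})

test_that("unidentifiable and contradictory observation sets raise errors", {
  # clone I and clone II indistinguishable from the mutation alone
  err <- tryCatch(
    deconvolve(loss_chain_model_1locus(),
               data.frame(statistic = "mcf", locus_id = "CYSLTR2", value = 0.7),
               ci = FALSE),
    unidentifiable_model_error = function(e) e
  )
  expect_s3_class(err, "unidentifiable_model_error")
  expect_match(conditionMessage(err), "cloneI|cloneII")
  # loss fraction exceeding the mutant fraction contradicts nesting
  expect_error(
    deconvolve(loss_chain_model_1locus(),
               data.frame(statistic = c("mcf", "aberrant_fraction"),
                          locus_id = "CYSLTR2", value = c(0.3, 0.6),
                          alteration = c(NA, "loss")),
               ci = FALSE),
    class = "model_mismatch_error"
  )
})

test_that("bootstrap composition intervals are seeded and cover the point", {
  obs <- data.frame(statistic = c("mcf", "aberrant_fraction"),
                    locus_id = "CYSLTR2", value = c(0.74, 0.67),
                    ci_low = c(0.72, 0.65), ci_high = c(0.76, 0.69),
                    alteration = c(NA, "loss"))
  d1 <- deconvolve(loss_chain_model_1locus(), obs, seed = 7)
  d2 <- deconvolve(loss_chain_model_1locus(), obs, seed = 7)
  expect_identical(d1$ci95, d2$ci95)
  expect_identical(d1$seed, 7)
  for (p in seq_along(d1$proportions)) {
    expect_lte(d1$ci95[1, p], d1$proportions[p] + 1e-9)
    expect_gte(d1$ci95[2, p], d1$proportions[p] - 1e-9)
  }
})

test_that("event ordering groups indistinguishable fractions as clonal", {
  tight <- data.frame(
    event = c("mut", "8q_gain", "1p_loss", "16q_loss"),
    fraction = 0.74, se = 0.005
  )
  out <- order_events(tight)
  expect_true(all(out$label == "clonal"))
  expect_equal(length(unique(out$group)), 1L)
})

test_that("separated fractions split into clonal and subclonal groups", {
  ev <- data.frame(event = c("mut", "13q_loss"),
                   fraction = c(0.74, 0.67),
                   ci_low = c(0.72, 0.65), ci_high = c(0.76, 0.69))
  out <- order_events(ev)
  expect_equal(out$label[out$event == "mut"], "clonal")
  expect_equal(out$label[out$event == "13q_loss"], "subclonal")
})

test_that("event ordering is invariant under input permutation", {
  ev <- data.frame(event = c("a", "b", "c"),
                   fraction = c(0.74, 0.67, 0.745),
                   se = c(0.004, 0.004, 0.004))
  ref <- order_events(ev)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    out <- order_events(ev[perm, ])
    expect_identical(out$event, ref$event)
    expect_identical(out$label, ref$label)
  }
  # single event: trivially clonal, not an error
  one <- order_events(ev[1, ])
  expect_identical(one$label, "clonal")
})

test_that("clone models validate their invariants", {
  expect_error(
    clone_model(
      loci = list(locus("L", c("a", "b"))),
      populations = list(population("healthy", list(L = c(a = 1, b = 2))))
    ),
    class = "invalid_model_error"
  )
  expect_error(clone_composition(c(0.5, 0.4)),
               class = "invalid_composition_error")
  m <- loss_chain_model()
  expect_identical(m$populations$cloneII$parent, "cloneI")
})
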