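# Droplet-level simulator: Poisson co-encapsulation into droplets, clone
# mixtures with locus-level gains/losses, and DNA/RNA allele counts with a
# tunable expression skew.  Every simulator is reproducible given its seed.

#' Configuration of a simulated tumour experiment
#'
#' Bundles the ground truth and the experimental scale used by
#' [simulate_tumor()] and [simulate_expression()].
#'
#' @param clone_model A [clone_model()]: the populations and their per-locus
#'   allele copy numbers.
#' @param composition A [clone_composition()] (or numeric vector on the
#'   simplex): the true mixing proportions.
#' @param seed Integer seed; required, so every run is reproducible.
#' @param n_droplets Droplets per well (~20,000 on the QX200).
#' @param droplet_volume_nl Partition volume in nanolitres.
#' @param input_copies_per_assay Genome (cell) equivalents loaded per well; a
#'   single-copy-per-cell target then has mean occupancy
#'   `input_copies_per_assay / n_droplets` copies per droplet.
#' @param rna_skew Fraction of transcripts originating from allele 1 per
#'   allele copy: 0.5 is balanced expression, 1 is monoallelic expression of
#'   allele 1.
#' @param rna_depth,dna_depth Total RNA / DNA molecule counts drawn for the
#'   expression simulation.
#' @param mutation_locus Locus carrying the somatic mutation (default: the
#'   first locus with an allele absent from healthy cells).
#' @param pipetting_cv Optional coefficient of variation of a multiplicative
#'   lognormal loading factor per well (default 0: Poisson loading only).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(clone_model, composition, seed,
                              n_droplets = 20000, droplet_volume_nl = 0.85,
                              input_copies_per_assay = 10000,
                              rna_skew = 0.5, rna_depth = 5000,
                              dna_depth = 5000, mutation_locus = NULL,
                              pipetting_cv = 0) {
  stopifnot(inherits(clone_model, "clone_model"))
  if (!inherits(composition, "clone_composition")) {
    composition <- clone_composition(composition,
                                     pop_ids = population_ids(clone_model))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            n_droplets >= 1, input_copies_per_assay > 0,
            rna_skew >= 0, rna_skew <= 1, rna_depth >= 1, dna_depth >= 1,
            pipetting_cv >= 0)
  if (is.null(mutation_locus)) {
    for (lid in names(clone_model$loci)) {
      if (!is.null(infer_somatic_allele(clone_model, lid))) {
        mutation_locus <- lid
        break
      }
    }
    mutation_locus <- mutation_locus %||% names(clone_model$loci)[1]
  }
  structure(
    list(clone_model = clone_model, composition = composition,
         seed = as.integer(seed), n_droplets = as.integer(n_droplets),
         droplet_volume_nl = droplet_volume_nl,
         input_copies_per_assay = input_copies_per_assay,
         rna_skew = rna_skew, rna_depth = as.integer(rna_depth),
         dna_depth = as.integer(dna_depth),
         mutation_locus = mutation_locus, pipetting_cv = pipetting_cv),
    class = "simulation_config"
  )
}

#' Simulate one duplex ddPCR well
#'
#' Each droplet receives an independent Poisson number of copies of each of
#' the two targets (no competition between targets), so it is positive on
#' channel `k` with probability `1 - exp(-lambda_k)`, and the four-way
#' classification (double positive / ch1 only / ch2 only / negative) is
#' multinomial with the product probabilities.
#'
#' @param true_lambda_ch1,true_lambda_ch2 True mean copies per droplet of
#'   the two targets (>= 0).
#' @param n_droplets Number of droplets in the well.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @param well_id Label of the simulated well.
#' @param droplet_volume_nl Partition volume.
#' @return A [droplet_well()].
#' @examples
#' simulate_well(1, 0.5, n_droplets = 20000, seed = 7)
#' @export
simulate_well <- function(true_lambda_ch1, true_lambda_ch2,
                          n_droplets = 20000, seed = NULL, well_id = "sim",
                          droplet_volume_nl = 0.85) {
  stopifnot(true_lambda_ch1 >= 0, true_lambda_ch2 >= 0, n_droplets >= 1)
  p1 <- -expm1(-true_lambda_ch1)
  p2 <- -expm1(-true_lambda_ch2)
  probs <- c(p1 * p2, p1 * (1 - p2), (1 - p1) * p2, (1 - p1) * (1 - p2))
  counts <- with_seed(seed, drop(stats::rmultinom(1, n_droplets, probs)))
  droplet_well(well_id, counts[1], counts[2], counts[3], counts[4],
               droplet_volume_nl)
}

# assay panel implied by a clone model: a mutation duplex at the mutation
# locus, a copy-number duplex (target vs in-well diploid reference) per
# locus, and a SNP duplex per germline-heterozygous two-allele locus
panel_from_model <- function(model, mutation_locus) {
  rows <- list()
  mut_allele <- infer_somatic_allele(model, mutation_locus)
  if (!is.null(mut_allele)) {
    other <- setdiff(model$loci[[mutation_locus]]$alleles, mut_allele)[1]
    rows[[length(rows) + 1L]] <- data.frame(
      assay_id = paste0("MUT-", mutation_locus), kind = "mutation_duplex",
      locus_id = mutation_locus, ch1_allele = mut_allele,
      ch2_allele = other, reference_assay_id = NA_character_
    )
  }
  for (lc in model$loci) {
    rows[[length(rows) + 1L]] <- data.frame(
      assay_id = paste0("CN-", lc$locus_id), kind = "cn_multiplex",
      locus_id = lc$locus_id, ch1_allele = "total", ch2_allele = "reference",
      reference_assay_id = NA_character_
    )
    healthy <- model$populations[[1]]$copies[[lc$locus_id]]
    if (length(lc$alleles) == 2L && all(healthy == 1) &&
        lc$locus_id != mutation_locus) {
      rows[[length(rows) + 1L]] <- data.frame(
        assay_id = paste0("SNP-", lc$locus_id), kind = "snp_duplex",
        locus_id = lc$locus_id, ch1_allele = lc$alleles[1],
        ch2_allele = lc$alleles[2], reference_assay_id = NA_character_
      )
    }
  }
  assay_panel(do.call(rbind, rows))
}

# true per-channel mean occupancies for every assay of a panel
assay_lambdas <- function(panel, model, composition, copies_per_droplet) {
  pred <- forward_model(model, composition)
  lam <- function(avg_copies) avg_copies * copies_per_droplet
  out <- lapply(seq_len(nrow(panel)), function(i) {
    row <- panel[i, ]
    switch(row$kind,
      mutation_duplex = ,
      snp_duplex = c(
        ch1 = lam(unname(pred$allele_avg[paste(row$locus_id, row$ch1_allele, sep = ":")])),
        ch2 = lam(unname(pred$allele_avg[paste(row$locus_id, row$ch2_allele, sep = ":")]))
      ),
      cn_multiplex = c(ch1 = lam(unname(pred$cn[row$locus_id])),
                       ch2 = lam(2))
    )
  })
  names(out) <- panel$assay_id
  out
}

#' Simulate a full multi-assay ddPCR experiment on a clone mixture
#'
#' Builds the assay panel implied by the clone model (mutation duplex,
#' per-locus copy-number duplexes against an unaltered diploid reference,
#' and SNP duplexes at germline-heterozygous loci), computes each assay's
#' true per-channel occupancy from the [forward_model()] allele averages
#' scaled by the loaded genome equivalents, and draws one well per assay.
#'
#' @param config A [simulation_config()].
#' @return A list with `wells` (data frame in the well-count CSV schema),
#'   `panel` (an [assay_panel()]), and `truth` (composition, per-locus copy
#'   number, mutant allele fraction, aberrant fractions and the true
#'   lambdas).
#' @export
simulate_tumor <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  model <- config$clone_model
  comp <- config$composition
  if (length(comp$proportions) != length(model$populations)) {
    dc_error("invalid_composition_error",
             "composition does not match the clone model's populations")
  }
  panel <- panel_from_model(model, config$mutation_locus)
  cpd <- config$input_copies_per_assay / config$n_droplets
  lambdas <- assay_lambdas(panel, model, comp, cpd)

  pred <- forward_model(model, comp)
  mut_allele <- infer_somatic_allele(model, config$mutation_locus)
  wells <- with_seed(config$seed, {
    do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
      lam <- lambdas[[panel$assay_id[i]]]
      if (config$pipetting_cv > 0) {
        sdlog <- sqrt(log1p(config$pipetting_cv^2))
        lam <- lam * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
      }
      w <- simulate_well(lam[["ch1"]], lam[["ch2"]],
                         n_droplets = config$n_droplets,
                         well_id = sprintf("W%02d", i),
                         droplet_volume_nl = config$droplet_volume_nl)
      data.frame(well_id = w$well_id, assay_id = panel$assay_id[i],
                 n_double_pos = w$n_double_pos, n_ch1_only = w$n_ch1_only,
                 n_ch2_only = w$n_ch2_only, n_negative = w$n_negative,
                 droplet_volume_nl = w$droplet_volume_nl)
    }))
  })

  aberrant <- list()
  tot <- total_copy_matrix(model)
  for (lid in names(model$loci)) {
    g <- model$loci[[lid]]$germline_copies
    dev <- tot[lid, ] - g
    if (any(dev != 0)) {
      aberrant[[lid]] <- list(
        alteration = if (any(dev < 0)) "single_copy_loss" else "single_copy_gain",
        fraction = sum(comp$proportions[dev != 0])
      )
    }
  }
  truth <- list(
    composition = comp,
    cn = pred$cn,
    maf = if (!is.null(mut_allele)) {
      predicted_fraction(pred, config$mutation_locus, mut_allele)
    } else NA_real_,
    mutation_locus = config$mutation_locus,
    mutant_allele = mut_allele,
    aberrant_fractions = aberrant,
    lambdas = lambdas
  )
  list(wells = wells, panel = panel, truth = truth)
}

#' Simulate paired DNA and RNA allele counts
#'
#' DNA molecule counts are binomial in the allele-1 fraction of the average
#' allele copy numbers under the clone mixture.  RNA counts are binomial in
#' the expression-weighted fraction: each allele-1 copy contributes weight
#' `rna_skew`, each allele-2 copy weight `1 - rna_skew`, so `rna_skew = 0.5`
#' reproduces the DNA balance (proportional expression) and `rna_skew = 1`
#' gives monoallelic expression of allele 1 whatever the DNA dosage.
#'
#' @param config A [simulation_config()]; the mutation locus provides the
#'   allele pair.
#' @return A list with `dna` and `rna` ([allele_count_pair()]s) and `truth`
#'   (the true DNA and RNA fractions and the skew).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  model <- config$clone_model
  lid <- config$mutation_locus
  alleles <- model$loci[[lid]]$alleles
  if (length(alleles) != 2L) {
    dc_error("invalid_model_error",
             "expression simulation needs a two-allele locus")
  }
  pred <- forward_model(model, config$composition)
  c1 <- pred$allele_avg[paste(lid, alleles[1], sep = ":")]
  c2 <- pred$allele_avg[paste(lid, alleles[2], sep = ":")]
  if (c1 + c2 <= 0) {
    dc_error("invalid_model_error", "locus has zero average copy number")
  }
  s <- config$rna_skew
  p_dna <- c1 / (c1 + c2)
  p_rna <- if (c1 * s + c2 * (1 - s) > 0) {
    c1 * s / (c1 * s + c2 * (1 - s))
  } else 0
  counts <- with_seed(config$seed, c(
    stats::rbinom(1, config$dna_depth, p_dna),
    stats::rbinom(1, config$rna_depth, p_rna)
  ))
  list(
    dna = allele_count_pair("sim", "DNA", counts[1],
                            config$dna_depth - counts[1],
                            allele_labels = alleles),
    rna = allele_count_pair("sim", "RNA", counts[2],
                            config$rna_depth - counts[2],
                            allele_labels = alleles),
    truth = list(dna_fraction = unname(p_dna), rna_fraction = unname(p_rna),
                 rna_skew = s)
  )
}
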