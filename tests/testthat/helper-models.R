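# Clone models used throughout the tests, built in code.

# linear chain with loss of the wild-type allele in clone II, plus a
# germline-heterozygous SNP locus lost in clone II (the companion arm loss)
loss_chain_model <- function() {
  clone_model(
    loci = list(
      locus("CYSLTR2", c("mut", "wt")),
      locus("chr3p", c("A", "B"))
    ),
    populations = list(
      population("healthy", list(CYSLTR2 = c(mut = 0, wt = 2),
                                 chr3p = c(A = 1, B = 1))),
      population("cloneI", list(CYSLTR2 = c(mut = 1, wt = 1),
                                chr3p = c(A = 1, B = 1))),
      population("cloneII", list(CYSLTR2 = c(mut = 1, wt = 0),
                                 chr3p = c(A = 1, B = 0)))
    )
  )
}

# single-locus version (mutation duplex + cn assay only)
loss_chain_model_1locus <- function() {
  clone_model(
    loci = list(locus("CYSLTR2", c("mut", "wt"))),
    populations = list(
      population("healthy", list(CYSLTR2 = c(mut = 0, wt = 2))),
      population("cloneI", list(CYSLTR2 = c(mut = 1, wt = 1))),
      population("cloneII", list(CYSLTR2 = c(mut = 1, wt = 0)))
    )
  )
}

# linear chain with a gain of the mutant allele in clone II
gain_chain_model <- function() {
  clone_model(
    loci = list(locus("CYSLTR2", c("mut", "wt"))),
    populations = list(
      population("healthy", list(CYSLTR2 = c(mut = 0, wt = 2))),
      population("cloneI", list(CYSLTR2 = c(mut = 1, wt = 1))),
      population("cloneII", list(CYSLTR2 = c(mut = 2, wt = 1)))
    )
  )
}

# random two-clone chain: clone I acquires the mutation, clone II a random
# single-copy loss of the wild type or gain of the mutant; uses the ambient
# RNG stream (seed it in the caller)
random_chain_model <- function() {
  if (stats::runif(1) < 0.5) loss_chain_model_1locus() else gain_chain_model()
}

# random interior composition over npop populations
random_interior_composition <- function(npop = 3, margin = 0.02) {
  w <- stats::runif(npop, margin, 1)
  w / sum(w)
}

# noise-free observations (mcf + aberrant fraction) from a model+composition
noise_free_observations <- function(model, w) {
  pred <- forward_model(model, w)
  tot <- dropclone:::total_copy_matrix(model)["CYSLTR2", ]
  alt <- dropclone:::infer_alteration(model, "CYSLTR2")
  dev <- if (alt == "single_copy_loss") pmax(0, 2 - tot) else pmax(0, tot - 2)
  data.frame(
    statistic = c("mcf", "aberrant_fraction"),
    locus_id = "CYSLTR2",
    value = c(sum(w[2:3]), sum(w * dev)),
    alteration = c(NA, alt)
  )
}
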