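# dropclone

Absolute quantification and clonal deconvolution of tumour samples from
droplet digital PCR (ddPCR) partition counts.

Digital PCR splits a reaction into ~20,000 nanolitre droplets and reports,
per droplet, presence or absence of each fluorescent target.  Because
thousands of alleles are counted per well, small allelic imbalances become
measurable even in degraded, low-input material (e.g. FFPE
microdissections) where sequencing at conventional depth cannot resolve
them.  `dropclone` is for researchers who use such assays to dissect the
genetic composition of bulk tumour samples: it converts droplet
classification counts into concentrations, allele fractions and locus
copy numbers with confidence intervals, translates those into
cell-level quantities, decomposes a bulk sample into healthy tissue plus
nested clones, orders somatic events as clonal or subclonal, and tests
DNA-versus-RNA allelic balance for preferential expression of one allele.
A droplet-level simulator provides ground truth for every step.

## The model in brief

* **Poisson correction.** A target's mean copies per droplet is
  $\hat\lambda = -\ln(1 - n_{pos}/n_{tot})$; the 95% CI uses the normal
  approximation with $\mathrm{var}(\hat\lambda) = (e^{\lambda}-1)/n$.
  Allele fractions $f = \lambda_1/(\lambda_1+\lambda_2)$ and copy numbers
  $cn = 2\,\lambda_t/\lambda_r$ carry delta-method intervals.
* **Cells from molecules.** A heterozygous mutant allele fraction (MAF)
  maps to a mutant cell fraction (MCF) as $2\times\mathrm{MAF}$; with a
  single-copy loss of the wild-type allele in a fraction $L$ of cells,
  $\mathrm{MCF} = \mathrm{MAF}(2-L)$, and with a gain of the mutant in
  fraction $G$, $\mathrm{MCF} = \mathrm{MAF}(2+G) - G$.  Alteration
  fractions come from copy number ($f = |cn - 2|$) or from allelic
  imbalance at a germline-heterozygous SNP.
* **Deconvolution.** A clone model (healthy cells plus a nested chain of
  clones with integer allele copy numbers per locus) has a forward model
  linear in the mixing proportions; `deconvolve()` inverts it by weighted
  least squares on the simplex, with bootstrap CIs, identifiability
  checks, and model-mismatch detection.
* **Event ordering.** Cell-fraction estimates are grouped by pairwise
  z-tests; the group with the largest fractions is clonal, the rest
  subclonal.
* **Allelic expression.** Count-based fractions use Wilson intervals; RNA
  versus DNA balance is tested by a two-proportion z-test, or by an exact
  binomial test against a fixed expected fraction (the proportional
  expression null under a known copy-number change).

See `vignettes/dropclone-methods.Rmd` for assumptions, parameters and
numerical details.

## Worked example

Simulate a tumour that is 26% healthy tissue, 7% a heterozygous-mutant
clone and 67% a clone that also lost the wild-type allele, then analyse it
blind:

```r
library(dropclone)

model <- read_clone_model(
  system.file("extdata", "loss_chain_model.json", package = "dropclone"))
sim <- simulate_tumor(simulation_config(model, c(0.26, 0.07, 0.67), seed = 12))
rep <- run_pipeline(sim$panel, model, sim$wells, sample_id = "PUM-like", seed = 3)
print(rep)
#> <tumor_report> sample PUM-like
#>   mutant allele fraction: 56% [0.553, 0.572]
#>   mutant cell fraction:   74% [0.720, 0.768]
#>   cn(CYSLTR2) = 1.32 [1.286, 1.358]
#> <clone_composition>
#>   healthy      26% [0.230, 0.282]
#>   cloneI       7% [0.000, 0.123]
#>   cloneII      68% [0.641, 0.715]
#>   clonal events (~74% of cells): mutation:CYSLTR2; subclonal events
#>   (~68% of cells): single_copy_loss:CYSLTR2; composition: healthy 26%,
#>   cloneI 7%, cloneII 68%
```

Reading the output: the mutation duplex measures a 56% mutant allele
fraction — above 50%, impossible for a heterozygous mutation in diploid
cells, and explained by the copy-number assay's average of 1.32 copies
(a single-copy loss in ~68% of cells).  Correcting the allele fraction
for that loss gives a 74% mutant **cell** fraction; deconvolution then
recovers the simulated composition within its bootstrap intervals, and
the event ordering separates the clonal mutation (74% of cells) from the
subclonal loss (68%).

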