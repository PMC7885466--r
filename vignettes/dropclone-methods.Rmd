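---
title: "Quantitative models behind dropclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative models behind dropclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropclone)
```

`dropclone` turns droplet digital PCR (ddPCR) partition counts into
cell-level tumour biology: which fraction of cells carries a point
mutation, which fraction carries a copy-number change, how a bulk sample
decomposes into healthy tissue plus nested clones, and in which order the
somatic events arose.  This vignette documents the statistical models, the
tunable parameters, the simulator, and the numerical choices, in the order
data flows through the package.

## The measurement layer: Poisson statistics on droplets

A ddPCR well partitions the reaction into roughly 20,000 droplets of about
0.85 nL (the nominal QX200 partition volume; `droplet_volume_nl` is
configurable everywhere because instruments differ).  Target molecules
land in droplets independently, so the per-droplet copy number is Poisson
with mean $\lambda$ and a droplet is *positive* when it holds at least one
copy.  From the positive fraction $\hat p$, `poisson_lambda()` recovers

$$\hat\lambda = -\ln(1 - \hat p),$$

the standard occupancy correction for partition-based PCR.  The 95%
interval uses the asymptotic normal approximation on $\lambda$ with
variance $(e^{\lambda}-1)/n$ (the delta-method transform of the binomial
variance of $\hat p$), which is the common choice in ddPCR practice and is
recorded as `ci_method = "normal_lambda"` in every estimate so the method
stays auditable.  Two boundary cases are handled explicitly:

* a **saturated** channel (every droplet positive) has no finite estimate
  and raises a `saturation_error` rather than returning infinity;
* a channel with **zero** positives has a degenerate normal variance, so
  the upper bound falls back to the rule-of-three bound $-\ln(1 - 3/n)$.
  This keeps downstream interval propagation honest: "no mutant droplets
  observed" still carries a positive upper bound on the mutant
  concentration.

In a duplex assay the two targets are independent amplicons, so
double-positive droplets contain both targets and count toward **both**
channels (`duplex_quantify()`).  Competitive-probe duplexes, where the two
probes fight for one amplicon, are out of scope.  Replicate wells are
pooled by summing counts before the Poisson correction (`pool_wells()`),
which is the maximum-likelihood treatment; quantifying wells separately
and averaging would weight wells incorrectly.

Derived quantities are ratios of concentrations:

* **allele fraction** $f = \lambda_1/(\lambda_1+\lambda_2)$
  (`allele_fraction()`), e.g. the mutant allele fraction (MAF) of a
  mutation duplex;
* **copy number** $cn = k\,\lambda_t/\lambda_r$ against a reference assay
  on a region assumed germline-diploid and unaltered ($k = 2$), in
  `copy_number()`.

Both propagate uncertainty by the first-order delta method, which keeps
results deterministic; `allele_fraction()` also offers a seeded parametric
bootstrap (`ci_method = "bootstrap"`) for users who prefer simulation, and
the two agree closely at typical droplet counts.  Fraction intervals are
clipped to $[0,1]$.

## From molecules to cells

The allele fraction counts molecules; the biology of interest counts
cells.  For a heterozygous mutation in diploid cells each mutant cell
contributes one mutant and one wild-type copy, so the mutant cell fraction
(MCF) is $2 \times \mathrm{MAF}$.  Copy-number alterations of the mutation
locus break that factor of two; `mutant_cell_fraction()` implements the
two single-copy corrections:

* loss of the wild-type allele in a fraction $L$ of all cells:
  $\mathrm{MCF} = \mathrm{MAF}\,(2 - L)$;
* gain of the mutant allele in a fraction $G$ of all cells:
  $\mathrm{MCF} = \mathrm{MAF}\,(2 + G) - G$.

The alteration fractions $L$ and $G$ come from two independent sources
that cross-validate each other:

* `aberrant_fraction_from_cn()`: a single-copy loss in fraction $f$ of
  cells gives average copy number $2-f$, a gain $2+f$; invert and
  translate the interval.
* `aberrant_fraction_from_snp()`: at a germline-heterozygous SNP, loss of
  one allele in fraction $f$ of cells gives concentration ratio
  affected/retained of $1-f$ (gain: $1+f$).

Aberrations are modelled as single-copy events; multi-copy or polyploid
genotypes must be written explicitly into a clone model and are otherwise
out of scope.  Each inversion checks that the measured quantity lies on
the correct side of its null value (2 for copy number, 1 for the SNP
ratio) at least within its confidence interval, and raises a
direction/model mismatch error otherwise — a wrong a-priori direction is a
modelling error, not something to silently absorb.  Likewise an MCF
outside $[0,1]$ beyond its interval raises an inconsistency error, because
it means the MAF and the copy-number measurement cannot both be right.

## Clone models, the forward model, and deconvolution

A `clone_model()` lists cell populations with integer allele copy numbers
per locus.  The first population is healthy (germline genotype
everywhere); by default populations form a linear chain, each clone
descending from the previous one — the topology relevant for a tumour
that acquired a driver mutation and later a copy-number change of the
same locus.  Branching topologies can be encoded via explicit `parent`
fields, but the package never infers topology from data: with a handful
of bulk measurements per sample, topology is an assumption, not an
estimate.

The forward model is linear in the mixing proportions $w$: average copies
per cell of each allele are $C w$ for the allele-copy matrix $C$, and
predicted observables (allele fractions, locus copy numbers, cell
fractions carrying an event) follow deterministically
(`forward_model()`).

`deconvolve()` inverts this map by weighted least squares on the simplex:

* each observation (MAF, copy number, aberrant fraction, or
  mutation-positive cell fraction) contributes one linear row; a MAF
  observation $f = M(w)/T(w)$ is linearised exactly as
  $M(w) - f\,T(w) = 0$, with its weight scaled by the squared germline
  total copies so that it is comparable to the direct observations;
* weights are inverse CI-derived variances (equal weights when no
  intervals are supplied);
* the sum-to-one constraint is explicit, non-negativity is enforced by
  active-set iteration on the KKT system, and degenerate faces are
  resolved by the minimal-norm (pseudoinverse) solution;
* a rank check on the weighted design flags unidentifiable models and
  names the confounded populations — e.g. the mutation alone can never
  separate two clones that both carry it;
* if the best unconstrained-on-the-simplex fit requires a proportion below
  `-mismatch_tol` (default −0.05), the observations contradict the clone
  model and an error is raised instead of clipping the contradiction away.

When the observation set exactly determines the composition — the common
case of one mutation measurement plus one alteration fraction on a
three-population chain — the solver returns the exact arithmetic solution.
Confidence intervals come from a seeded parametric bootstrap (default 200
replicates) that redraws each observation from a normal distribution with
its standard error, truncated to its valid range; the seed is recorded in
the output.  In the full pipeline the deconvolution consumes the
*measurement-layer* estimates (MAF from the mutation well, aberrant
fractions from the copy-number or SNP wells) rather than the derived MCF,
because those come from different wells and are therefore independent —
which is exactly what the bootstrap assumes.

## Ordering events: clonal versus subclonal

Cell-fraction estimates on the same denominator (the whole sample) are
compared pairwise by two-sided z-tests on their CI-derived standard
errors at $\alpha = 0.05$ (`order_events()`).  Events whose differences
are not significant merge into groups (connected components of the
non-significant graph, so the grouping is permutation invariant); groups
sort by descending fraction; the top group is labelled *clonal*, the rest
*subclonal*.  The z-test grouping is this package's choice of procedure —
"present in a significantly smaller proportion" admits several tests, and
the z-test on CI-derived errors is the one that uses exactly the
information the estimates carry.

## DNA-versus-RNA allelic balance

Count-based allele fractions (`allele_fraction_from_counts()`) use the
Wilson score interval, which behaves well at small counts and at the 0/1
boundaries where the Wald interval collapses; $\lambda$-based fractions
keep their delta-method intervals, and each estimate records which method
produced it.  `compare_dna_rna()` tests two nulls:

* without an expected fraction: RNA fraction = DNA fraction (each allele
  copy expressed equally), by a two-sided two-proportion z-test on the raw
  counts;
* with `expected_rna_fraction` (e.g. the DNA fraction implied by a known
  copy-number change — the *proportional expression* null): an exact
  two-sided binomial test of the RNA counts.

Samples are tested independently, matching per-tumour reporting;
`ase_report(p_adjust = "BH")` offers Benjamini–Hochberg correction across
samples for users screening many tumours.  Sequencing-derived DNA
fractions are compared as measured, without purity correction.

## The simulator

`simulate_well()` draws the 2×2 droplet classification from a single
multinomial with probabilities
$(p_1 p_2,\; p_1(1-p_2),\; (1-p_1)p_2,\; (1-p_1)(1-p_2))$ where
$p_k = 1 - e^{-\lambda_k}$ — exactly the model the estimators assume:
Poisson occupancy per target, independent across targets, no competition.
`simulate_tumor()` derives each assay's true $\lambda$ from the forward
model scaled by `input_copies_per_assay` genome equivalents per well
(default 10,000 over 20,000 droplets, i.e. 0.5 cell equivalents per
droplet, a realistic load that keeps wells far from saturation), and
returns the wells, the implied assay panel and a truth record.
`simulate_expression()` draws DNA counts binomially from the average
allele copy numbers and RNA counts from the expression-weighted fraction
$c_1 s / (c_1 s + c_2 (1-s))$ with skew $s$ per allele copy.

What the simulator deliberately does **not** model: fluorescence
amplitudes, rain and gating artefacts (upstream of the package's inputs),
pre-PCR degradation and amplification bias, and between-tumour expression
variability (RNA totals are fixed-depth binomial, not negative binomial).
Pipetting variation is available as an optional multiplicative lognormal
loading factor (`pipetting_cv`, default off).  Passing tests on synthetic
data therefore demonstrate correctness of the statistical inversion under
the stated sampling model — not robustness to gating errors or assay
chemistry effects, which must be judged on real wells.

All simulators take an explicit seed and restore the caller's RNG state,
so a seeded simulation is bit-reproducible and never perturbs the
surrounding analysis.

## Test problem sizes and statistical guarantees

The test suite verifies, among unit-level properties:

* forward∘inverse identity of the deconvolution on 200 random noise-free
  chain mixtures (tolerance $10^{-6}$);
* 93–97% empirical coverage of the $\lambda$ interval over 2,000 simulated
  wells at $\lambda = 1$, $n = 20{,}000$;
* per-population coverage of the bootstrap composition intervals of at
  least 90% over 500 simulated tumours at 20,000 droplets per assay
  (interior compositions with a 5% margin, so that boundary clipping does
  not dominate);
* a 4–6% empirical type-I error of the DNA-versus-RNA z-test under the
  null over 5,000 replicates at depth 1,000.

These sizes were chosen to give the binomial checks enough resolution
(standard errors of roughly 0.5 percentage points on the coverage rates)
while keeping the suite quick to run.

## Known limitations

* Copy-number work assumes a diploid, unaltered reference region; a wrong
  reference shifts every copy number multiplicatively.
* Single-copy gains/losses only, unless encoded explicitly; complex
  polyploid genomes need per-population copy numbers written out, and
  their identifiability from a few bulk measurements is limited.
* The chain topology is assumed, not inferred; multi-region phylogenetics
  is out of scope (the package compares compositions of separately
  analysed samples instead).
* Delta-method intervals are first-order and can be slightly anticonservative
  for extreme fractions at low droplet counts; the bootstrap options exist
  for those cases.
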