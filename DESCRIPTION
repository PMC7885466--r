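Package: dropclone
Title: Droplet Digital PCR Quantification and Clonal Deconvolution of
    Tumour Samples
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Absolute quantification of nucleic-acid targets from droplet
    digital PCR (ddPCR) partition counts via Poisson statistics, with
    confidence intervals on concentrations, allele fractions and locus copy
    number; translation of these measurements into cell-level quantities
    (aberrant-cell fractions from copy number or SNP allelic imbalance,
    copy-number-corrected mutant cell fractions); deconvolution of bulk
    tumour samples into healthy tissue plus nested clones by constrained
    weighted least squares; ordering of somatic events as clonal or
    subclonal; DNA-versus-RNA allelic-balance tests for preferential allele
    expression; and a droplet-level simulator providing ground truth for
    every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
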