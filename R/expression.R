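# DNA-versus-RNA allelic balance: count-based allele fractions (Wilson
# intervals) and tests for preferential expression of one allele.

#' Allele counts for one sample at one level (DNA or RNA)
#'
#' @param sample_id Sample label.
#' @param level `"DNA"` or `"RNA"`.
#' @param n_allele1,n_allele2 Molecule (ddPCR) or read (sequencing) counts of
#'   the two alleles; their sum must be positive.
#' @param source `"ddPCR"` or `"sequencing"`.
#' @param allele_labels Labels of the two alleles (e.g. mutant / wild type,
#'   or two SNP alleles).
#' @return An object of class `allele_count_pair`.
#' @export
allele_count_pair <- function(sample_id, level = c("DNA", "RNA"),
                              n_allele1, n_allele2,
                              source = c("ddPCR", "sequencing"),
                              allele_labels = c("allele1", "allele2")) {
  level <- match.arg(level)
  source <- match.arg(source)
  if (!is_count(n_allele1) || !is_count(n_allele2)) {
    dc_error("invalid_counts_error", "allele counts must be non-negative integers")
  }
  if (n_allele1 + n_allele2 <= 0) {
    dc_error("undefined_fraction_error",
             "both allele counts are zero: nothing to analyse")
  }
  structure(
    list(sample_id = as.character(sample_id), level = level,
         n_allele1 = as.integer(n_allele1), n_allele2 = as.integer(n_allele2),
         source = source, allele_labels = allele_labels),
    class = "allele_count_pair"
  )
}

#' @export
print.allele_count_pair <- function(x, ...) {
  cat(sprintf("<allele counts, %s/%s> %s: %s = %d, %s = %d\n",
              x$level, x$source, x$sample_id,
              x$allele_labels[1], x$n_allele1,
              x$allele_labels[2], x$n_allele2))
  invisible(x)
}

wilson_interval <- function(x, n, conf_level = 0.95) {
  z <- z_crit(conf_level)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  clip01(c(centre - half, centre + half))
}

#' Allele fraction from molecule or read counts
#'
#' The point estimate is `n_allele1 / (n_allele1 + n_allele2)`; the 95%
#' interval is the Wilson score interval, which behaves sensibly at small
#' counts and at the 0/1 boundaries (unlike the Wald interval).
#'
#' @param pair An [allele_count_pair()].
#' @param conf_level Confidence level.
#' @return An `allele_fraction_estimate` with `ci_method = "wilson"`.
#' @examples
#' allele_fraction_from_counts(
#'   allele_count_pair("12B", "DNA", 184, 816, allele_labels = c("mut", "wt")))
#' @export
allele_fraction_from_counts <- function(pair, conf_level = 0.95) {
  stopifnot(inherits(pair, "allele_count_pair"))
  n <- pair$n_allele1 + pair$n_allele2
  f <- pair$n_allele1 / n
  ci <- wilson_interval(pair$n_allele1, n, conf_level)
  new_allele_fraction_estimate(
    f, se = se_from_ci(ci[1], ci[2], conf_level), ci95 = ci,
    level = pair$level, allele_labels = pair$allele_labels,
    ci_method = "wilson"
  )
}

two_proportion_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  if (se == 0) return(list(z = 0, p = 1))
  z <- (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Test DNA-versus-RNA allelic balance
#'
#' Compares the allele-1 fraction between DNA and RNA of the same sample.
#' With no `expected_rna_fraction`, the null hypothesis is that RNA and DNA
#' fractions are equal (each allele copy is expressed equally), tested with
#' a two-sided two-proportion z-test on the raw counts.  With
#' `expected_rna_fraction` given — e.g. the DNA fraction implied by a known
#' copy-number change, the "proportional expression" null — an exact
#' two-sided binomial test of the RNA counts against that fixed fraction is
#' used instead.
#'
#' @param dna,rna [allele_count_pair()]s for the same sample and allele pair.
#' @param expected_rna_fraction Optional fixed null fraction for allele 1 at
#'   the RNA level.
#' @param alpha Significance level for the verdict.
#' @return A list of class `balance_comparison` with the two
#'   `allele_fraction_estimate`s, `delta` (RNA minus DNA fraction),
#'   `p_value`, `test`, and `verdict` (`"balanced"`, `"skewed_to_allele1"`
#'   or `"skewed_to_allele2"`).
#' @examples
#' d <- allele_count_pair("PUM-1A", "DNA", 500, 500)
#' r <- allele_count_pair("PUM-1A", "RNA", 990, 10)
#' compare_dna_rna(d, r)$verdict
#' @export
compare_dna_rna <- function(dna, rna, expected_rna_fraction = NULL,
                            alpha = 0.05) {
  stopifnot(inherits(dna, "allele_count_pair"),
            inherits(rna, "allele_count_pair"))
  if (dna$level != "DNA" || rna$level != "RNA") {
    dc_error("pairing_error",
             "compare_dna_rna needs one DNA-level and one RNA-level count pair")
  }
  if (dna$sample_id != rna$sample_id ||
      !identical(dna$allele_labels, rna$allele_labels)) {
    dc_error("pairing_error",
             "DNA and RNA counts must come from the same sample and allele pair")
  }
  dna_f <- allele_fraction_from_counts(dna)
  rna_f <- allele_fraction_from_counts(rna)
  if (is.null(expected_rna_fraction)) {
    tst <- two_proportion_z(rna$n_allele1, rna$n_allele1 + rna$n_allele2,
                            dna$n_allele1, dna$n_allele1 + dna$n_allele2)
    p_value <- tst$p
    null_fraction <- dna_f$fraction
    test <- "two_proportion_z"
  } else {
    stopifnot(expected_rna_fraction >= 0, expected_rna_fraction <= 1)
    p_value <- stats::binom.test(rna$n_allele1,
                                 rna$n_allele1 + rna$n_allele2,
                                 p = expected_rna_fraction)$p.value
    null_fraction <- expected_rna_fraction
    test <- "exact_binomial"
  }
  verdict <- if (p_value >= alpha) {
    "balanced"
  } else if (rna_f$fraction > null_fraction) {
    "skewed_to_allele1"
  } else {
    "skewed_to_allele2"
  }
  structure(
    list(sample_id = dna$sample_id, dna_fraction = dna_f,
         rna_fraction = rna_f, delta = rna_f$fraction - dna_f$fraction,
         p_value = p_value, test = test, null_fraction = null_fraction,
         alpha = alpha, verdict = verdict),
    class = "balance_comparison"
  )
}

#' @export
print.balance_comparison <- function(x, ...) {
  cat(sprintf(
    "<balance_comparison> %s: DNA %s %s, RNA %s %s, delta %+.3f, p = %.3g (%s) -> %s\n",
    x$sample_id,
    fmt_pct(x$dna_fraction$fraction), fmt_ci(x$dna_fraction$ci95),
    fmt_pct(x$rna_fraction$fraction), fmt_ci(x$rna_fraction$ci95),
    x$delta, x$p_value, x$test, x$verdict
  ))
  invisible(x)
}

#' Run balance comparisons for a table of allele counts
#'
#' Convenience wrapper applying [compare_dna_rna()] per sample to a count
#' table as read by [read_allele_counts()].  Samples are tested
#' independently; `p_adjust = "BH"` optionally applies Benjamini-Hochberg
#' correction across samples.
#'
#' @param counts Data frame with columns `sample_id`, `level`,
#'   `allele1_label`, `allele2_label`, `n_allele1`, `n_allele2`, `source`.
#' @param alpha Significance level.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Data frame with one row per sample: fractions, CIs, delta, p,
#'   verdict.
#' @export
ase_report <- function(counts, alpha = 0.05, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(is.data.frame(counts))
  comps <- lapply(split(counts, counts$sample_id), function(d) {
    pick <- function(lev) {
      row <- d[d$level == lev, ]
      if (nrow(row) != 1L) {
        dc_error("pairing_error",
                 sprintf("sample '%s' needs exactly one %s row",
                         d$sample_id[1], lev))
      }
      allele_count_pair(row$sample_id, lev, row$n_allele1, row$n_allele2,
                        source = row$source,
                        allele_labels = c(row$allele1_label, row$allele2_label))
    }
    compare_dna_rna(pick("DNA"), pick("RNA"), alpha = alpha)
  })
  out <- do.call(rbind, lapply(comps, function(cmp) {
    data.frame(
      sample_id = cmp$sample_id,
      dna_fraction = cmp$dna_fraction$fraction,
      dna_ci_low = cmp$dna_fraction$ci95[1],
      dna_ci_high = cmp$dna_fraction$ci95[2],
      rna_fraction = cmp$rna_fraction$fraction,
      rna_ci_low = cmp$rna_fraction$ci95[1],
      rna_ci_high = cmp$rna_fraction$ci95[2],
      delta = cmp$delta, p_value = cmp$p_value, verdict = cmp$verdict,
      row.names = NULL
    )
  }))
  if (p_adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$verdict[out$p_adjusted >= alpha] <- "balanced"
  }
  rownames(out) <- NULL
  out
}
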