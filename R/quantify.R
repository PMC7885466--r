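# Measurement layer: droplet counts -> concentrations, fractions, copy number.

new_concentration_estimate <- function(lambda_hat, se, ci95, n_droplets,
                                       droplet_volume_nl,
                                       ci_method = "normal_lambda") {
  structure(
    list(
      lambda_hat = lambda_hat,
      se = se,
      ci95 = ci95,
      copies_per_ul = lambda_hat / (droplet_volume_nl * 1e-3),
      n_droplets = n_droplets,
      droplet_volume_nl = droplet_volume_nl,
      ci_method = ci_method
    ),
    class = "concentration_estimate"
  )
}

#' Poisson-corrected target concentration from droplet counts
#'
#' In digital PCR the number of target molecules per droplet is Poisson
#' distributed; a droplet is positive when it holds at least one molecule.
#' The mean occupancy is therefore recovered from the fraction of positive
#' droplets as \eqn{\hat\lambda = -\ln(1 - n_{pos}/n_{tot})}.  The 95%
#' confidence interval uses the asymptotic normal approximation on
#' \eqn{\lambda} with variance \eqn{(e^{\lambda} - 1)/n}; when no droplet is
#' positive that variance degenerates to zero, and the upper bound falls back
#' to the rule-of-three bound \eqn{-\ln(1 - 3/n)}.
#'
#' @param n_positive Number of positive droplets.
#' @param n_total Total number of droplets (> `n_positive`; a fully positive
#'   well is saturated and cannot be quantified).
#' @param droplet_volume_nl Partition volume in nanolitres, used to convert
#'   copies/droplet into copies/microlitre.
#' @param conf_level Confidence level for the interval.
#'
#' @return A `concentration_estimate` with fields `lambda_hat` (mean copies
#'   per droplet), `se`, `ci95`, `copies_per_ul`, `n_droplets` and
#'   `ci_method`.
#' @examples
#' poisson_lambda(5000, 20000)   # lambda = -log(0.75)
#' @export
poisson_lambda <- function(n_positive, n_total, droplet_volume_nl = 0.85,
                           conf_level = 0.95) {
  if (!is_count(n_positive) || !is_count(n_total)) {
    dc_error("invalid_well_error", "droplet counts must be non-negative integers")
  }
  if (n_total == 0) {
    dc_error("empty_well_error", "cannot quantify a well with zero droplets")
  }
  if (n_positive > n_total) {
    dc_error("invalid_well_error", "n_positive exceeds n_total")
  }
  if (n_positive == n_total) {
    dc_error("saturation_error",
             "all droplets positive: channel saturated, concentration unbounded")
  }
  p <- n_positive / n_total
  lambda <- -log1p(-p)
  z <- z_crit(conf_level)
  if (n_positive == 0) {
    hi <- -log1p(-min(3 / n_total, 1 - 1e-12))
    ci <- c(0, hi)
    se <- se_from_ci(0, hi, conf_level)
  } else {
    se <- sqrt(expm1(lambda) / n_total)
    ci <- c(max(0, lambda - z * se), lambda + z * se)
  }
  new_concentration_estimate(lambda, se, ci, n_total, droplet_volume_nl)
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf(
    "<concentration> lambda = %.4f %s (%s), %.0f copies/uL, %d droplets\n",
    x$lambda_hat, fmt_ci(x$ci95), x$ci_method, x$copies_per_ul, x$n_droplets
  ))
  invisible(x)
}

#' Quantify both channels of a duplex well
#'
#' For a duplex assay with two independent targets (e.g. FAM-labelled mutant
#' on channel 1, HEX-labelled wild type on channel 2), double-positive
#' droplets contain both targets and count toward both channels:
#' channel 1 positives are `n_double_pos + n_ch1_only`, channel 2 positives
#' `n_double_pos + n_ch2_only`.  Competitive-probe duplexes, where one
#' target excludes the other, are not modelled.
#'
#' @param well A [droplet_well()].
#' @param conf_level Confidence level passed to [poisson_lambda()].
#' @return A list with elements `ch1` and `ch2`, each a
#'   `concentration_estimate`.
#' @examples
#' w <- droplet_well("A01", 100, 900, 900, 18100)
#' duplex_quantify(w)
#' @export
duplex_quantify <- function(well, conf_level = 0.95) {
  stopifnot(inherits(well, "droplet_well"))
  total <- n_droplets(well)
  quant <- function(n_pos, channel) {
    tryCatch(
      poisson_lambda(n_pos, total, well$droplet_volume_nl, conf_level),
      dropclone_error = function(e) {
        dc_error(class(e)[1],
                 sprintf("well %s channel %d: %s", well$well_id, channel,
                         conditionMessage(e)))
      }
    )
  }
  list(
    ch1 = quant(well$n_double_pos + well$n_ch1_only, 1L),
    ch2 = quant(well$n_double_pos + well$n_ch2_only, 2L)
  )
}

new_allele_fraction_estimate <- function(fraction, se, ci95, level,
                                         allele_labels, ci_method) {
  structure(
    list(fraction = fraction, se = se, ci95 = ci95, level = level,
         allele_labels = allele_labels, ci_method = ci_method),
    class = "allele_fraction_estimate"
  )
}

#' @export
print.allele_fraction_estimate <- function(x, ...) {
  cat(sprintf(
    "<allele fraction, %s> %s = %.3f (%s) %s, CI by %s\n",
    x$level, x$allele_labels[1], x$fraction, fmt_pct(x$fraction),
    fmt_ci(x$ci95), x$ci_method
  ))
  invisible(x)
}

#' Allele fraction from two concentration estimates
#'
#' Computes the fraction of the numerator allele among both alleles,
#' \eqn{f = \lambda_1 / (\lambda_1 + \lambda_2)}, e.g. the mutant allele
#' fraction from a mutation duplex.  The default confidence interval uses
#' first-order (delta-method) propagation of the two concentration standard
#' errors, clipped to `[0, 1]`; `ci_method = "bootstrap"` instead draws the
#' two concentrations from their sampling distributions (seeded, hence
#' reproducible).
#'
#' @param num `concentration_estimate` of the numerator allele (e.g. mutant).
#' @param den_other `concentration_estimate` of the other allele (e.g. wild
#'   type); the denominator is the sum of both.
#' @param level `"DNA"` or `"RNA"`.
#' @param allele_labels Character vector of length 2 naming numerator and
#'   other allele.
#' @param ci_method `"delta"` (default, deterministic) or `"bootstrap"`.
#' @param n_boot,seed Bootstrap replicates and seed (bootstrap method only).
#' @param conf_level Confidence level.
#' @return An `allele_fraction_estimate`.
#' @examples
#' mut <- poisson_lambda(1000, 20000)
#' wt <- poisson_lambda(5000, 20000)
#' allele_fraction(mut, wt, allele_labels = c("mut", "wt"))
#' @export
allele_fraction <- function(num, den_other, level = c("DNA", "RNA"),
                            allele_labels = c("allele1", "allele2"),
                            ci_method = c("delta", "bootstrap"),
                            n_boot = 2000, seed = 1L, conf_level = 0.95) {
  stopifnot(inherits(num, "concentration_estimate"),
            inherits(den_other, "concentration_estimate"))
  level <- match.arg(level)
  ci_method <- match.arg(ci_method)
  a <- num$lambda_hat
  b <- den_other$lambda_hat
  if (a + b <= 0) {
    dc_error("undefined_fraction_error",
             "both concentrations are zero: allele fraction undefined")
  }
  f <- a / (a + b)
  z <- z_crit(conf_level)
  if (ci_method == "delta") {
    # f = a/(a+b); df/da = b/(a+b)^2, df/db = -a/(a+b)^2
    v <- (b^2 * num$se^2 + a^2 * den_other$se^2) / (a + b)^4
    se <- sqrt(v)
    ci <- clip01(c(f - z * se, f + z * se))
  } else {
    draws <- with_seed(seed, {
      aa <- pmax(0, stats::rnorm(n_boot, a, num$se))
      bb <- pmax(0, stats::rnorm(n_boot, b, den_other$se))
      ok <- aa + bb > 0
      aa[ok] / (aa[ok] + bb[ok])
    })
    ci <- clip01(unname(stats::quantile(draws, c((1 - conf_level) / 2,
                                                 1 - (1 - conf_level) / 2))))
    se <- stats::sd(draws)
  }
  new_allele_fraction_estimate(f, se, ci, level, allele_labels, ci_method)
}

new_copy_number_estimate <- function(cn, se, ci95, target_assay,
                                     reference_assay, reference_copies) {
  structure(
    list(cn = cn, se = se, ci95 = ci95, target_assay = target_assay,
         reference_assay = reference_assay,
         reference_copies = reference_copies, ci_method = "delta"),
    class = "copy_number_estimate"
  )
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("<copy number> %s vs %s: cn = %.3f %s\n",
              x$target_assay, x$reference_assay, x$cn, fmt_ci(x$ci95)))
  invisible(x)
}

#' Germline-normalised locus copy number
#'
#' Average copies per cell of a target locus, estimated against a reference
#' assay on a region assumed germline-diploid and unaltered in the tumour:
#' \eqn{cn = k \lambda_t / \lambda_r} with `k = reference_copies` (2 for a
#' diploid reference).  The interval is delta-method on the ratio.
#'
#' @param target `concentration_estimate` of the locus of interest.
#' @param reference `concentration_estimate` of the reference region.
#' @param reference_copies Germline copies of the reference region per cell.
#' @param target_assay,reference_assay Labels recorded in the output.
#' @param conf_level Confidence level.
#' @return A `copy_number_estimate`.
#' @examples
#' t <- poisson_lambda(3400, 20000)
#' r <- poisson_lambda(5000, 20000)
#' copy_number(t, r)
#' @export
copy_number <- function(target, reference, reference_copies = 2,
                        target_assay = "target",
                        reference_assay = "reference", conf_level = 0.95) {
  stopifnot(inherits(target, "concentration_estimate"),
            inherits(reference, "concentration_estimate"))
  lt <- target$lambda_hat
  lr <- reference$lambda_hat
  if (lr <= 0) {
    dc_error("no_reference_error",
             "reference concentration is zero: copy number undefined")
  }
  cn <- reference_copies * lt / lr
  # delta method on the ratio: d/dlt = k/lr, d/dlr = -k lt / lr^2
  v <- (reference_copies / lr)^2 * target$se^2 +
    (reference_copies * lt / lr^2)^2 * reference$se^2
  se <- sqrt(v)
  z <- z_crit(conf_level)
  ci <- c(max(0, cn - z * se), cn + z * se)
  new_copy_number_estimate(cn, se, ci, target_assay, reference_assay,
                           reference_copies)
}

#' Wrap an externally reported allele fraction as an estimate
#'
#' For reproducing analyses from published point estimates (e.g. a mutant
#' allele fraction printed as a rounded percentage) when the underlying
#' droplet counts are not available.  The standard error is derived from the
#' confidence bounds when given, and zero otherwise.
#'
#' @param fraction Point estimate in `[0, 1]`.
#' @param ci_low,ci_high Optional 95% bounds.
#' @param level `"DNA"` or `"RNA"`.
#' @param allele_labels Labels of the numerator allele and its partner.
#' @return An `allele_fraction_estimate` with `ci_method = "external"`.
#' @export
as_fraction_estimate <- function(fraction, ci_low = NA, ci_high = NA,
                                 level = c("DNA", "RNA"),
                                 allele_labels = c("mut", "wt")) {
  level <- match.arg(level)
  stopifnot(fraction >= 0, fraction <= 1)
  se <- if (is.finite(ci_low) && is.finite(ci_high)) {
    se_from_ci(ci_low, ci_high)
  } else 0
  ci <- if (is.finite(ci_low)) c(ci_low, ci_high) else c(fraction, fraction)
  new_allele_fraction_estimate(fraction, se, ci, level, allele_labels,
                               "external")
}
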