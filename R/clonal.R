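# Cell-level layer: aberrant-cell fractions, copy-number-corrected mutant
# cell fractions, the linear forward model of a clone mixture, its
# deconvolution, and clonal/subclonal ordering.

norm_alteration <- function(alteration) {
  a <- match.arg(alteration, c("single_copy_loss", "single_copy_gain",
                               "loss", "gain"))
  switch(a, loss = "single_copy_loss", gain = "single_copy_gain", a)
}

new_aberrant_fraction_estimate <- function(fraction, se, ci95, alteration,
                                           locus_id, source) {
  structure(
    list(fraction = fraction, se = se, ci95 = ci95, alteration = alteration,
         locus_id = locus_id, source = source),
    class = c("aberrant_fraction_estimate", "cell_fraction_estimate")
  )
}

#' @export
print.aberrant_fraction_estimate <- function(x, ...) {
  cat(sprintf("<aberrant fraction> %s at %s in %s of cells %s (%s)\n",
              x$alteration, x$locus_id %||% "?", fmt_pct(x$fraction),
              fmt_ci(x$ci95), x$source))
  invisible(x)
}

#' Fraction of cells carrying a single-copy gain or loss, from copy number
#'
#' If a fraction `f` of all cells carries a single-copy loss of a locus the
#' average copy number is `2 - f`; for a single-copy gain it is `2 + f`.
#' Inverting gives `f = 2 - cn` (loss) or `f = cn - 2` (gain), with the
#' confidence interval translated from the copy-number interval and clipped
#' to `[0, 1]`.  Multi-copy events must instead be encoded explicitly in a
#' [clone_model()].
#'
#' @param cn A `copy_number_estimate` from [copy_number()].
#' @param alteration `"single_copy_loss"` or `"single_copy_gain"` (the
#'   shorthands `"loss"`/`"gain"` are accepted).  If the whole copy-number
#'   interval lies on the wrong side of 2 the stated direction is
#'   inconsistent with the data and an error is raised.
#' @param locus_id Optional locus label recorded in the output.
#' @param germline_copies Germline copies of the locus.
#' @return An `aberrant_fraction_estimate`.
#' @examples
#' r <- poisson_lambda(5000, 20000)
#' t <- poisson_lambda(3400, 20000)                # cn ~ 1.33
#' aberrant_fraction_from_cn(copy_number(t, r), "loss")
#' @export
aberrant_fraction_from_cn <- function(cn, alteration, locus_id = NULL,
                                      germline_copies = 2) {
  stopifnot(inherits(cn, "copy_number_estimate"))
  alteration <- norm_alteration(alteration)
  g <- germline_copies
  if (alteration == "single_copy_loss") {
    if (cn$ci95[1] > g) {
      dc_error("direction_mismatch_error",
               sprintf("copy number %.3f is above %g beyond its CI: not a loss",
                       cn$cn, g))
    }
    f <- g - cn$cn
    ci <- c(g - cn$ci95[2], g - cn$ci95[1])
  } else {
    if (cn$ci95[2] < g) {
      dc_error("direction_mismatch_error",
               sprintf("copy number %.3f is below %g beyond its CI: not a gain",
                       cn$cn, g))
    }
    f <- cn$cn - g
    ci <- c(cn$ci95[1] - g, cn$ci95[2] - g)
  }
  new_aberrant_fraction_estimate(clip01(f), cn$se, clip01(ci), alteration,
                                 locus_id %||% cn$target_assay, "copy_number")
}

#' Aberrant-cell fraction from allelic imbalance at a heterozygous SNP
#'
#' At a germline-heterozygous SNP each cell carries one copy of each allele.
#' If a fraction `f` of cells loses the affected allele, the concentration
#' ratio affected/retained is `1 - f`; if a fraction gains one extra copy
#' the ratio is `1 + f`.  The ratio CI is delta-method on the two
#' concentrations.
#'
#' @param retained `concentration_estimate` of the unaltered allele.
#' @param affected `concentration_estimate` of the allele that is lost or
#'   gained.
#' @param alteration `"single_copy_loss"` or `"single_copy_gain"`.
#' @param locus_id Optional locus label.
#' @return An `aberrant_fraction_estimate`.
#' @examples
#' a <- poisson_lambda(1700, 20000)
#' r <- poisson_lambda(5000, 20000)
#' aberrant_fraction_from_snp(r, a, "loss", locus_id = "chr13q")
#' @export
aberrant_fraction_from_snp <- function(retained, affected, alteration,
                                       locus_id = NULL) {
  stopifnot(inherits(retained, "concentration_estimate"),
            inherits(affected, "concentration_estimate"))
  alteration <- norm_alteration(alteration)
  lr <- retained$lambda_hat
  la <- affected$lambda_hat
  if (lr <= 0) {
    dc_error("no_reference_error",
             "retained-allele concentration is zero: imbalance undefined")
  }
  rho <- la / lr
  v <- (1 / lr)^2 * affected$se^2 + (la / lr^2)^2 * retained$se^2
  se <- sqrt(v)
  z <- z_crit(0.95)
  rho_ci <- c(max(0, rho - z * se), rho + z * se)
  if (alteration == "single_copy_loss") {
    if (rho_ci[1] > 1) {
      dc_error("model_mismatch_error",
               "affected/retained ratio exceeds 1 beyond its CI: not a loss")
    }
    f <- 1 - rho
    ci <- c(1 - rho_ci[2], 1 - rho_ci[1])
  } else {
    if (rho_ci[2] < 1) {
      dc_error("model_mismatch_error",
               "affected/retained ratio is below 1 beyond its CI: not a gain")
    }
    f <- rho - 1
    ci <- c(rho_ci[1] - 1, rho_ci[2] - 1)
  }
  new_aberrant_fraction_estimate(clip01(f), se, clip01(ci), alteration,
                                 locus_id, "snp_imbalance")
}

new_cell_fraction_estimate <- function(fraction, se, ci95,
                                       label = "mutant_cell_fraction") {
  structure(list(fraction = fraction, se = se, ci95 = ci95, label = label),
            class = "cell_fraction_estimate")
}

#' @export
print.cell_fraction_estimate <- function(x, ...) {
  cat(sprintf("<%s> %s of cells %s\n", x$label, fmt_pct(x$fraction),
              fmt_ci(x$ci95)))
  invisible(x)
}

#' Copy-number-corrected mutant cell fraction
#'
#' The mutant allele fraction (MAF) measures molecules, not cells.  For a
#' heterozygous mutation in otherwise diploid cells, each mutant cell
#' contributes one mutant and one wild-type copy, so the mutant cell
#' fraction (MCF) is `2 x MAF`.  A copy-number alteration of the locus
#' breaks that factor of two:
#' \itemize{
#'   \item single-copy loss of the wild-type allele in a fraction `L` of all
#'     cells: `MCF = MAF x (2 - L)`;
#'   \item single-copy gain of the mutant allele in a fraction `G` of all
#'     cells: `MCF = MAF x (2 + G) - G`.
#' }
#' The interval is first-order propagation of the MAF and alteration-
#' fraction intervals, clipped to `[0, 1]`; an MCF outside `[0, 1]` beyond
#' its CI means the two measurements are mutually inconsistent and raises an
#' error.
#'
#' @param maf An `allele_fraction_estimate` of the mutant allele.
#' @param cna_fraction `NULL` for the diploid heterozygous case, otherwise an
#'   `aberrant_fraction_estimate` for the mutation locus; its `alteration`
#'   field selects the loss (of wild type) or gain (of mutant) correction.
#' @param model Optional [clone_model()]; when given, the direction of the
#'   correction is cross-checked against the model's genotype at
#'   `mutation_locus`.
#' @param mutation_locus Locus id of the mutation in `model`.
#' @return A `cell_fraction_estimate`.
#' @examples
#' maf <- allele_fraction(poisson_lambda(1800, 20000),
#'                        poisson_lambda(7600, 20000),
#'                        allele_labels = c("mut", "wt"))
#' mutant_cell_fraction(maf)   # ~ 2 x MAF
#' @export
mutant_cell_fraction <- function(maf, cna_fraction = NULL, model = NULL,
                                 mutation_locus = NULL) {
  stopifnot(inherits(maf, "allele_fraction_estimate"))
  m <- maf$fraction
  vm <- maf$se^2
  z <- z_crit(0.95)
  if (is.null(cna_fraction)) {
    mcf <- 2 * m
    se <- 2 * maf$se
  } else {
    stopifnot(inherits(cna_fraction, "aberrant_fraction_estimate"))
    f <- cna_fraction$fraction
    vf <- cna_fraction$se^2
    if (!is.null(model)) {
      alt <- infer_alteration(model, mutation_locus %||% names(model$loci)[1])
      if (!is.null(alt) && alt != cna_fraction$alteration) {
        dc_error("model_mismatch_error",
                 sprintf("clone model implies %s at the mutation locus, got %s",
                         alt, cna_fraction$alteration))
      }
    }
    if (cna_fraction$alteration == "single_copy_loss") {
      mcf <- m * (2 - f)
      se <- sqrt((2 - f)^2 * vm + m^2 * vf)
    } else {
      mcf <- m * (2 + f) - f
      se <- sqrt((2 + f)^2 * vm + (m - 1)^2 * vf)
    }
  }
  ci <- c(mcf - z * se, mcf + z * se)
  if (ci[1] > 1 || ci[2] < 0) {
    dc_error("inconsistent_measurements_error",
             sprintf("mutant cell fraction %.3f lies outside [0, 1] beyond its CI",
                     mcf))
  }
  new_cell_fraction_estimate(clip01(mcf), se, clip01(ci))
}

# the allele that is somatically acquired: absent in healthy cells,
# present in at least one clone; NULL when no such allele exists
infer_somatic_allele <- function(model, locus_id) {
  lc <- model$loci[[locus_id]]
  if (is.null(lc)) return(NULL)
  healthy <- model$populations[[1]]$copies[[locus_id]]
  for (al in lc$alleles) {
    if (healthy[al] == 0 &&
        any(vapply(model$populations, function(p) p$copies[[locus_id]][al] > 0,
                   logical(1)))) {
      return(al)
    }
  }
  NULL
}

# direction of the copy-number change a model encodes at a locus
infer_alteration <- function(model, locus_id) {
  tot <- total_copy_matrix(model)[locus_id, ]
  g <- model$loci[[locus_id]]$germline_copies
  if (any(tot < g)) return("single_copy_loss")
  if (any(tot > g)) return("single_copy_gain")
  NULL
}

#' Predicted measurements of a clone mixture
#'
#' The forward model is linear in the mixing proportions `w`: the average
#' copies per cell of each allele are the composition-weighted sum of the
#' population copy numbers.  From these averages the predicted allele
#' fraction at each locus (allele copies / total copies) and the predicted
#' copy number (total copies) follow deterministically.
#'
#' @param model A [clone_model()].
#' @param composition A [clone_composition()] (or a bare numeric vector on
#'   the simplex) over the model's populations.
#' @return A list of class `forward_prediction` with `allele_avg` (named
#'   `locus:allele` vector), `cn` (named per-locus totals), and `fractions`
#'   (data frame of per-allele fractions).
#' @examples
#' m <- clone_model(
#'   loci = list(locus("CYSLTR2", c("mut", "wt"))),
#'   populations = list(
#'     population("healthy", list(CYSLTR2 = c(mut = 0, wt = 2))),
#'     population("cloneI",  list(CYSLTR2 = c(mut = 1, wt = 1))),
#'     population("cloneII", list(CYSLTR2 = c(mut = 2, wt = 1)))
#'   )
#' )
#' forward_model(m, c(0.15, 0.17, 0.68))$fractions
#' @export
forward_model <- function(model, composition) {
  stopifnot(inherits(model, "clone_model"))
  if (!inherits(composition, "clone_composition")) {
    composition <- clone_composition(composition,
                                     pop_ids = population_ids(model))
  }
  w <- composition$proportions
  if (length(w) != length(model$populations)) {
    dc_error("invalid_composition_error",
             "composition length does not match the model's populations")
  }
  ac <- allele_copy_matrix(model)
  avg <- drop(ac %*% w)
  lids <- sub(":.*$", "", names(avg))
  cn <- vapply(split(avg, lids), sum, numeric(1))[names(model$loci)]
  fractions <- data.frame(
    locus_id = lids,
    allele = sub("^[^:]*:", "", names(avg)),
    avg_copies = unname(avg),
    locus_cn = unname(cn[lids]),
    fraction = unname(ifelse(cn[lids] > 0, avg / cn[lids], NA_real_)),
    row.names = NULL
  )
  structure(list(allele_avg = avg, cn = cn, fractions = fractions),
            class = "forward_prediction")
}

#' @export
print.forward_prediction <- function(x, ...) {
  cat("<forward_prediction>\n")
  print(x$fractions)
  invisible(x)
}

#' Extract a predicted allele fraction from a forward prediction
#' @param pred A `forward_prediction` from [forward_model()].
#' @param locus_id,allele Which allele fraction to return.
#' @return The predicted fraction (numeric).
#' @export
predicted_fraction <- function(pred, locus_id, allele) {
  stopifnot(inherits(pred, "forward_prediction"))
  i <- pred$fractions$locus_id == locus_id & pred$fractions$allele == allele
  if (!any(i)) dc_error("invalid_model_error", "no such locus/allele")
  pred$fractions$fraction[i]
}

# ---- deconvolution ---------------------------------------------------------

# map an observation table onto the linear forward model: one row of the
# design matrix per observation.  A MAF observation f = M(w)/T(w) is folded
# into the linear system as M(w) - f T(w) = 0.
build_design <- function(model, obs) {
  ac <- allele_copy_matrix(model)
  tot <- total_copy_matrix(model)
  npop <- length(model$populations)
  A <- matrix(0, nrow = nrow(obs), ncol = npop,
              dimnames = list(NULL, population_ids(model)))
  b <- numeric(nrow(obs))
  vscale <- rep(1, nrow(obs))  # multiplies var(value) to get var(residual)
  for (i in seq_len(nrow(obs))) {
    stat <- obs$statistic[i]
    lid <- obs$locus_id[i]
    if (!stat %in% c("maf", "cn", "aberrant_fraction", "mcf")) {
      dc_error("invalid_observation_error",
               sprintf("unknown statistic '%s'", stat))
    }
    if (is.na(lid) || !lid %in% names(model$loci)) {
      dc_error("invalid_observation_error",
               sprintf("observation %d: unknown locus '%s'", i, lid))
    }
    g <- model$loci[[lid]]$germline_copies
    if (stat == "cn") {
      A[i, ] <- tot[lid, ]
      b[i] <- obs$value[i]
    } else if (stat == "aberrant_fraction") {
      alt <- obs$alteration[i]
      if (is.na(alt)) alt <- infer_alteration(model, lid)
      if (is.null(alt)) {
        dc_error("invalid_observation_error",
                 sprintf("observation %d: alteration direction needed", i))
      }
      alt <- norm_alteration(alt)
      A[i, ] <- if (alt == "single_copy_loss") pmax(0, g - tot[lid, ])
                else pmax(0, tot[lid, ] - g)
      b[i] <- obs$value[i]
    } else {
      al <- obs$allele[i]
      if (is.na(al)) al <- infer_somatic_allele(model, lid)
      if (is.null(al) || !al %in% model$loci[[lid]]$alleles) {
        dc_error("invalid_observation_error",
                 sprintf("observation %d: allele needed for '%s'", i, stat))
      }
      arow <- ac[paste(lid, al, sep = ":"), ]
      if (stat == "mcf") {
        A[i, ] <- as.numeric(arow > 0)
        b[i] <- obs$value[i]
      } else {                       # maf: M(w) - f T(w) = 0
        A[i, ] <- arow - obs$value[i] * tot[lid, ]
        b[i] <- 0
        vscale[i] <- g^2             # residual ~ T(w) * (f_true - f), T ~ g
      }
    }
  }
  list(A = A, b = b, vscale = vscale)
}

obs_variance <- function(obs, conf_level = 0.95) {
  v <- rep(NA_real_, nrow(obs))
  if (!is.null(obs$se)) v <- obs$se^2
  if (!is.null(obs$ci_low) && !is.null(obs$ci_high)) {
    miss <- !is.finite(v)
    v[miss] <- se_from_ci(obs$ci_low[miss], obs$ci_high[miss], conf_level)^2
  }
  if (all(!is.finite(v))) return(rep(1, nrow(obs)))
  v[!is.finite(v) | v <= 0] <- stats::median(v[is.finite(v) & v > 0])
  v
}

# weighted least squares on the simplex: min ||sqrt(W)(Aw - b)|| subject to
# sum(w) = 1, w >= 0.  Active-set iteration on the equality-constrained KKT
# system; MASS::ginv gives the minimal-norm solution on degenerate faces.
simplex_wls <- function(A, b, wts) {
  npop <- ncol(A)
  solve_face <- function(free) {
    Af <- A[, free, drop = FALSE]
    H <- crossprod(Af, Af * wts)
    g <- crossprod(Af, b * wts)
    k <- length(free)
    K <- rbind(cbind(2 * H, rep(1, k)), c(rep(1, k), 0))
    sol <- MASS::ginv(K) %*% c(2 * g, 1)
    sol[seq_len(k)]
  }
  active <- rep(FALSE, npop)
  w <- rep(NA_real_, npop)
  repeat {
    free <- which(!active)
    wf <- solve_face(free)
    if (min(wf) >= -1e-9 || length(free) == 1L) {
      w[] <- 0
      w[free] <- pmax(0, wf)
      break
    }
    active[free[which.min(wf)]] <- TRUE
  }
  w / sum(w)
}

#' Deconvolve a bulk sample into healthy cells and nested clones
#'
#' Solves the linear forward model of [forward_model()] for the mixing
#' proportions `w`, given a set of measurement-layer observations: mutant
#' allele fractions (`"maf"`), locus copy numbers (`"cn"`), aberrant-cell
#' fractions (`"aberrant_fraction"`, with a loss/gain direction), and/or
#' mutation-positive cell fractions (`"mcf"`).  The solve is weighted least
#' squares on the simplex (weights = inverse CI-derived variances, explicit
#' sum-to-one constraint, non-negativity by active-set iteration, ties
#' broken by the minimal-norm solution); when the observation set exactly
#' determines the composition the exact solution is returned.  Confidence
#' intervals come from a seeded parametric bootstrap that redraws each
#' observation from a normal distribution with its standard error.
#'
#' @param model A [clone_model()].
#' @param observations Data frame with columns `statistic` (one of `maf`,
#'   `cn`, `aberrant_fraction`, `mcf`), `locus_id`, `value`, and optionally
#'   `allele`, `alteration`, `ci_low`, `ci_high`, `se`.
#' @param ci Compute bootstrap confidence intervals?
#' @param n_boot Number of bootstrap replicates.
#' @param seed Seed for the bootstrap (recorded in the output).
#' @param mismatch_tol If the unconstrained simplex solution has a component
#'   below `-mismatch_tol` the observations contradict the model and a
#'   model-mismatch error is raised rather than silently clipping.
#' @param conf_level Confidence level of the bootstrap intervals.
#' @return A [clone_composition()] with elements `proportions`, `ci95`
#'   (2 x populations matrix, when `ci = TRUE`), `fitted` observations,
#'   `seed` and `n_boot`.
#' @examples
#' m <- clone_model(
#'   loci = list(locus("CYSLTR2", c("mut", "wt"))),
#'   populations = list(
#'     population("healthy", list(CYSLTR2 = c(mut = 0, wt = 2))),
#'     population("cloneI",  list(CYSLTR2 = c(mut = 1, wt = 1))),
#'     population("cloneII", list(CYSLTR2 = c(mut = 1, wt = 0)))
#'   )
#' )
#' obs <- data.frame(statistic = c("mcf", "aberrant_fraction"),
#'                   locus_id = "CYSLTR2", value = c(0.74, 0.67),
#'                   alteration = c(NA, "loss"))
#' deconvolve(m, obs, ci = FALSE)$proportions
#' @export
deconvolve <- function(model, observations, ci = TRUE, n_boot = 200,
                       seed = 1L, mismatch_tol = 0.05, conf_level = 0.95) {
  stopifnot(inherits(model, "clone_model"), is.data.frame(observations),
            nrow(observations) >= 1L)
  obs <- observations
  for (col in c("locus_id", "allele", "alteration")) {
    if (is.null(obs[[col]])) obs[[col]] <- NA_character_
  }
  des <- build_design(model, obs)
  v <- obs_variance(obs, conf_level) * des$vscale
  wts <- 1 / v

  # identifiability: the design (with the sum constraint) must have full
  # column rank, otherwise some populations are confounded
  M <- rbind(des$A * sqrt(wts), 1)
  sv <- svd(M, nu = 0, nv = ncol(M))
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (rank < ncol(M)) {
    null_vec <- sv$v[, ncol(M)]
    confounded <- population_ids(model)[abs(null_vec) > 1e-8]
    dc_error("unidentifiable_model_error",
             sprintf("observations cannot separate populations: %s",
                     paste(confounded, collapse = ", ")))
  }

  # unconstrained (equality-only) solution flags model mismatch
  H <- crossprod(des$A, des$A * wts)
  g <- crossprod(des$A, des$b * wts)
  npop <- ncol(des$A)
  K <- rbind(cbind(2 * H, rep(1, npop)), c(rep(1, npop), 0))
  w_eq <- (MASS::ginv(K) %*% c(2 * g, 1))[seq_len(npop)]
  if (min(w_eq) < -mismatch_tol) {
    dc_error("model_mismatch_error",
             sprintf("best fit requires a negative proportion (%.3f) for '%s': observations contradict the clone model",
                     min(w_eq), population_ids(model)[which.min(w_eq)]))
  }

  w <- simplex_wls(des$A, des$b, wts)
  names(w) <- population_ids(model)

  out <- clone_composition(w)
  pred <- forward_model(model, out)
  out$fitted <- cbind(obs[c("statistic", "locus_id", "value")],
                      fitted = fitted_observations(model, out, obs))
  out$seed <- seed
  out$n_boot <- if (ci) n_boot else 0L
  if (ci) {
    se_all <- sqrt(obs_variance(obs, conf_level))
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        ob <- obs
        ob$value <- stats::rnorm(nrow(obs), obs$value, se_all)
        frac <- ob$statistic %in% c("maf", "aberrant_fraction", "mcf")
        ob$value[frac] <- clip01(ob$value[frac])
        ob$value[!frac] <- pmax(0, ob$value[!frac])
        d <- build_design(model, ob)
        simplex_wls(d$A, d$b, wts)
      }, numeric(npop))
    })
    alpha <- 1 - conf_level
    out$ci95 <- apply(boots, 1, stats::quantile,
                      probs = c(alpha / 2, 1 - alpha / 2))
    colnames(out$ci95) <- population_ids(model)
  }
  out
}

# evaluate the observation statistics under a fitted composition
fitted_observations <- function(model, composition, obs) {
  pred <- forward_model(model, composition)
  w <- composition$proportions
  tot <- total_copy_matrix(model)
  ac <- allele_copy_matrix(model)
  vapply(seq_len(nrow(obs)), function(i) {
    lid <- obs$locus_id[i]
    g <- model$loci[[lid]]$germline_copies
    switch(obs$statistic[i],
      cn = unname(pred$cn[lid]),
      maf = {
        al <- obs$allele[i]
        if (is.na(al)) al <- infer_somatic_allele(model, lid)
        predicted_fraction(pred, lid, al)
      },
      mcf = {
        al <- obs$allele[i]
        if (is.na(al)) al <- infer_somatic_allele(model, lid)
        sum(w[ac[paste(lid, al, sep = ":"), ] > 0])
      },
      aberrant_fraction = {
        alt <- obs$alteration[i]
        if (is.na(alt)) alt <- infer_alteration(model, lid)
        alt <- norm_alteration(alt)
        a <- if (alt == "single_copy_loss") pmax(0, g - tot[lid, ])
             else pmax(0, tot[lid, ] - g)
        sum(w * a)
      }
    )
  }, numeric(1))
}

# ---- event ordering --------------------------------------------------------

as_event_table <- function(events) {
  if (is.data.frame(events)) {
    stopifnot(all(c("event", "fraction") %in% names(events)))
    ev <- events
    if (is.null(ev$se)) {
      ev$se <- se_from_ci(ev$ci_low, ev$ci_high)
    }
    return(ev[c("event", "fraction", "se")])
  }
  stopifnot(is.list(events), length(events) >= 1L)
  data.frame(
    event = vapply(seq_along(events), function(i) {
      e <- events[[i]]
      names(events)[i] %||% e$locus_id %||% e$label %||% sprintf("event%d", i)
    }, character(1)),
    fraction = vapply(events, `[[`, numeric(1), "fraction"),
    se = vapply(events, `[[`, numeric(1), "se"),
    row.names = NULL
  )
}

#' Order somatic events into clonal and subclonal groups
#'
#' Events measured on the same cell denominator (mutant cell fractions and
#' aberrant-cell fractions) are compared pairwise with two-sided z-tests on
#' their CI-derived standard errors.  Events whose pairwise differences are
#' not significant at `alpha` are merged (connected components of the
#' non-significant graph), groups are sorted by descending cell fraction,
#' and the top group is labelled clonal, all others subclonal — later,
#' smaller groups arose later in tumour evolution within the chain model.
#' The grouping is deterministic and invariant under permutation of the
#' input.
#'
#' @param events Either a data frame with columns `event`, `fraction` and
#'   `se` (or `ci_low`/`ci_high`), or a (possibly named) list of
#'   `cell_fraction_estimate`/`aberrant_fraction_estimate` objects.
#' @param alpha Significance level of the pairwise tests.
#' @return A data frame with columns `event`, `fraction`, `se`, `group`
#'   (1 = largest) and `label` (`"clonal"`/`"subclonal"`), ordered by
#'   descending fraction; the matrix of pairwise p-values is attached as
#'   attribute `"p_values"`.
#' @examples
#' ev <- data.frame(event = c("CYSLTR2mut", "13qloss"),
#'                  fraction = c(0.74, 0.67), se = c(0.005, 0.005))
#' order_events(ev)
#' @export
order_events <- function(events, alpha = 0.05) {
  ev <- as_event_table(events)
  n <- nrow(ev)
  if (n == 1L) {
    out <- cbind(ev, group = 1L, label = "clonal")
    attr(out, "p_values") <- matrix(NA_real_, 1, 1)
    return(out)
  }
  p <- matrix(NA_real_, n, n, dimnames = list(ev$event, ev$event))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      z <- (ev$fraction[i] - ev$fraction[j]) /
        sqrt(ev$se[i]^2 + ev$se[j]^2)
      p[i, j] <- p[j, i] <- 2 * stats::pnorm(-abs(z))
    }
  }
  # union-find over the "not significantly different" graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (p[i, j] >= alpha) parent[find(j)] <- find(i)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  grp_frac <- vapply(split(ev$fraction, comp), mean, numeric(1))
  ord <- names(sort(grp_frac, decreasing = TRUE))
  group <- match(as.character(comp), ord)
  out <- ev
  out$group <- group
  out$label <- ifelse(group == 1L, "clonal", "subclonal")
  out <- out[order(out$group, -out$fraction, out$event), ]
  rownames(out) <- NULL
  attr(out, "p_values") <- p
  out
}

#' Wrap an externally reported aberrant-cell fraction as an estimate
#'
#' Companion to [as_fraction_estimate()] for cell fractions of a single-copy
#' gain or loss taken from a report rather than computed from droplet
#' counts.
#'
#' @param fraction Fraction of cells carrying the alteration.
#' @param alteration `"single_copy_loss"` or `"single_copy_gain"`.
#' @param ci_low,ci_high Optional 95% bounds.
#' @param locus_id Optional locus label.
#' @return An `aberrant_fraction_estimate` with source `"external"`.
#' @export
as_aberrant_fraction <- function(fraction, alteration, ci_low = NA,
                                 ci_high = NA, locus_id = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  alteration <- norm_alteration(alteration)
  se <- if (is.finite(ci_low) && is.finite(ci_high)) {
    se_from_ci(ci_low, ci_high)
  } else 0
  ci <- if (is.finite(ci_low)) c(ci_low, ci_high) else c(fraction, fraction)
  new_aberrant_fraction_estimate(fraction, se, ci, alteration, locus_id,
                                 "external")
}
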