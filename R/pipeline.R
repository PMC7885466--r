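# End-to-end driver: droplet counts -> concentrations -> allele fractions,
# copy numbers and SNP imbalances -> aberrant-cell fractions -> mutant cell
# fraction -> deconvolution -> event ordering -> report.

#' Run the full analysis pipeline on one sample
#'
#' @param panel An [assay_panel()] describing the assays.
#' @param model A [clone_model()] for the sample.
#' @param well_counts Data frame in the well-count schema (from
#'   [read_well_counts()] or [simulate_tumor()]).  Replicate wells per assay
#'   are pooled before quantification.
#' @param sample_id Sample label for the report.
#' @param alpha Significance level for event ordering and detection.
#' @param seed Seed for the deconvolution bootstrap (recorded in the
#'   report).
#' @param n_boot Bootstrap replicates for composition CIs.
#' @return A list of class `tumor_report`: quantification table, allele
#'   fraction / copy number / aberrant fraction estimates, mutant cell
#'   fraction, clone composition with CIs, ordered events, and a narrative.
#'   Deterministic given inputs and seed.
#' @examples
#' m <- clone_model(
#'   loci = list(locus("CYSLTR2", c("mut", "wt"))),
#'   populations = list(
#'     population("healthy", list(CYSLTR2 = c(mut = 0, wt = 2))),
#'     population("cloneI",  list(CYSLTR2 = c(mut = 1, wt = 1))),
#'     population("cloneII", list(CYSLTR2 = c(mut = 1, wt = 0)))
#'   )
#' )
#' sim <- simulate_tumor(simulation_config(m, c(0.26, 0.07, 0.67), seed = 1))
#' rep <- run_pipeline(sim$panel, m, sim$wells, sample_id = "PUM-like")
#' rep$composition$proportions
#' @export
run_pipeline <- function(panel, model, well_counts, sample_id = "sample",
                         alpha = 0.05, seed = 1L, n_boot = 200) {
  stopifnot(inherits(panel, "assay_panel"), inherits(model, "clone_model"),
            is.data.frame(well_counts))
  absent <- setdiff(panel$assay_id, unique(well_counts$assay_id))
  if (length(absent)) {
    dc_error("configuration_error",
             paste("panel assays absent from well counts:",
                   paste(absent, collapse = ", ")))
  }

  # stage 1: Poisson quantification per assay
  conc <- lapply(panel$assay_id, function(aid) {
    well <- wells_for_assay(well_counts, aid)
    duplex_quantify(well)
  })
  names(conc) <- panel$assay_id
  quantification <- do.call(rbind, lapply(panel$assay_id, function(aid) {
    q <- conc[[aid]]
    data.frame(
      assay_id = aid, kind = panel$kind[panel$assay_id == aid],
      lambda_ch1 = q$ch1$lambda_hat, lambda_ch1_low = q$ch1$ci95[1],
      lambda_ch1_high = q$ch1$ci95[2],
      lambda_ch2 = q$ch2$lambda_hat, lambda_ch2_low = q$ch2$ci95[1],
      lambda_ch2_high = q$ch2$ci95[2],
      copies_per_ul_ch1 = q$ch1$copies_per_ul,
      copies_per_ul_ch2 = q$ch2$copies_per_ul,
      n_droplets = q$ch1$n_droplets
    )
  }))

  # stage 2: allele fractions, copy numbers, SNP imbalances
  maf <- NULL
  mutation_locus <- NULL
  cn <- list()
  aberrant <- list()
  for (i in seq_len(nrow(panel))) {
    aid <- panel$assay_id[i]
    lid <- panel$locus_id[i]
    q <- conc[[aid]]
    if (panel$kind[i] == "mutation_duplex") {
      maf <- allele_fraction(q$ch1, q$ch2,
                             allele_labels = c(panel$ch1_allele[i],
                                               panel$ch2_allele[i]))
      mutation_locus <- lid
    } else if (panel$kind[i] == "cn_multiplex") {
      ref <- panel$reference_assay_id[i]
      ref_est <- if (is.na(ref)) q$ch2 else conc[[ref]]$ch1
      cn[[lid]] <- copy_number(q$ch1, ref_est, target_assay = lid,
                               reference_assay = if (is.na(ref)) aid else ref)
      alt <- infer_alteration(model, lid)
      if (!is.null(alt)) {
        aberrant[[lid]] <- aberrant_fraction_from_cn(cn[[lid]], alt,
                                                     locus_id = lid)
      }
    } else {  # snp_duplex: which allele does the model alter?
      healthy <- model$populations[[1]]$copies[[lid]]
      changed <- vapply(model$loci[[lid]]$alleles, function(al) {
        any(vapply(model$populations, function(p) {
          p$copies[[lid]][al] != healthy[al]
        }, logical(1)))
      }, logical(1))
      if (any(changed) && !lid %in% names(aberrant)) {
        affected <- model$loci[[lid]]$alleles[changed][1]
        retained <- setdiff(model$loci[[lid]]$alleles, affected)[1]
        est <- list(q$ch1, q$ch2)
        names(est) <- c(panel$ch1_allele[i], panel$ch2_allele[i])
        aberrant[[lid]] <- aberrant_fraction_from_snp(
          est[[retained]], est[[affected]],
          infer_alteration(model, lid), locus_id = lid
        )
      }
    }
  }

  # stage 3: copy-number-corrected mutant cell fraction
  mcf <- NULL
  if (!is.null(maf)) {
    cna_at_mut <- aberrant[[mutation_locus]]
    mcf <- mutant_cell_fraction(maf, cna_at_mut, model = model,
                                mutation_locus = mutation_locus)
  }

  # stage 4: deconvolution.  The observations are the independent
  # measurement-layer estimates (MAF from the mutation well, aberrant
  # fractions from the copy-number/SNP wells), not the derived MCF, so the
  # bootstrap's independence assumption holds.
  obs <- NULL
  composition <- NULL
  if (!is.null(maf)) {
    obs <- data.frame(statistic = "maf", locus_id = mutation_locus,
                      value = maf$fraction, se = maf$se,
                      ci_low = maf$ci95[1], ci_high = maf$ci95[2],
                      alteration = NA_character_)
    for (lid in names(aberrant)) {
      ab <- aberrant[[lid]]
      obs <- rbind(obs, data.frame(
        statistic = "aberrant_fraction", locus_id = lid,
        value = ab$fraction, se = ab$se,
        ci_low = ab$ci95[1], ci_high = ab$ci95[2],
        alteration = ab$alteration
      ))
    }
    composition <- tryCatch(
      deconvolve(model, obs, ci = TRUE, n_boot = n_boot, seed = seed),
      unidentifiable_model_error = function(e) NULL
    )
  }

  # stage 5: clonal/subclonal ordering
  events <- NULL
  cell_fractions <- list()
  if (!is.null(mcf)) {
    cell_fractions[[paste0("mutation:", mutation_locus)]] <- mcf
  }
  for (lid in names(aberrant)) {
    cell_fractions[[paste0(aberrant[[lid]]$alteration, ":", lid)]] <-
      aberrant[[lid]]
  }
  if (length(cell_fractions) >= 1L) {
    events <- order_events(cell_fractions, alpha = alpha)
  }

  narrative <- build_narrative(model, composition, maf, aberrant, events,
                               alpha)
  structure(
    list(sample_id = sample_id, quantification = quantification, maf = maf,
         mutation_locus = mutation_locus, mcf = mcf, cn = cn,
         aberrant = aberrant, observations = obs, composition = composition,
         events = events, narrative = narrative, alpha = alpha, seed = seed),
    class = "tumor_report"
  )
}

# human-readable evolution summary; every number also exists in the report
build_narrative <- function(model, composition, maf, aberrant, events,
                            alpha) {
  mut_detected <- !is.null(maf) && maf$ci95[1] > 0
  cna_detected <- any(vapply(aberrant, function(a) a$ci95[1] > 0, logical(1)))
  if (!mut_detected && !cna_detected) {
    return("no somatic events detected")
  }
  lines <- character(0)
  if (!is.null(events)) {
    for (g in unique(events$group)) {
      ev <- events[events$group == g, ]
      lines <- c(lines, sprintf(
        "%s events (~%s of cells): %s",
        ev$label[1], fmt_pct(mean(ev$fraction)),
        paste(ev$event, collapse = ", ")
      ))
    }
  }
  if (!is.null(composition)) {
    lines <- c(lines, paste(
      "composition:",
      paste(sprintf("%s %s", names(composition$proportions),
                    vapply(composition$proportions, fmt_pct, character(1))),
            collapse = ", ")
    ))
  }
  paste(lines, collapse = "; ")
}

#' @export
print.tumor_report <- function(x, ...) {
  cat(sprintf("<tumor_report> sample %s\n", x$sample_id))
  if (!is.null(x$maf)) {
    cat(sprintf("  mutant allele fraction: %s %s\n",
                fmt_pct(x$maf$fraction), fmt_ci(x$maf$ci95)))
  }
  if (!is.null(x$mcf)) {
    cat(sprintf("  mutant cell fraction:   %s %s\n",
                fmt_pct(x$mcf$fraction), fmt_ci(x$mcf$ci95)))
  }
  for (lid in names(x$cn)) {
    cat(sprintf("  cn(%s) = %.2f %s\n", lid, x$cn[[lid]]$cn,
                fmt_ci(x$cn[[lid]]$ci95)))
  }
  if (!is.null(x$composition)) {
    print(x$composition)
  }
  cat("  ", x$narrative, "\n", sep = "")
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes `<sample>_report.json` (full precision, the record of authority),
#' plus `<sample>_composition.tsv` and `<sample>_events.tsv` with
#' percentages rounded to whole numbers for display.  Identical inputs and
#' seed produce byte-identical files.
#'
#' @param report A `tumor_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The JSON path, invisibly.
#' @export
write_report <- function(report, dir = ".") {
  stopifnot(inherits(report, "tumor_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, report$sample_id)
  json_path <- paste0(stem, "_report.json")
  jsonlite::write_json(
    rapply(unclass(report), unclass, how = "replace"),
    json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null",
    force = TRUE
  )
  if (!is.null(report$composition)) {
    comp <- data.frame(
      population = names(report$composition$proportions),
      percent = round(100 * report$composition$proportions)
    )
    if (!is.null(report$composition$ci95)) {
      comp$ci_low_percent <- round(100 * report$composition$ci95[1, ])
      comp$ci_high_percent <- round(100 * report$composition$ci95[2, ])
    }
    utils::write.table(comp, paste0(stem, "_composition.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$events)) {
    ev <- report$events
    ev$percent <- round(100 * ev$fraction)
    utils::write.table(ev[c("event", "percent", "group", "label")],
                       paste0(stem, "_events.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
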