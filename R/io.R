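# File interfaces: well-count CSV, assay-panel JSON, observation TSV,
# allele-count TSV, and result writers.

#' Validate an assay panel
#'
#' An assay panel describes which ddPCR assay measures which allele or
#' locus: `mutation_duplex` (channel 1 = somatic allele, channel 2 = wild
#' type), `cn_multiplex` (channel 1 = locus total, channel 2 = a
#' germline-diploid reference, either in-well or via `reference_assay_id`),
#' and `snp_duplex` (the two alleles of a germline-heterozygous SNP).
#'
#' @param assays Data frame with columns `assay_id`, `kind`, `locus_id`,
#'   `ch1_allele`, `ch2_allele`, and optionally `reference_assay_id`.
#' @return The validated data frame, classed `assay_panel`.
#' @export
assay_panel <- function(assays) {
  stopifnot(is.data.frame(assays))
  needed <- c("assay_id", "kind", "locus_id", "ch1_allele", "ch2_allele")
  missing <- setdiff(needed, names(assays))
  if (length(missing)) {
    dc_error("invalid_panel_error",
             paste("panel lacks columns:", paste(missing, collapse = ", ")))
  }
  if (is.null(assays$reference_assay_id)) {
    assays$reference_assay_id <- NA_character_
  }
  bad <- !assays$kind %in% c("mutation_duplex", "cn_multiplex", "snp_duplex")
  if (any(bad)) {
    dc_error("invalid_panel_error",
             paste("unknown assay kind:", paste(unique(assays$kind[bad]),
                                                collapse = ", ")))
  }
  if (anyDuplicated(assays$assay_id)) {
    dc_error("invalid_panel_error", "duplicate assay_id in panel")
  }
  refs <- assays$reference_assay_id
  unknown <- !is.na(refs) & !refs %in% assays$assay_id
  if (any(unknown)) {
    dc_error("invalid_panel_error",
             paste("reference assay not in panel:",
                   paste(refs[unknown], collapse = ", ")))
  }
  rownames(assays) <- NULL
  class(assays) <- c("assay_panel", "data.frame")
  assays
}

#' Read an assay panel from JSON
#' @param path Path to a JSON file of the form `{"assays": [...]}`.
#' @return An [assay_panel()].
#' @export
read_assay_panel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$assays)) {
    dc_error("invalid_panel_error", "panel JSON needs an 'assays' array")
  }
  assay_panel(as.data.frame(obj$assays))
}

#' @rdname read_assay_panel
#' @param panel An [assay_panel()].
#' @export
write_assay_panel <- function(panel, path) {
  stopifnot(inherits(panel, "assay_panel"))
  jsonlite::write_json(list(assays = as.data.frame(panel)), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

well_count_columns <- c("well_id", "assay_id", "n_double_pos", "n_ch1_only",
                        "n_ch2_only", "n_negative")

#' Read and validate a well-count CSV
#'
#' Expects one row per well per assay with columns `well_id`, `assay_id`,
#' `n_double_pos`, `n_ch1_only`, `n_ch2_only`, `n_negative` and optionally
#' `droplet_volume_nl` (default 0.85).  Malformed rows are reported with
#' their line number; a duplicated (well, assay) pair is an error.
#'
#' @param path Path to the CSV file (header required, UTF-8).
#' @return A data frame of validated counts; convert a subset to
#'   [droplet_well()] objects with [wells_for_assay()].
#' @export
read_well_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(well_count_columns, names(df))
  if (length(missing)) {
    dc_error("invalid_file_error",
             paste("well-count CSV lacks columns:",
                   paste(missing, collapse = ", ")))
  }
  if (is.null(df$droplet_volume_nl)) df$droplet_volume_nl <- 0.85
  count_cols <- c("n_double_pos", "n_ch1_only", "n_ch2_only", "n_negative")
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    for (col in count_cols) {
      x <- df[[col]][i]
      if (is.na(x) || !is.numeric(x) || x < 0 || abs(x - round(x)) > 1e-8) {
        dc_error("invalid_file_error",
                 sprintf("line %d: column '%s' must be a non-negative integer (got %s)",
                         line, col, format(x)))
      }
    }
    if (sum(as.numeric(df[i, count_cols])) <= 0) {
      dc_error("invalid_file_error",
               sprintf("line %d: well has zero droplets", line))
    }
    if (is.na(df$droplet_volume_nl[i]) || df$droplet_volume_nl[i] <= 0) {
      dc_error("invalid_file_error",
               sprintf("line %d: droplet_volume_nl must be positive", line))
    }
  }
  key <- paste(df$well_id, df$assay_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    dc_error("duplicate_record_error",
             sprintf("duplicate well/assay pair: %s",
                     sub("\r", " / ", dup, fixed = TRUE)))
  }
  df
}

#' @rdname read_well_counts
#' @param wells Data frame in the well-count schema (e.g. from
#'   [simulate_tumor()]).
#' @export
write_well_counts <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pooled droplet wells for one assay
#'
#' Selects the rows of a well-count table belonging to `assay_id` and pools
#' replicate wells by summing their counts (see [pool_wells()]).
#'
#' @param counts Data frame from [read_well_counts()].
#' @param assay_id Assay to extract.
#' @return A single [droplet_well()].
#' @export
wells_for_assay <- function(counts, assay_id) {
  rows <- counts[counts$assay_id == assay_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    dc_error("configuration_error",
             sprintf("no wells found for assay '%s'", assay_id))
  }
  pool_wells(lapply(seq_len(nrow(rows)), function(i) {
    droplet_well(rows$well_id[i], rows$n_double_pos[i], rows$n_ch1_only[i],
                 rows$n_ch2_only[i], rows$n_negative[i],
                 rows$droplet_volume_nl[i])
  }))
}

#' Read an observation TSV for deconvolution
#'
#' Columns: `sample_id`, `locus_id`, `statistic` (`maf`, `cn`,
#' `aberrant_fraction` or `mcf`), `value`, `ci_low`, `ci_high`, and
#' optionally `allele` and `alteration`.
#'
#' @param path Path to the TSV file.
#' @return A data frame usable as the `observations` of [deconvolve()].
#' @export
read_observations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "locus_id", "statistic", "value")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    dc_error("invalid_file_error",
             paste("observation TSV lacks columns:",
                   paste(missing, collapse = ", ")))
  }
  df
}

#' Read an allele-count TSV for expression analysis
#'
#' Columns: `sample_id`, `level` (`DNA`/`RNA`), `allele1_label`,
#' `allele2_label`, `n_allele1`, `n_allele2`, `source`.
#'
#' @param path Path to the TSV file.
#' @return A data frame usable by [ase_report()].
#' @export
read_allele_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "level", "allele1_label", "allele2_label",
              "n_allele1", "n_allele2", "source")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    dc_error("invalid_file_error",
             paste("allele-count TSV lacks columns:",
                   paste(missing, collapse = ", ")))
  }
  df
}

#' Write per-assay quantification results
#'
#' @param quant Data frame of quantification records (as found in the
#'   `quantification` element of a [run_pipeline()] report).
#' @param path Output TSV path.
#' @export
write_quantification_tsv <- function(quant, path) {
  utils::write.table(quant, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
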