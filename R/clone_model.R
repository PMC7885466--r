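# Clone models: loci, populations with per-locus allele copy numbers,
# compositions on the simplex, and JSON (de)serialisation.

#' Define a genomic locus measured by the assay panel
#'
#' @param locus_id Locus label, e.g. `"CYSLTR2"` or a chromosome arm such as
#'   `"chr13q"`.
#' @param alleles Character vector of allele labels at this locus (e.g.
#'   `c("mut", "wt")` or two SNP alleles).  Defaults to a single unphased
#'   label equal to `locus_id`, for loci where only total copy number is
#'   measured.
#' @param germline_copies Total copies per cell in the germline (2 for an
#'   autosomal locus).
#' @return An object of class `dc_locus`.
#' @export
locus <- function(locus_id, alleles = locus_id, germline_copies = 2L) {
  stopifnot(is.character(locus_id), length(locus_id) == 1L,
            is.character(alleles), length(alleles) >= 1L,
            !anyDuplicated(alleles),
            is_count(germline_copies), germline_copies >= 1)
  structure(
    list(locus_id = locus_id, alleles = alleles,
         germline_copies = as.integer(germline_copies)),
    class = "dc_locus"
  )
}

#' Define one cell population of a clone model
#'
#' @param id Population label; the first population of a model must be the
#'   healthy (germline) population.
#' @param copies Named list, one entry per locus, each a named numeric vector
#'   of allele copy numbers (or a single number for unphased loci).
#' @param parent Id of the parent population; defaults to the previous
#'   population in the model (linear chain).
#' @return An object of class `dc_population`.
#' @export
population <- function(id, copies, parent = NULL) {
  stopifnot(is.character(id), length(id) == 1L, is.list(copies))
  structure(list(id = id, copies = copies, parent = parent),
            class = "dc_population")
}

#' Build a clone model: healthy cells plus nested clones
#'
#' A clone model lists the cell populations that may make up a bulk sample
#' and the integer allele copy numbers each carries at every measured locus.
#' The first population is the healthy one and must carry the germline
#' genotype everywhere.  By default the populations form a linear chain
#' (each clone descends from the previous population and inherits its
#' alterations), the topology relevant for a tumour that acquired a driver
#' mutation and later a copy-number change of the same locus.  Branching
#' topologies can be encoded through explicit `parent` fields but are never
#' inferred.
#'
#' @param loci List of [locus()] objects.
#' @param populations List of [population()] objects, healthy first.
#' @return An object of class `clone_model`.
#' @examples
#' # germline -> clone I (heterozygous mutation) -> clone II (wild type lost)
#' m <- clone_model(
#'   loci = list(locus("CYSLTR2", c("mut", "wt"))),
#'   populations = list(
#'     population("healthy", list(CYSLTR2 = c(mut = 0, wt = 2))),
#'     population("cloneI",  list(CYSLTR2 = c(mut = 1, wt = 1))),
#'     population("cloneII", list(CYSLTR2 = c(mut = 1, wt = 0)))
#'   )
#' )
#' @export
clone_model <- function(loci, populations) {
  stopifnot(length(loci) >= 1L, length(populations) >= 1L,
            all(vapply(loci, inherits, logical(1), "dc_locus")),
            all(vapply(populations, inherits, logical(1), "dc_population")))
  locus_ids <- vapply(loci, `[[`, character(1), "locus_id")
  pop_ids <- vapply(populations, `[[`, character(1), "id")
  if (anyDuplicated(locus_ids)) dc_error("invalid_model_error", "duplicate locus ids")
  if (anyDuplicated(pop_ids)) dc_error("invalid_model_error", "duplicate population ids")
  names(loci) <- locus_ids

  # normalise copies: every population must state every locus, alleles named
  populations <- lapply(populations, function(pop) {
    for (lid in locus_ids) {
      cp <- pop$copies[[lid]]
      if (is.null(cp)) {
        dc_error("invalid_model_error",
                 sprintf("population '%s' lacks copies for locus '%s'",
                         pop$id, lid))
      }
      cp <- unlist(cp)
      alleles <- loci[[lid]]$alleles
      if (is.null(names(cp)) && length(cp) == length(alleles)) {
        names(cp) <- alleles
      }
      if (!setequal(names(cp), alleles)) {
        dc_error("invalid_model_error",
                 sprintf("population '%s', locus '%s': alleles must be {%s}",
                         pop$id, lid, paste(alleles, collapse = ", ")))
      }
      cp <- cp[alleles]
      if (any(cp < 0) || any(abs(cp - round(cp)) > 1e-8)) {
        dc_error("invalid_model_error",
                 "allele copy numbers must be non-negative integers")
      }
      pop$copies[[lid]] <- cp
    }
    pop
  })

  # healthy population carries the germline genotype at every locus
  healthy <- populations[[1]]
  for (lc in loci) {
    if (abs(sum(healthy$copies[[lc$locus_id]]) - lc$germline_copies) > 1e-8) {
      dc_error("invalid_model_error",
               sprintf("healthy population must carry %d copies at '%s'",
                       lc$germline_copies, lc$locus_id))
    }
  }

  # default nesting: linear chain
  for (i in seq_along(populations)) {
    if (i > 1 && is.null(populations[[i]]$parent)) {
      populations[[i]]$parent <- pop_ids[i - 1]
    }
    p <- populations[[i]]$parent
    if (!is.null(p) && !p %in% pop_ids[seq_len(i - 1)]) {
      dc_error("invalid_model_error",
               sprintf("parent '%s' of population '%s' must precede it",
                       p, pop_ids[i]))
    }
  }
  names(populations) <- pop_ids
  structure(list(loci = loci, populations = populations),
            class = "clone_model")
}

#' @export
print.clone_model <- function(x, ...) {
  cat(sprintf("<clone_model> %d loci, %d populations (%s)\n",
              length(x$loci), length(x$populations),
              paste(names(x$populations), collapse = " -> ")))
  invisible(x)
}

population_ids <- function(model) names(model$populations)

# (locus:allele) x population matrix of allele copy numbers
allele_copy_matrix <- function(model) {
  rows <- unlist(lapply(model$loci, function(lc) {
    paste(lc$locus_id, lc$alleles, sep = ":")
  }), use.names = FALSE)
  m <- matrix(0, nrow = length(rows), ncol = length(model$populations),
              dimnames = list(rows, population_ids(model)))
  for (pop in model$populations) {
    for (lc in model$loci) {
      m[paste(lc$locus_id, lc$alleles, sep = ":"), pop$id] <-
        pop$copies[[lc$locus_id]]
    }
  }
  m
}

# locus x population matrix of total copy numbers
total_copy_matrix <- function(model) {
  m <- allele_copy_matrix(model)
  lids <- sub(":.*$", "", rownames(m))
  t(vapply(model$loci, function(lc) {
    colSums(m[lids == lc$locus_id, , drop = FALSE])
  }, numeric(ncol(m))))
}

#' Mixing proportions of a clone model's populations
#'
#' @param proportions Numeric vector, one proportion per population, each in
#'   `[0, 1]` and summing to 1 (within 1e-9).
#' @param pop_ids Optional population names (taken from `names(proportions)`
#'   otherwise).
#' @return An object of class `clone_composition`.
#' @export
clone_composition <- function(proportions, pop_ids = names(proportions)) {
  stopifnot(is.numeric(proportions), length(proportions) >= 1L)
  if (any(proportions < -1e-9) || any(proportions > 1 + 1e-9)) {
    dc_error("invalid_composition_error", "proportions must lie in [0, 1]")
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    dc_error("invalid_composition_error",
             sprintf("proportions must sum to 1 (got %.12f)", sum(proportions)))
  }
  proportions <- clip01(proportions)
  if (!is.null(pop_ids)) names(proportions) <- pop_ids
  structure(list(proportions = proportions), class = "clone_composition")
}

#' @export
print.clone_composition <- function(x, ...) {
  cat("<clone_composition>\n")
  for (i in seq_along(x$proportions)) {
    nm <- names(x$proportions)[i] %||% sprintf("pop%d", i)
    line <- sprintf("  %-12s %s", nm, fmt_pct(x$proportions[i]))
    if (!is.null(x$ci95)) {
      line <- paste0(line, " ", fmt_ci(x$ci95[, i]))
    }
    cat(line, "\n")
  }
  invisible(x)
}

#' Read or write a clone model as JSON
#'
#' The on-disk schema is
#' `{"loci": [{"locus_id", "germline_copies", "alleles"}],
#'   "populations": [{"id", "parent", "copies": {locus: {allele: n}}}]}`.
#'
#' @param path File path.
#' @return `read_clone_model()` returns a [clone_model()];
#'   `write_clone_model()` returns `path` invisibly.
#' @export
read_clone_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$loci) || is.null(obj$populations)) {
    dc_error("invalid_model_error",
             "clone-model JSON needs 'loci' and 'populations'")
  }
  loci <- lapply(obj$loci, function(l) {
    locus(l$locus_id,
          alleles = unlist(l$alleles) %||% l$locus_id,
          germline_copies = l$germline_copies %||% 2L)
  })
  pops <- lapply(obj$populations, function(p) {
    population(p$id, lapply(p$copies, unlist), parent = p$parent)
  })
  clone_model(loci, pops)
}

#' @rdname read_clone_model
#' @param model A [clone_model()].
#' @export
write_clone_model <- function(model, path) {
  stopifnot(inherits(model, "clone_model"))
  obj <- list(
    loci = lapply(unname(model$loci), function(l) {
      list(locus_id = l$locus_id, germline_copies = l$germline_copies,
           alleles = as.list(l$alleles))
    }),
    populations = lapply(unname(model$populations), function(p) {
      list(id = p$id, parent = p$parent,
           copies = lapply(p$copies, as.list))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
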