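#' A single ddPCR well: 2x2 droplet classification counts
#'
#' Represents the endpoint readout of one duplex ddPCR well after droplet
#' gating: the number of droplets positive on both channels, on channel 1
#' only, on channel 2 only, and negative on both.  Raw fluorescence
#' thresholding is upstream (done by the instrument software); `dropclone`
#' consumes the classified counts.
#'
#' @param well_id Character label for the well.
#' @param n_double_pos Droplets positive on both channels.
#' @param n_ch1_only Droplets positive on channel 1 only.
#' @param n_ch2_only Droplets positive on channel 2 only.
#' @param n_negative Droplets negative on both channels.
#' @param droplet_volume_nl Partition volume in nanolitres.  Defaults to
#'   0.85 nL, the nominal droplet volume of the QX200 platform.
#'
#' @return An object of class `droplet_well`.
#' @examples
#' droplet_well("A01", n_double_pos = 100, n_ch1_only = 900,
#'              n_ch2_only = 900, n_negative = 18100)
#' @export
droplet_well <- function(well_id, n_double_pos, n_ch1_only, n_ch2_only,
                         n_negative, droplet_volume_nl = 0.85) {
  counts <- c(n_double_pos, n_ch1_only, n_ch2_only, n_negative)
  for (x in counts) {
    if (!is_count(x)) {
      dc_error("invalid_well_error",
               "droplet counts must be single non-negative integers")
    }
  }
  if (sum(counts) <= 0) {
    dc_error("empty_well_error", "well contains no droplets")
  }
  if (!is.numeric(droplet_volume_nl) || droplet_volume_nl <= 0) {
    dc_error("invalid_well_error", "droplet_volume_nl must be positive")
  }
  structure(
    list(
      well_id = as.character(well_id),
      n_double_pos = as.integer(n_double_pos),
      n_ch1_only = as.integer(n_ch1_only),
      n_ch2_only = as.integer(n_ch2_only),
      n_negative = as.integer(n_negative),
      droplet_volume_nl = droplet_volume_nl
    ),
    class = "droplet_well"
  )
}

#' @export
print.droplet_well <- function(x, ...) {
  cat(sprintf(
    "<droplet_well %s> %d droplets (%.2f nL): ++ %d, ch1 %d, ch2 %d, -- %d\n",
    x$well_id, n_droplets(x), x$droplet_volume_nl,
    x$n_double_pos, x$n_ch1_only, x$n_ch2_only, x$n_negative
  ))
  invisible(x)
}

#' Total droplet count of a well
#' @param well A [droplet_well()].
#' @return Integer droplet count.
#' @export
n_droplets <- function(well) {
  stopifnot(inherits(well, "droplet_well"))
  well$n_double_pos + well$n_ch1_only + well$n_ch2_only + well$n_negative
}

#' Pool replicate wells of the same assay
#'
#' Counts are summed before Poisson correction (the maximum-likelihood
#' treatment of replicates), not quantified per well and averaged.
#'
#' @param wells A list of [droplet_well()] objects run with the same assay
#'   and partition volume.
#' @return A single [droplet_well()] with summed counts.
#' @export
pool_wells <- function(wells) {
  stopifnot(length(wells) >= 1L,
            all(vapply(wells, inherits, logical(1), "droplet_well")))
  vols <- vapply(wells, `[[`, numeric(1), "droplet_volume_nl")
  if (diff(range(vols)) > 1e-9) {
    dc_error("invalid_well_error",
             "cannot pool wells with different droplet volumes")
  }
  droplet_well(
    well_id = paste(vapply(wells, `[[`, character(1), "well_id"),
                    collapse = "+"),
    n_double_pos = sum(vapply(wells, `[[`, integer(1), "n_double_pos")),
    n_ch1_only = sum(vapply(wells, `[[`, integer(1), "n_ch1_only")),
    n_ch2_only = sum(vapply(wells, `[[`, integer(1), "n_ch2_only")),
    n_negative = sum(vapply(wells, `[[`, integer(1), "n_negative")),
    droplet_volume_nl = vols[1]
  )
}
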