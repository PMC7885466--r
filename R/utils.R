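# internal helpers: classed conditions, seed scoping, CI arithmetic

dc_error <- function(subclass, message) {
  cond <- structure(
    list(message = message, call = NULL),
    class = c(subclass, "dropclone_error", "error", "condition")
  )
  stop(cond)
}

# run `code` with the RNG seeded, restoring the caller's RNG state afterwards
# so that seeded simulations never perturb the global random stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

z_crit <- function(conf_level) stats::qnorm(1 - (1 - conf_level) / 2)

se_from_ci <- function(ci_low, ci_high, conf_level = 0.95) {
  (ci_high - ci_low) / (2 * z_crit(conf_level))
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 &&
    abs(x - round(x)) < 1e-8
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_pct <- function(x) sprintf("%d%%", round(100 * x))

fmt_ci <- function(ci) sprintf("[%.3f, %.3f]", ci[1], ci[2])
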