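# Shared constants and small helpers.

# Boltzmann constant in kJ/mol/K
.KB_KJMOL <- 0.00831446

#' Thermal energy kT in kJ/mol
#'
#' @param temperature_K temperature in kelvin (default 300).
#' @return kT in kJ/mol.
#' @export
kBT <- function(temperature_K = 300) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  .KB_KJMOL * temperature_K
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals (slice sampling,
#' PSO, the toy sampler) never disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible vector of sub-seeds (< 2^31) from one root seed.
derive_seeds <- function(root_seed, n) {
  with_seed(root_seed, sample.int(.Machine$integer.max, n, replace = FALSE))
}

# stop() with a consistent prefix for data-shape problems
.chk <- function(ok, ...) {
  if (!ok) stop(..., call. = FALSE)
  invisible(TRUE)
}
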