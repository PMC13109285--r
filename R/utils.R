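# Internal helpers: classed conditions, seeded evaluation, rounding.

# Classed errors so callers (and the bootstrap) can distinguish failure modes.
mic_stop <- function(subclass, msg, call. = FALSE) {
  stop(structure(
    class = c(subclass, "micfim_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

stop_validation <- function(msg) mic_stop("micfim_validation_error", msg)
stop_config     <- function(msg) mic_stop("micfim_config_error", msg)
stop_degenerate <- function(msg) mic_stop("micfim_degenerate_error", msg)
stop_separation <- function(msg) mic_stop("micfim_separation_error", msg)
stop_convergence <- function(msg) mic_stop("micfim_convergence_error", msg)

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards,
# so library functions never clobber a user's random stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# One root seed -> a reproducible table of child seeds, independent of the
# order in which the children are consumed.  Kept below 2^31 - 1.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding to the nearest integer, used for headline
#' integer MIC values: 18.5 rounds to 19, unlike [round()]'s banker's rounding.
#'
#' @param x Numeric vector.
#' @return Numeric vector of integers (as doubles).
#' @examples
#' round_half_up(c(18.5, 3.5, 22.4))
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt1 <- function(x) formatC(x, format = "f", digits = 1)
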