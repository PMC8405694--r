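# Shared numeric helpers.

#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds up in magnitude), used wherever a
#' percentage is reported as an integer; `base::round()` rounds half to even,
#' which does not reproduce tabulated membrane-composition percentages.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# population standard deviation (divisor n, not n-1)
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

#' Derive a module-specific sub-seed from a global seed
#'
#' Fans one global integer seed out to reproducible per-module seeds by a
#' stable arithmetic hash of the module name, so each stage of a pipeline can
#' be re-run independently with the same stream.
#'
#' @param seed integer global seed.
#' @param module character scalar naming the consumer.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, module) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(module))
  cp <- utf8ToInt(module)
  h <- sum(cp * seq_along(cp))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483629)
}

# stop() with a classed condition so callers can test error categories
abort2 <- function(msg, class) {
  stop(structure(
    class = c(class, "membranekit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
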