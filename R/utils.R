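#' Derive a child seed from a root seed
#'
#' Folds an arbitrary sequence of integer or character keys into a root seed
#' with a Lehmer-style multiplicative mix modulo the Mersenne prime 2^31 - 1.
#' Used throughout the package to give every replicate, simulation run, GA
#' operator phase and resampling unit its own reproducible stream, so that
#' changing e.g. the number of simulations per candidate never perturbs the
#' draws of an unrelated component, and job order cannot change results.
#'
#' @param root Integer root seed.
#' @param ... Integer or character keys identifying the stream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(42, "init")
#' derive_seed(42, "sim", 3, 7)
#' @export
derive_seed <- function(root, ...) {
  keys <- list(...)
  s <- as.double(root) %% 2147483647
  for (k in keys) {
    if (is.character(k)) {
      cp <- utf8ToInt(k)
      k <- sum(cp * seq_along(cp))
    }
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  }
  s <- (s * 48271 + 1) %% 2147483647
  if (s < 1) s <- 1
  as.integer(s)
}

# classed abort helpers so callers can distinguish error families
stop_parse <- function(msg) abort(msg, class = "stochcal_error_parse")
stop_align <- function(msg) abort(msg, class = "stochcal_error_align")
stop_validation <- function(msg) abort(msg, class = "stochcal_error_validation")
stop_degenerate <- function(msg) abort(msg, class = "stochcal_error_degenerate")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
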