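stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a reproducible sub-seed from a base seed
#'
#' All stochastic stages of the package draw from sub-seeds derived from one
#' user-supplied base seed with this fixed scheme, so that a single integer
#' reproduces a whole study while independent stages (universe generation,
#' per-condition coverage, per-cell bootstrap resampling) do not share a
#' random stream.
#'
#' @param seed integer base seed.
#' @param index non-negative integer stream index.
#' @return An integer in \code{[0, 2^31 - 2]}.
#' @export
sub_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  as.integer((as.double(seed) + 7919 * as.double(index)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
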