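#' @keywords internal
#' @useDynLib mbode
"_PACKAGE"

# Natural-log factor between log10 and natural parameter scales.
LN10 <- log(10)

#' Clip a vector element-wise into a box
#'
#' @param x numeric vector.
#' @param lower,upper bounds, recycled to `length(x)`.
#' @return `x` with each element forced into `[lower, upper]`.
#' @keywords internal
clip_box <- function(x, lower, upper) {
  pmin(pmax(x, lower), upper)
}

#' Derive a child seed from a base seed and a stream index
#'
#' All randomness in the package (start sampling, epoch shuffling, measurement
#' noise) flows from one user-facing seed through named streams, so that e.g.
#' two optimizer settings can share start points while their batch shuffles
#' differ. The derived seed stays below 2^31.
#'
#' @param seed integer base seed.
#' @param stream integer stream index (>= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 1664525 * as.double(stream) + 12345) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_finite_vec <- function(x) length(x) > 0 && all(is.finite(x))
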