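#' Round half away from zero
#'
#' Base `round()` rounds half to even; percentage reporting here follows the
#' usual half-up convention (e.g. 99.925 -> 99.93 at two decimals).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# condition constructor: all package errors carry class "bgcrep_error" plus a
# specific subclass so callers/tests can distinguish them
bgc_stop <- function(subclass, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(subclass, "bgcrep_error"), call = call))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
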