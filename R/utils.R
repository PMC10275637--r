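# Internal numerical helpers shared across modules.

#' Log-sum-exp of a numeric vector
#'
#' Stable computation of \code{log(sum(exp(x)))}; tolerates \code{-Inf}
#' entries (empty configurations) and returns \code{-Inf} for an empty input.
#'
#' @param x numeric vector of log-scale values.
#' @return scalar \code{log(sum(exp(x)))}.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, clamped at -Inf when the difference
# underflows (used for the H3 configuration sum).
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# softmax on the log scale
softmax_log <- function(x) {
  exp(x - logsumexp(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Central BED <-> 1-based coordinate conversion: a 1-based position pos
# falls in 0-based half-open [start, end) iff start <= pos - 1 < end.
pos_in_bed_interval <- function(pos, start, end) {
  (pos - 1L) >= start & (pos - 1L) < end
}

# two-sided normal p-value from z, on the log scale when requested
z_to_p <- function(z, log.p = FALSE) {
  if (log.p) log(2) + stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)
  else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

# derive a stream of per-unit seeds below 2^31 from one master seed
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
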