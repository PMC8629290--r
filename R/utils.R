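# Internal numeric helpers shared across modules.

# Sample skewness g1 = m3 / m2^(3/2) with population moments.
# Defined as 0 for constant (or near-constant) samples.
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) {
    return(0)
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= .Machine$double.eps * max(1, m^2)) {
    return(0)
  }
  mean((x - m)^3) / m2^1.5
}

# Population (divide-by-n) standard deviation.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_synoptic <- function(...) {
  stop(..., call. = FALSE)
}
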