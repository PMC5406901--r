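# internal numerics shared across the package

#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @keywords internal
#' @noRd
logmeanexp <- function(x) logsumexp(x) - log(length(x))

# derive a bounded 32-bit seed stream from a master seed; keeps every seed
# strictly below 2^31 so set.seed() never overflows
#' @keywords internal
#' @noRd
seed_stream <- function(seed, n, salt = 0L) {
  a <- (as.double(seed) %% 2147483629) + 1
  s <- numeric(n)
  x <- (a * 48271 + salt * 1299721 + 11) %% 2147483647
  for (i in seq_len(n)) {
    x <- (x * 48271 + 11) %% 2147483647
    s[i] <- x
  }
  as.integer(s %% 2147483646 + 1)
}
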