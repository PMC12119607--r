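# Internal helpers shared across modules.

# Deterministic substream seeds: a small multiplicative hash of the master
# seed and an index, kept strictly below 2^31 so set.seed() accepts it.
# Partial regeneration is stable because each cell only consumes its own
# substream.
substream_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.double(master) %% m)
  for (i in as.double(index)) {
    s <- (s * 48271 + i + 1) %% m
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_domain(sprintf("'%s' must be a positive finite scalar", name))
  }
  invisible(x)
}

# Five-number summary as a named vector (Tukey-style, type 7 quartiles).
five_num <- function(x) {
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}
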