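# Brute-force LZ76 oracle: parses the sequence into the exhaustive history
# by direct substring search (each phrase is the longest extension
# reproducible from the whole preceding text, plus one symbol). Independent
# of the compiled Kaspar-Schuster counter it checks.
lz76_oracle <- function(bits) {
  s <- paste(as.integer(bits), collapse = "")
  n <- nchar(s)
  if (n == 0) return(0L)
  cnt <- 0L
  i <- 1L
  while (i <= n) {
    k <- 0L
    while (i + k <= n &&
           grepl(substr(s, i, i + k), substr(s, 1, i + k - 1), fixed = TRUE))
      k <- k + 1L
    cnt <- cnt + 1L
    i <- i + k + 1L
  }
  cnt
}

# all binary vectors of length n, as rows
all_bitstrings <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(m) <- NULL
  m
}
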