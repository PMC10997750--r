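# First-order Reed-Muller code RM(1, m): length 2^m, dimension m + 1,
# minimum distance 2^(m-1). Codewords are the truth tables of affine
# Boolean functions a0 + <a, x>; maximum-likelihood decoding is a fast
# Hadamard transform. Used by the fuzzy extractor as the binary block
# code of its code-offset sketch: with bounded-distance decoding at
# radius t <= 2^(m-2) - 1 every error pattern of weight <= t decodes
# uniquely to the transmitted codeword.

# message bits: c(a0, a1, ..., am) -> codeword of length 2^m
rm1_encode <- function(msg, m) {
  stopifnot(length(msg) == m + 1L, all(msg %in% c(0L, 1L)))
  n <- 2L^m
  x <- 0:(n - 1L)
  bits <- vapply(seq_len(m), function(j) bitwAnd(bitwShiftR(x, j - 1L), 1L),
                 integer(n))
  inner <- as.integer(bits %*% msg[-1L]) %% 2L
  (msg[1L] + inner) %% 2L
}

# in-place fast Walsh-Hadamard transform of a numeric vector (length 2^m)
fwht <- function(v) {
  n <- length(v)
  h <- 1L
  while (h < n) {
    for (i in seq(1L, n, by = 2L * h)) {
      a <- v[i:(i + h - 1L)]
      b <- v[(i + h):(i + 2L * h - 1L)]
      v[i:(i + h - 1L)] <- a + b
      v[(i + h):(i + 2L * h - 1L)] <- a - b
    }
    h <- 2L * h
  }
  v
}

# Bounded-distance decoding: ML estimate via the Hadamard spectrum, then
# accept only if the decoded codeword lies within Hamming radius t of the
# received word. Returns list(ok, msg, codeword).
rm1_decode <- function(received, m, t) {
  stopifnot(length(received) == 2L^m)
  w <- fwht(1 - 2 * received)          # (-1)^bit spectrum
  j <- which.max(abs(w))
  a0 <- as.integer(w[j] < 0)
  a <- vapply(seq_len(m), function(b) bitwAnd(bitwShiftR(j - 1L, b - 1L), 1L),
              integer(1))
  msg <- c(a0, a)
  cw <- rm1_encode(msg, m)
  dist <- sum(cw != received)
  list(ok = dist <= t, msg = msg, codeword = cw, dist = dist)
}
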