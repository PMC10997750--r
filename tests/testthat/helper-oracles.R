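# Independent oracles and tiny fixture builders. The oracles deliberately
# avoid the implementation paths they check.

# Levenshtein distance by explicit dynamic programming.
dp_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    D[i + 1, j + 1] <- min(D[i, j + 1] + 1L, D[i + 1, j] + 1L,
                           D[i, j] + (x[i] != y[j]))
  D[n + 1, m + 1]
}

# Weighted Jaccard by direct summation over a merged named vector.
oracle_weighted_jaccard <- function(a, b) {
  keys <- union(names(a), names(b))
  av <- ifelse(keys %in% names(a), a[keys], 0)
  bv <- ifelse(keys %in% names(b), b[keys], 0)
  sum(pmin(av, bv, na.rm = TRUE)) / sum(pmax(av, bv, na.rm = TRUE))
}

# Plain (set) Jaccard.
set_jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

random_string <- function(len = 10L) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# n distinct random k-mer strings.
random_kmer_set <- function(n, len = 10L) {
  out <- unique(replicate(2L * n + 10L, random_string(len)))
  stopifnot(length(out) >= n)
  out[seq_len(n)]
}

# Minimal output table built directly from sequences and counts.
make_output_table <- function(seqs, counts) {
  stopifnot(length(seqs) == length(counts))
  structure(list(kmer = seqs, count = as.integer(counts),
                 n_total_reads = sum(counts), n_passing = sum(counts),
                 output_length = nchar(seqs[1])),
            class = "cuf_output_table")
}

# A tiny pool with fully specified random segments: each row of `rand`
# gives input1, output, input2 for one template.
make_pool <- function(design, rand, counts = rep(1, nrow(rand))) {
  seg <- design$segments
  seqs <- paste0(seg$sequence[1], rand[, 1], seg$sequence[3], rand[, 2],
                 seg$sequence[5], rand[, 3], seg$sequence[7])
  cufsim:::new_pool(seqs, counts, "copiable", design)
}

# All 4^n base strings of length n.
all_inputs <- function(n) {
  grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), n))
  apply(grid, 1, paste, collapse = "")
}
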