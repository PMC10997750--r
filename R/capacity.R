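#' Capacity and security arithmetic of a CUF
#'
#' Pure analytic functions for the scales at which real pools operate
#' (1e8 to 2.6e10 unique sequences and beyond), where materializing the
#' pool is impossible and the relevant quantities follow from counting
#' arguments.
#'
#' \describe{
#'   \item{\code{crp_count(n)}}{number of challenge-response pairs for an
#'     n-base input: exactly 4^n (a power of 2, hence exact in double
#'     arithmetic for any practical n). n = 13 gives ~67 million CRPs.}
#'   \item{\code{expected_match_count(pool_size, n)}}{expected number of
#'     pool templates perfectly matching a random n-base challenge:
#'     pool_size / 4^n. A 1e8-sequence pool at n = 13 expects ~1.5.}
#'   \item{\code{coupon_depth(n_unique)}}{coupon-collector sequencing
#'     redundancy needed to observe every unique sequence at least once:
#'     depth ~ ln(n), total reads ~ n ln(n). \code{exact = TRUE} uses the
#'     full n * H_n form instead of the ln(n) simplification.}
#'   \item{\code{evaluation_capacity(branching, generations,
#'     ops_per_pool)}}{operations supported by a proliferation tree:
#'     branching^generations leaf pools times operations per pool.}
#'   \item{\code{resynthesis_cost(n_seq, seq_length, usd_per_nt)}}{cost of
#'     re-synthesizing the pool sequence by sequence.}
#'   \item{\code{pool_entropy(n_seq, random_nt)}}{chemical entropy of the
#'     pool at the theoretical density of 2 bits per base: bits and
#'     exabytes.}
#' }
#'
#' @param n challenge length (number of input bases).
#' @return \code{crp_count}: a count (exact double).
#' @examples
#' crp_count(13)                      # 67108864
#' expected_match_count(1e8, 13)      # ~1.49
#' coupon_depth(2.6e10)$depth         # ~24
#' evaluation_capacity(200, 5, 200)   # 6.4e13
#' resynthesis_cost(2.6e10, 100, 1e-5)  # 2.6e7 USD
#' pool_entropy(6e16, 40)$exabytes    # 0.6
#' @export
crp_count <- function(n) {
  stopifnot(n >= 0)
  4^n
}

#' @rdname crp_count
#' @param pool_size number of unique sequences in the pool.
#' @export
expected_match_count <- function(pool_size, n) {
  stopifnot(pool_size >= 1)
  pool_size / 4^n
}

#' @rdname crp_count
#' @param n_unique number of unique sequences to be read.
#' @param exact use the exact coupon-collector form n * H_n rather than
#'   the ln(n) simplification.
#' @export
coupon_depth <- function(n_unique, exact = FALSE) {
  stopifnot(n_unique >= 2)
  if (exact) {
    harm <- if (n_unique <= 1e6) sum(1 / seq_len(n_unique))
            else log(n_unique) + 0.5772156649015329 + 1 / (2 * n_unique)
    list(depth = harm, total_reads = n_unique * harm)
  } else {
    list(depth = log(n_unique), total_reads = n_unique * log(n_unique))
  }
}

#' @rdname crp_count
#' @param branching copies produced per proliferation step.
#' @param generations proliferation depth.
#' @param ops_per_pool function operations supported by one pool copy.
#' @export
evaluation_capacity <- function(branching, generations, ops_per_pool) {
  stopifnot(branching >= 1, generations >= 1, ops_per_pool >= 1)
  branching^generations * ops_per_pool
}

#' @rdname crp_count
#' @param n_seq number of sequences to re-synthesize.
#' @param seq_length length (nt) of each sequence.
#' @param usd_per_nt synthesis price per nucleotide.
#' @export
resynthesis_cost <- function(n_seq, seq_length, usd_per_nt) {
  stopifnot(n_seq > 0, seq_length > 0, usd_per_nt > 0)
  n_seq * seq_length * usd_per_nt
}

#' @rdname crp_count
#' @param random_nt random nucleotides per sequence.
#' @export
pool_entropy <- function(n_seq, random_nt) {
  stopifnot(n_seq > 0, random_nt > 0)
  bits <- n_seq * random_nt * 2
  list(bits = bits, exabytes = bits / 8 / 1e18)
}

#' Assemble a full capacity report
#'
#' @param pool_size unique sequences in the operated pool.
#' @param n challenge length in bases.
#' @param random_nt random nucleotides per sequence.
#' @param seq_length full sequence length (nt) for resynthesis costing.
#' @param usd_per_nt synthesis price per nucleotide.
#' @param branching,generations,ops_per_pool proliferation-tree geometry.
#' @param masterpool_size unique sequences in the synthesized masterpool
#'   (for the entropy figures).
#' @return A \code{cuf_capacity_report} (named list of the analytic
#'   quantities above).
#' @export
capacity_report <- function(pool_size, n, random_nt = 40L, seq_length = 100L,
                            usd_per_nt = 1e-5, branching = 200L,
                            generations = 5L, ops_per_pool = 200L,
                            masterpool_size = 6e16) {
  cd <- coupon_depth(pool_size)
  pe <- pool_entropy(masterpool_size, random_nt)
  structure(list(
    crp_count = crp_count(n),
    expected_matches = expected_match_count(pool_size, n),
    coupon_depth = cd$depth,
    total_reads_needed = cd$total_reads,
    evaluation_capacity = evaluation_capacity(branching, generations,
                                              ops_per_pool),
    resynthesis_cost_usd = resynthesis_cost(pool_size, seq_length, usd_per_nt),
    entropy_bits = pe$bits,
    entropy_exabytes = pe$exabytes
  ), class = "cuf_capacity_report")
}

#' @export
print.cuf_capacity_report <- function(x, ...) {
  cat("CUF capacity report\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]], digits = 6)))
  invisible(x)
}
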