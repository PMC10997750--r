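#' Parameters for k-mer profiling and MinHash signatures
#'
#' @param k k-mer length used to decompose output segments. The default
#'   10 keeps 4^k far above the number of distinct outputs while a single
#'   substitution corrupts at most k of the 12 windows of a 21-mer.
#' @param abundance_min minimum summed window count for a k-mer to enter
#'   the MinHash set; singletons are dominated by sequencing errors.
#' @param abundance_min_rel minimum k-mer count as a fraction of passing
#'   reads. Recurrent substitution errors scale with depth, so a purely
#'   absolute threshold stops filtering them at realistic depths; the
#'   effective threshold is \code{max(abundance_min, abundance_min_rel *
#'   n_passing)}. True k-mers of a response with m matching templates
#'   carry a per-read share of about 1/m (m is typically 10-30), so the
#'   default 0.005 sits an order of magnitude below them and an order of
#'   magnitude above recurrent errors.
#' @param L signature length in bits.
#' @param hash_seed integer seed of the (seed-stable) hash family.
#' @return A \code{cuf_sig_params} object with a \code{fingerprint} string
#'   used to refuse comparisons across incompatible parameterizations.
#' @export
signature_params <- function(k = 10L, abundance_min = 2L,
                             abundance_min_rel = 0.005, L = 256L,
                             hash_seed = 42L) {
  stopifnot(k >= 1L, L >= 1L, abundance_min >= 0L,
            abundance_min_rel >= 0, abundance_min_rel < 1)
  p <- list(k = as.integer(k), abundance_min = as.integer(abundance_min),
            abundance_min_rel = abundance_min_rel,
            L = as.integer(L), hash_seed = as.integer(hash_seed))
  p$fingerprint <- sprintf("k=%d;amin=%d;arel=%g;L=%d;hs=%d",
                           p$k, p$abundance_min, p$abundance_min_rel,
                           p$L, p$hash_seed)
  class(p) <- "cuf_sig_params"
  p
}

#' Weighted k-mer profile of a response
#'
#' Every length-k substring of every output sequence contributes its read
#' count; weights are then normalized to sum to 1, so unequal sequencing
#' depths cancel when profiles are compared. Raw summed counts are kept
#' alongside for the abundance filter applied by [minhash_signature()].
#'
#' @param tab a non-empty \code{cuf_output_table}.
#' @param params a \code{cuf_sig_params}; \code{k} must not exceed the
#'   output length.
#' @return A \code{cuf_kmer_profile}: k-mers, normalized weights, raw
#'   counts and \code{k}.
#' @export
extract_kmers <- function(tab, params = signature_params()) {
  if (length(tab$kmer) == 0L) stop("empty output table", call. = FALSE)
  k <- params$k
  if (k > tab$output_length)
    stop("k exceeds the output length", call. = FALSE)
  n_win <- tab$output_length - k + 1L
  # windows of all outputs, each weighted by the read count of its parent
  kmers <- unlist(lapply(seq_len(n_win),
                         function(i) substr(tab$kmer, i, i + k - 1L)),
                  use.names = FALSE)
  counts <- rep(tab$count, times = n_win)
  agg <- rowsum(counts, kmers)
  structure(list(n_reads = tab$n_passing,
                 kmer = rownames(agg),
                 weight = unname(agg[, 1]) / sum(agg[, 1]),
                 count = unname(agg[, 1]),
                 k = k),
            class = "cuf_kmer_profile")
}

#' @export
print.cuf_kmer_profile <- function(x, ...) {
  cat(sprintf("k-mer profile: %d distinct %d-mers\n", length(x$kmer), x$k))
  invisible(x)
}

#' Weighted Jaccard similarity between two k-mer profiles
#'
#' \deqn{J_w(a, b) = \sum_x \min(a_x, b_x) / \sum_x \max(a_x, b_x)}
#' over the union of supports: a score between 0 and 1, equal to 1 for
#' identical weighted sets and 0 for disjoint supports.
#'
#' @param a,b \code{cuf_kmer_profile}s with equal \code{k}.
#' @return Similarity score in [0, 1].
#' @examples
#' t1 <- structure(list(kmer = c("ACGTACGTACGTACGTACGTA"), count = 4L,
#'   n_total_reads = 4L, n_passing = 4L, output_length = 21L),
#'   class = "cuf_output_table")
#' p <- extract_kmers(t1)
#' weighted_jaccard(p, p)  # 1
#' @export
weighted_jaccard <- function(a, b) {
  stopifnot(inherits(a, "cuf_kmer_profile"), inherits(b, "cuf_kmer_profile"))
  if (a$k != b$k) stop("profiles use different k", call. = FALSE)
  if (length(a$kmer) == 0L && length(b$kmer) == 0L)
    stop("weighted Jaccard is undefined for two empty profiles", call. = FALSE)
  universe <- union(a$kmer, b$kmer)
  wa <- setNames(numeric(length(universe)), universe)
  wb <- wa
  wa[a$kmer] <- a$weight
  wb[b$kmer] <- b$weight
  sum(pmin(wa, wb)) / sum(pmax(wa, wb))
}

#' MinHash (1-bit minwise) signature
#'
#' For each of L independent hash seeds the retained k-mer with minimal
#' hash value is located (ties broken toward the lexicographically
#' smallest k-mer) and reduced to one bit, the parity of an independent
#' secondary hash. Two sets with plain Jaccard similarity J agree on each
#' bit with probability (1 + J) / 2, so the expected relative Hamming
#' distance is (1 - J) / 2 -- 0 for identical sets and 0.5 for unrelated
#' ones. The signature operates on the abundance-filtered k-mer SET
#' (summed window count at least \code{max(abundance_min,
#' abundance_min_rel * n_passing)}), not on weights: set semantics are
#' what make the 0.5 expectation exact for disjoint inputs.
#'
#' @param x a \code{cuf_kmer_profile}, or a character vector interpreted
#'   directly as a k-mer set (no abundance filter applied).
#' @param params a \code{cuf_sig_params}.
#' @return A \code{cuf_signature}: integer bit vector of length L plus the
#'   parameter fingerprint. Deterministic given input and params.
#' @export
minhash_signature <- function(x, params = signature_params()) {
  UseMethod("minhash_signature")
}

#' @export
minhash_signature.cuf_kmer_profile <- function(x, params = signature_params()) {
  thr <- max(params$abundance_min,
             params$abundance_min_rel * (x$n_reads %||% 0))
  keep <- x$kmer[x$count >= thr]
  if (length(keep) == 0L)
    stop("no k-mer passes the abundance filter; lower abundance_min",
         call. = FALSE)
  minhash_signature.character(keep, params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
minhash_signature.character <- function(x, params = signature_params()) {
  if (length(x) == 0L) stop("empty k-mer set", call. = FALSE)
  bits <- .minhash_bits(unique(x), params$L, params$hash_seed)
  structure(list(bits = bits, fingerprint = params$fingerprint),
            class = "cuf_signature")
}

#' @export
print.cuf_signature <- function(x, ...) {
  cat(sprintf("MinHash signature: %d bits (%s)\n  %s...\n",
              length(x$bits), x$fingerprint, signature_hex(x)))
  invisible(x)
}

#' Relative Hamming distance between two signatures
#'
#' Fraction of differing bits; 0 for identical signatures, expected 0.5
#' for signatures of unrelated inputs. Refuses to compare signatures
#' produced under different parameter fingerprints.
#'
#' @param s1,s2 \code{cuf_signature}s of equal length.
#' @return Score in [0, 1].
#' @export
relative_hamming <- function(s1, s2) {
  if (!identical(s1$fingerprint, s2$fingerprint))
    stop("signatures were produced under different parameters", call. = FALSE)
  if (length(s1$bits) != length(s2$bits))
    stop("signatures have different lengths", call. = FALSE)
  mean(s1$bits != s2$bits)
}

#' Serialize signatures as hex
#'
#' @param s a \code{cuf_signature} (bit length must be a multiple of 8).
#' @return \code{signature_hex} returns a hex string;
#'   \code{signature_from_hex} reconstructs the \code{cuf_signature}.
#' @export
signature_hex <- function(s) {
  bits <- s$bits
  stopifnot(length(bits) %% 8L == 0L)
  bytes <- vapply(seq_len(length(bits) / 8L), function(i) {
    sum(bits[(8L * i - 7L):(8L * i)] * 2L^(7:0))
  }, numeric(1))
  paste(sprintf("%02x", bytes), collapse = "")
}

#' @rdname signature_hex
#' @param hex hex string.
#' @param fingerprint parameter fingerprint to attach.
#' @export
signature_from_hex <- function(hex, fingerprint) {
  bytes <- strtoi(substring(hex, seq(1, nchar(hex), 2),
                            seq(2, nchar(hex), 2)), 16L)
  bits <- as.integer(unlist(lapply(bytes, function(b)
    as.integer(intToBits(b))[8:1])))
  structure(list(bits = bits, fingerprint = fingerprint),
            class = "cuf_signature")
}
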