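#' Filter reads on constant regions and extract output segments
#'
#' A read passes the filter iff both internal sequencing adapters match
#' their expected constant sequences at their designed coordinates with at
#' most \code{max_mismatch} substitutions each; the output segment between
#' them is then extracted and counted. Matching is positional (fixed
#' coordinates, substitution count): the noise model contains no indels,
#' so alignment is unnecessary. Reads shorter than the design simply fail
#' the filter.
#'
#' @param reads a \code{cuf_reads} (or character vector of reads).
#' @param design the \code{cuf_design} the reads were generated under.
#' @param max_mismatch maximum substitutions tolerated per adapter.
#' @return A \code{cuf_output_table}: counts per distinct output k-mer
#'   plus \code{n_total_reads} and \code{n_passing}.
#' @examples
#' d <- default_design(1)
#' p <- synthesize_masterpool(d, 50, seed = 3)
#' a <- select_amplify(p, challenge("", d), noise = noise_free())
#' r <- sequence_reads(a, 200, noise_free(), seed = 5)
#' filter_and_extract(r, d)
#' @export
filter_and_extract <- function(reads, design, max_mismatch = 2L) {
  stopifnot(max_mismatch >= 0L)
  rd <- if (inherits(reads, "cuf_reads")) reads$reads else reads
  n_total <- length(rd)
  long_enough <- nchar(rd) >= design$seq_length
  rd_ok <- rd[long_enough]
  pass <- mismatch_count(rd_ok, design, "adapter5") <= max_mismatch &
          mismatch_count(rd_ok, design, "adapter3") <= max_mismatch
  outputs <- segment_substr(rd_ok[pass], design, "output")
  counts <- table(outputs)
  structure(list(kmer = as.character(names(counts)),
                 count = as.integer(counts),
                 n_total_reads = n_total,
                 n_passing = sum(pass),
                 output_length = design$output_length),
            class = "cuf_output_table")
}

# Per-read substitution count against a constant segment at its designed
# coordinates (vectorized over equal-length reads).
mismatch_count <- function(reads, design, segment) {
  if (length(reads) == 0L) return(integer(0))
  expected <- strsplit(segment_sequence(design, segment), "", fixed = TRUE)[[1]]
  obs <- segment_substr(reads, design, segment)
  m <- matrix(unlist(strsplit(obs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(expected))
  as.integer(colSums(m != expected))
}

#' @export
print.cuf_output_table <- function(x, ...) {
  cat(sprintf("output table: %d distinct %d-mers, %d/%d reads passing\n",
              length(x$kmer), x$output_length, x$n_passing, x$n_total_reads))
  invisible(x)
}

#' Top output sequences by read count
#'
#' The most frequent output sequences of a response with absolute read
#' counts and relative frequencies -- the compact tabular view used to
#' eyeball reproducibility between responses. Ordered by descending
#' count, ties broken lexicographically.
#'
#' @param tab a \code{cuf_output_table}.
#' @param top_n number of rows to return.
#' @return A data.frame with columns \code{sequence}, \code{count},
#'   \code{frequency}.
#' @export
frequency_table <- function(tab, top_n = 10L) {
  stopifnot(top_n >= 1L)
  if (length(tab$kmer) == 0L)
    return(data.frame(sequence = character(0), count = integer(0),
                      frequency = numeric(0)))
  ord <- order(-tab$count, tab$kmer)
  ord <- head(ord, top_n)
  data.frame(sequence = tab$kmer[ord],
             count = tab$count[ord],
             frequency = tab$count[ord] / tab$n_passing,
             stringsAsFactors = FALSE)
}

#' Positional base content of a response
#'
#' Relative frequency of A, C, G and T at each of the output positions
#' across the whole read set, weighted by read counts. A selected
#' response shows visibly reduced positional randomness compared with
#' non-selectively read random DNA, whose rows all sit near 0.25.
#'
#' @param tab a non-empty \code{cuf_output_table}.
#' @return A positions x 4 matrix; every row sums to 1.
#' @export
positional_base_content <- function(tab) {
  if (length(tab$kmer) == 0L) stop("empty output table", call. = FALSE)
  len <- tab$output_length
  m <- matrix(unlist(strsplit(tab$kmer, "", fixed = TRUE), use.names = FALSE),
              nrow = len)
  out <- matrix(0, nrow = len, ncol = 4,
                dimnames = list(NULL, DNA_BASES))
  for (b in DNA_BASES)
    out[, b] <- as.vector((m == b) %*% tab$count)
  out / rowSums(out)
}

# Mean per-position Shannon entropy (bits) of the output positions;
# diagnostic for selection (selected responses sit well below the ~2 bits
# of an unselected random pool).
positional_entropy <- function(tab) {
  pbc <- positional_base_content(tab)
  ent <- -rowSums(ifelse(pbc > 0, pbc * log2(pbc), 0))
  mean(ent)
}

#' Write / read an output table as TSV
#'
#' @param tab a \code{cuf_output_table}.
#' @param path TSV path (columns \code{kmer}, \code{count}).
#' @return \code{read_output_table} returns a \code{cuf_output_table}.
#' @export
write_output_table <- function(tab, path) {
  utils::write.table(data.frame(kmer = tab$kmer, count = tab$count),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_output_table
#' @param n_total_reads total read count before filtering (defaults to the
#'   sum of counts, i.e., assumes every read passed).
#' @export
read_output_table <- function(path, n_total_reads = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer"))
  structure(list(kmer = df$kmer, count = df$count,
                 n_total_reads = if (is.null(n_total_reads)) sum(df$count)
                                 else n_total_reads,
                 n_passing = sum(df$count),
                 output_length = if (nrow(df)) nchar(df$kmer[1]) else 0L),
            class = "cuf_output_table")
}
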