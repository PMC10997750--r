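#' Default operable random DNA (orDNA) library design
#'
#' An orDNA template interleaves constant and random segments so that the
#' randomness laid down by synthesis stays addressable by PCR:
#' \preformatted{handle5 - input1 - adapter5 - output - adapter3 - input2 - handle3}
#' The two handles are constant outer PCR handles used to copy the whole
#' pool; the two adapters are constant sequencing adapters flanking the
#' random output segment; \code{input1} and \code{input2} are the random
#' segments that challenge primers select on. By default a template
#' carries 40 random nucleotides: a 21-nt output plus input segments of
#' 10 and 9 nt.
#'
#' Constant segment contents are generated pseudo-randomly from
#' \code{seed}, so the same seed always yields the identical design. They
#' are synthetic stand-ins: the pipeline is agnostic to the actual
#' constant sequences, only to their lengths and positions.
#'
#' @param seed integer seed determining the constant segment sequences.
#' @param output_length length (nt) of the random output segment.
#' @param input_lengths integer vector of length 2: lengths (nt) of the
#'   two random input segments.
#' @param handle_lengths integer vector of length 2: lengths of the 5' and
#'   3' outer handles.
#' @param adapter_lengths integer vector of length 2: lengths of the two
#'   internal sequencing adapters.
#' @return A \code{cuf_design} object: a list with the segment table
#'   (name, kind, length, sequence, 0-based half-open \code{start}/\code{end}
#'   coordinates on the full-length strand), \code{output_length},
#'   \code{input_lengths}, \code{total_random_nt} and \code{seq_length}.
#' @examples
#' d <- default_design(seed = 1)
#' d$total_random_nt   # 40
#' d$segments
#' @export
default_design <- function(seed = 1L,
                           output_length = 21L,
                           input_lengths = c(10L, 9L),
                           handle_lengths = c(20L, 20L),
                           adapter_lengths = c(18L, 18L)) {
  stopifnot(output_length >= 1L, length(input_lengths) == 2L,
            all(input_lengths >= 1L), all(handle_lengths >= 1L),
            all(adapter_lengths >= 1L))
  const_len <- c(handle_lengths[1], adapter_lengths[1],
                 adapter_lengths[2], handle_lengths[2])
  const_seq <- with_seed(seed, lapply(const_len, random_bases))
  segments <- data.frame(
    name = c("handle5", "input1", "adapter5", "output",
             "adapter3", "input2", "handle3"),
    kind = c("constant", "random", "constant", "random",
             "constant", "random", "constant"),
    length = as.integer(c(handle_lengths[1], input_lengths[1],
                          adapter_lengths[1], output_length,
                          adapter_lengths[2], input_lengths[2],
                          handle_lengths[2])),
    sequence = c(const_seq[[1]], NA, const_seq[[2]], NA,
                 const_seq[[3]], NA, const_seq[[4]]),
    stringsAsFactors = FALSE
  )
  new_design(segments)
}

# Assemble a cuf_design from a segment table, recomputing coordinates.
new_design <- function(segments) {
  stopifnot(identical(segments$kind[segments$name %in%
              c("input1", "output", "input2")], rep("random", 3L)))
  for (i in which(segments$kind == "constant")) {
    check_bases(segments$sequence[i], segments$name[i])
    stopifnot(nchar(segments$sequence[i]) == segments$length[i])
  }
  ends <- cumsum(segments$length)
  segments$start <- c(0L, ends[-length(ends)])
  segments$end <- as.integer(ends)
  d <- list(
    segments = segments,
    output_length = segments$length[segments$name == "output"],
    input_lengths = segments$length[segments$name %in% c("input1", "input2")],
    total_random_nt = sum(segments$length[segments$kind == "random"]),
    seq_length = sum(segments$length)
  )
  class(d) <- "cuf_design"
  d
}

#' @export
print.cuf_design <- function(x, ...) {
  cat("orDNA library design:", x$seq_length, "nt,",
      x$total_random_nt, "random nt (output", x$output_length,
      "nt, inputs", paste(x$input_lengths, collapse = "+"), "nt)\n")
  print(x$segments[, c("name", "kind", "length", "start", "end")],
        row.names = FALSE)
  invisible(x)
}

# 0-based half-open [start, end) coordinates of a named segment.
segment_coords <- function(design, name) {
  i <- match(name, design$segments$name)
  if (is.na(i)) stop("unknown segment: ", name, call. = FALSE)
  c(start = design$segments$start[i], end = design$segments$end[i])
}

segment_sequence <- function(design, name) {
  design$segments$sequence[match(name, design$segments$name)]
}

# Substring of full-length sequences covering a named segment
# (vectorized over `seqs`).
segment_substr <- function(seqs, design, name) {
  co <- segment_coords(design, name)
  substr(seqs, co["start"] + 1L, co["end"])
}

#' Construct a challenge (input base string)
#'
#' A challenge is an n-base input that is mapped to a primer pair and so
#' selects pool templates whose random input segments carry exactly those
#' bases. The first \code{split[1]} bases sit at the start of
#' \code{input1} (adjacent to the 5' handle) and the remaining
#' \code{split[2]} bases at the end of \code{input2} (adjacent to the 3'
#' handle), so that each primer stays contiguous with its constant flank.
#'
#' @param input_bases challenge string over A/C/G/T (forward strand).
#' @param design a \code{cuf_design}; used to validate lengths.
#' @param split integer vector \code{c(n_fw, n_rv)} allocating challenge
#'   bases to the forward/reverse primers; defaults to a balanced split
#'   (ceiling/floor of n/2) capped by the input segment lengths, so a
#'   13-base challenge splits 7 + 6.
#' @return A \code{cuf_challenge} object.
#' @examples
#' ch <- challenge("ACGTACGTACGTA", default_design(1))
#' ch$split   # 7 6
#' @export
challenge <- function(input_bases, design = default_design(), split = NULL) {
  check_bases(input_bases, "challenge")
  n <- nchar(input_bases)
  if (n > sum(design$input_lengths))
    stop("challenge length ", n, " exceeds the ",
         sum(design$input_lengths), " random input positions", call. = FALSE)
  if (is.null(split)) {
    n_fw <- min(ceiling(n / 2), design$input_lengths[1])
    split <- c(n_fw, n - n_fw)
  }
  split <- as.integer(split)
  if (length(split) != 2L || any(split < 0L) || sum(split) != n)
    stop("split must be two non-negative counts summing to nchar(input_bases)",
         call. = FALSE)
  if (split[1] > design$input_lengths[1] || split[2] > design$input_lengths[2])
    stop("split exceeds input segment lengths", call. = FALSE)
  structure(list(input_bases = input_bases, n = n, split = split),
            class = "cuf_challenge")
}

#' @export
print.cuf_challenge <- function(x, ...) {
  cat("challenge:", if (x$n) x$input_bases else "(empty)",
      sprintf("(n = %d, split %d + %d)\n", x$n, x$split[1], x$split[2]))
  invisible(x)
}

as_challenge <- function(x, design) {
  if (inherits(x, "cuf_challenge")) x else challenge(x, design)
}

#' Map a challenge to its selection-PCR primer pair
#'
#' The forward primer is the 3' end of the 5' handle (the constant flank)
#' followed by the first \code{split[1]} challenge bases; the reverse
#' primer is the reverse complement of the last \code{split[2]} challenge
#' bases together with the adjoining start of the 3' handle, reported in
#' its own 5'-to-3' orientation. Challenge bases are always specified on
#' the forward strand. The mapping is injective for a fixed n and split.
#'
#' @param ch a \code{cuf_challenge} (or challenge string).
#' @param design a \code{cuf_design}.
#' @param flank_nt constant-flank length (nt) incorporated into each primer.
#' @return A \code{cuf_primer_pair}: list with \code{fw} and \code{rv}.
#' @examples
#' d <- default_design(1)
#' challenge_to_primers(challenge("ACGTACGTACGTA", d), d)
#' @export
challenge_to_primers <- function(ch, design = default_design(),
                                 flank_nt = 10L) {
  ch <- as_challenge(ch, design)
  h5 <- segment_sequence(design, "handle5")
  h3 <- segment_sequence(design, "handle3")
  flank_fw <- substr(h5, nchar(h5) - min(flank_nt, nchar(h5)) + 1L, nchar(h5))
  flank_rv <- substr(h3, 1L, min(flank_nt, nchar(h3)))
  fw_bases <- substr(ch$input_bases, 1L, ch$split[1])
  rv_bases <- if (ch$split[2] > 0L)
    substr(ch$input_bases, ch$split[1] + 1L, ch$n) else ""
  pp <- list(fw = paste0(flank_fw, fw_bases),
             rv = revcomp(paste0(rv_bases, flank_rv)))
  class(pp) <- "cuf_primer_pair"
  pp
}

#' @export
print.cuf_primer_pair <- function(x, ...) {
  cat("fw:", x$fw, "\nrv:", x$rv, "\n")
  invisible(x)
}

#' Levenshtein distance between two challenges
#'
#' The edit distance between input base strings; challenges at distance 1
#' are the hardest discrimination cases for the readout, since a single
#' changed input base must flip the response from "same" to "different".
#'
#' @param c1,c2 \code{cuf_challenge} objects or challenge strings.
#' @return Integer edit distance; 0 iff the inputs are identical.
#' @examples
#' challenge_distance("ACGT", "ACTT")  # 1
#' @export
challenge_distance <- function(c1, c2) {
  s1 <- if (inherits(c1, "cuf_challenge")) c1$input_bases else c1
  s2 <- if (inherits(c2, "cuf_challenge")) c2$input_bases else c2
  as.integer(adist(s1, s2)[1, 1])
}

#' Write / read a library design as JSON
#'
#' Serializes the segment table (name, kind, length, sequence) so a design
#' can be shared between the simulator and the readout of real FASTQ data.
#'
#' @param design a \code{cuf_design}.
#' @param path file path.
#' @return \code{read_design} returns a \code{cuf_design};
#'   \code{write_design} returns \code{path} invisibly.
#' @export
write_design <- function(design, path) {
  jsonlite::write_json(
    design$segments[, c("name", "kind", "length", "sequence")],
    path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  seg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(seg$sequence)) seg$sequence <- NA_character_
  seg$sequence[!nzchar(seg$sequence) | is.na(seg$sequence)] <- NA
  new_design(as.data.frame(seg, stringsAsFactors = FALSE))
}
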