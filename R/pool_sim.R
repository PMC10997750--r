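#' Noise model for pool operation and sequencing
#'
#' Collects the stochastic imperfections of operating a DNA pool: PCR
#' copying substitutes bases at up to 2e-4 per base per duplication, which
#' over the effective number of doublings accumulates into a per-base
#' substitution probability; sequencing adds its own per-base error; and a
#' small fraction of reads derives from off-target amplification of
#' non-matching templates. PCR mutations are not materialized into the
#' pool (at ~16,000 copies per sequence that would be prohibitive);
#' instead they are folded into the per-read error rate at sequencing
#' time, which preserves the observable mutant-read fraction:
#' \deqn{p_{err} = 1 - (1 - \mu)^{c} + e_{seq}}
#'
#' @param pcr_mut_rate per-base substitution probability per duplication.
#' @param effective_doublings effective number of PCR doublings a molecule
#'   undergoes between pool and flow cell.
#' @param seq_err_rate per-base sequencing substitution probability.
#' @param offtarget_fraction probability that a read derives from a
#'   non-matching template.
#' @return A \code{cuf_noise} object.
#' @examples
#' noise_model()                 # defaults
#' read_error_rate(noise_model())  # ~0.006
#' noise_free()
#' @export
noise_model <- function(pcr_mut_rate = 2e-4,
                        effective_doublings = 25L,
                        seq_err_rate = 1e-3,
                        offtarget_fraction = 0.01) {
  stopifnot(pcr_mut_rate >= 0, pcr_mut_rate <= 1,
            effective_doublings >= 0,
            seq_err_rate >= 0, seq_err_rate <= 1,
            offtarget_fraction >= 0, offtarget_fraction <= 1)
  structure(list(pcr_mut_rate = pcr_mut_rate,
                 effective_doublings = as.integer(effective_doublings),
                 seq_err_rate = seq_err_rate,
                 offtarget_fraction = offtarget_fraction),
            class = "cuf_noise")
}

#' @rdname noise_model
#' @export
noise_free <- function() {
  noise_model(pcr_mut_rate = 0, effective_doublings = 0L,
              seq_err_rate = 0, offtarget_fraction = 0)
}

#' @rdname noise_model
#' @param noise a \code{cuf_noise} object.
#' @export
read_error_rate <- function(noise) {
  1 - (1 - noise$pcr_mut_rate)^noise$effective_doublings + noise$seq_err_rate
}

new_pool <- function(seq, count, state, design) {
  structure(list(seq = seq, count = as.numeric(count),
                 state = state, design = design),
            class = "cuf_pool")
}

#' @export
print.cuf_pool <- function(x, ...) {
  cat(sprintf("CUF pool: %d unique sequences, %s state, mean copy count %.1f\n",
              length(x$seq), x$state, mean(x$count)))
  invisible(x)
}

stop_state <- function() {
  stop(errorCondition(
    paste("global amplification disabled: pool is in the uncopiable state;",
          "selection PCR (select_amplify) remains possible"),
    class = "cuf_state_error"))
}

#' Synthesize an orDNA masterpool
#'
#' Emulates combined sequence-determined and random solid-phase synthesis:
#' constant segments are fixed by the design and every random position is
#' drawn i.i.d. uniformly over A/C/G/T. Each of the \code{n_unique}
#' single-stranded products starts with copy count 1 and the pool is in
#' the copiable state.
#'
#' Real masterpools reach ~6e16 unique strands; materializing sequences
#' caps at \code{cap} (default 1e7) -- the larger scales are handled
#' analytically by [capacity_report()] and by scaled-down experiments.
#'
#' @param design a \code{cuf_design}.
#' @param n_unique number of unique sequences to synthesize.
#' @param seed integer seed.
#' @param cap materialization cap on \code{n_unique}.
#' @return A \code{cuf_pool}.
#' @examples
#' p <- synthesize_masterpool(default_design(1), 100, seed = 7)
#' @export
synthesize_masterpool <- function(design, n_unique, seed, cap = 1e7) {
  if (n_unique < 1) stop("n_unique must be >= 1", call. = FALSE)
  if (n_unique > cap)
    stop("n_unique exceeds the materialization cap (", format(cap, scientific = TRUE),
         "); pools at this scale are analyzed with capacity_report() and ",
         "expected_match_count() rather than materialized", call. = FALSE)
  n_unique <- as.integer(n_unique)
  nrand <- design$total_random_nt
  rand_mat <- with_seed(seed, matrix(
    sample(DNA_BASES, n_unique * nrand, replace = TRUE),
    nrow = n_unique))
  # collapse per-segment random blocks, then interleave with constants
  seg <- design$segments
  pieces <- vector("list", nrow(seg))
  off <- 0L
  for (i in seq_len(nrow(seg))) {
    if (seg$kind[i] == "constant") {
      pieces[[i]] <- seg$sequence[i]
    } else {
      cols <- (off + 1L):(off + seg$length[i])
      pieces[[i]] <- do.call(paste0, as.data.frame(rand_mat[, cols, drop = FALSE]))
      off <- off + seg$length[i]
    }
  }
  seqs <- do.call(paste0, pieces)
  new_pool(seqs, rep(1, n_unique), "copiable", design)
}

#' Draw a subpool by urn sampling without replacement
#'
#' Picking an aliquot from the masterpool is an additional random process:
#' \code{n} unique sequences are drawn without replacement, so even an
#' actor holding the masterpool cannot re-create a given subpool. The
#' drawn sequences keep their copy counts.
#'
#' @param pool a copiable \code{cuf_pool}.
#' @param n number of unique sequences to draw.
#' @param seed integer seed.
#' @return A \code{cuf_pool} whose sequences are a subset of \code{pool}'s.
#' @export
sample_subpool <- function(pool, n, seed) {
  if (pool$state != "copiable") stop_state()
  if (n > length(pool$seq))
    stop("cannot draw ", n, " unique sequences from a pool of ",
         length(pool$seq), call. = FALSE)
  idx <- with_seed(seed, sample.int(length(pool$seq), n))
  new_pool(pool$seq[idx], pool$count[idx], pool$state, pool$design)
}

#' Amplify a pool with the outer handles
#'
#' Global PCR over the constant handles multiplies every template's copy
#' count by a positive random gain with the requested mean (lognormal,
#' shape sigma = 0.5), reproducing the unequal-draw stochasticity caused
#' by the limited copy number of unique sequences. The unique-sequence set
#' is preserved; PCR substitutions are deferred to read generation (see
#' [noise_model()]). Amplification is refused for pools in the uncopiable
#' state -- that refusal is the unclonability contract of the locked pool.
#'
#' @param pool a copiable \code{cuf_pool}.
#' @param mean_copies mean per-template copy-number gain (a typical
#'   pool-generation PCR yields ~16,000 copies per sampled sequence).
#' @param noise a \code{cuf_noise} (carried for interface symmetry; the
#'   substitution load is applied at sequencing).
#' @param seed integer seed.
#' @param sigma lognormal shape of the per-template gain.
#' @return A \code{cuf_pool} with scaled copy counts.
#' @export
amplify_pool <- function(pool, mean_copies = 16000, noise = noise_model(),
                         seed = 1L, sigma = 0.5) {
  if (pool$state != "copiable") stop_state()
  stopifnot(mean_copies > 0)
  gain <- with_seed(seed, rlnorm(length(pool$seq),
                                 meanlog = log(mean_copies) - sigma^2 / 2,
                                 sdlog = sigma))
  # copy counts stay continuous: they act only as relative abundances in
  # later multinomial draws, and rounding would bias small gains upward
  new_pool(pool$seq, pool$count * gain, pool$state, pool$design)
}

#' Proliferate a pool into daughter generations
#'
#' Serial amplification in which each generation uses the product of the
#' previous one as its template, producing daughter pools P1..Pn that
#' share the identical unique-sequence set. Responses of daughter
#' generations to the same challenge should classify as "same".
#'
#' @inheritParams amplify_pool
#' @param generations number of daughter generations.
#' @return A list of \code{cuf_pool} objects of length \code{generations}.
#' @export
proliferate <- function(pool, generations, mean_copies = 200,
                        noise = noise_model(), seed = 1L) {
  stopifnot(generations >= 1)
  seeds <- derive_seeds(seed, generations)
  out <- vector("list", generations)
  cur <- pool
  for (g in seq_len(generations)) {
    cur <- amplify_pool(cur, mean_copies, noise, seeds[g])
    out[[g]] <- cur
  }
  names(out) <- paste0("P", seq_len(generations))
  out
}

#' Lock a pool into the uncopiable state
#'
#' Models the irreversible removal of the outer amplification handles
#' (restriction digest followed by dideoxy blunting of the ends): the
#' handles are truncated to 7 residual defined bases on the 5' side and 6
#' on the 3' side, and the pool state flips to uncopiable. Selection PCR
#' on the inner input regions ([select_amplify()]) still works, so the
#' function can still be operated, but [amplify_pool()],
#' [proliferate()] and [sample_subpool()] are refused: the pool can no
#' longer be copied as a whole.
#'
#' @param pool a \code{cuf_pool}.
#' @param residual_nt defined bases left of the 5' and 3' handles.
#' @return The locked \code{cuf_pool} (unchanged, with a warning, if it
#'   was already uncopiable).
#' @export
make_uncopiable <- function(pool, residual_nt = c(7L, 6L)) {
  if (pool$state == "uncopiable") {
    warning("pool is already uncopiable; returned unchanged")
    return(pool)
  }
  seg <- pool$design$segments
  h5 <- which(seg$name == "handle5")
  h3 <- which(seg$name == "handle3")
  stopifnot(residual_nt[1] <= seg$length[h5], residual_nt[2] <= seg$length[h3])
  cut5 <- seg$length[h5] - residual_nt[1]
  cut3 <- seg$length[h3] - residual_nt[2]
  seqs <- substr(pool$seq, cut5 + 1L, nchar(pool$seq) - cut3)
  seg$sequence[h5] <- substr(seg$sequence[h5], cut5 + 1L, seg$length[h5])
  seg$length[h5] <- as.integer(residual_nt[1])
  seg$sequence[h3] <- substr(seg$sequence[h3], 1L, residual_nt[2])
  seg$length[h3] <- as.integer(residual_nt[2])
  new_pool(seqs, pool$count, "uncopiable", new_design(seg))
}

#' Selection PCR: operate the pool with a challenge
#'
#' The primer pair encoded by the challenge favorably binds templates
#' whose random input positions carry exactly the challenged bases;
#' exponential amplification then lifts them above the background.
#' Matching templates receive weight proportional to their copy counts,
#' scaled by \code{1 - offtarget_fraction}; all other templates share the
#' off-target fraction, again proportionally to copy counts. Weights are
#' normalized to sum to 1. Works in both the copiable and the uncopiable
#' state (only the inner regions are primed).
#'
#' @param pool a \code{cuf_pool}.
#' @param ch a \code{cuf_challenge} or challenge string.
#' @param design design override (defaults to the pool's own design).
#' @param noise a \code{cuf_noise}; only \code{offtarget_fraction} acts here.
#' @param seed accepted for interface symmetry; selection weights are a
#'   deterministic function of the pool and challenge.
#' @return A \code{cuf_amplicon}: sequences, normalized weights, the
#'   challenge and design, plus the matching-template count
#'   (\code{n_matching}).
#' @export
select_amplify <- function(pool, ch, design = pool$design,
                           noise = noise_model(), seed = NULL) {
  ch <- as_challenge(ch, design)
  match <- matching_templates(pool$seq, ch, design)
  n_match <- sum(match)
  off <- noise$offtarget_fraction
  if (n_match == 0L && off == 0)
    stop(errorCondition(
      paste("no template matches the challenge and off-target amplification",
            "is disabled: empty response. The expected number of matches is",
            "pool_size / 4^n (see expected_match_count())"),
      class = "cuf_empty_response"))
  w <- numeric(length(pool$seq))
  target_share <- if (n_match > 0L) 1 - off else 0
  if (n_match > 0L)
    w[match] <- target_share * pool$count[match] / sum(pool$count[match])
  if (off > 0 && n_match < length(pool$seq)) {
    bg_share <- if (n_match > 0L) off else 1
    w[!match] <- bg_share * pool$count[!match] / sum(pool$count[!match])
  }
  keep <- w > 0
  structure(list(seq = pool$seq[keep], weight = w[keep] / sum(w[keep]),
                 challenge = ch, design = design, n_matching = n_match),
            class = "cuf_amplicon")
}

# Logical vector: which full-length sequences match all challenged bases
# (prefix of input1, suffix of input2, per the challenge split).
matching_templates <- function(seqs, ch, design) {
  if (ch$n == 0L) return(rep(TRUE, length(seqs)))
  ok <- rep(TRUE, length(seqs))
  if (ch$split[1] > 0L) {
    co <- segment_coords(design, "input1")
    want <- substr(ch$input_bases, 1L, ch$split[1])
    ok <- substr(seqs, co["start"] + 1L, co["start"] + ch$split[1]) == want
  }
  if (ch$split[2] > 0L) {
    co <- segment_coords(design, "input2")
    want <- substr(ch$input_bases, ch$split[1] + 1L, ch$n)
    ok <- ok & substr(seqs, co["end"] - ch$split[2] + 1L, co["end"]) == want
  }
  ok
}

#' @export
print.cuf_amplicon <- function(x, ...) {
  cat(sprintf("amplicon pool: %d templates with weight (%d matching), challenge %s\n",
              length(x$seq), x$n_matching, x$challenge$input_bases))
  invisible(x)
}

#' Sequence an amplicon pool at finite depth
#'
#' Draws \code{depth} reads multinomially from the amplicon weights and
#' applies the accumulated per-base substitution load
#' \code{p_err = 1 - (1 - pcr_mut_rate)^effective_doublings + seq_err_rate}
#' (substitution to a uniformly chosen different base). Reads span the
#' full amplicon length on the forward strand.
#'
#' @param amplicon a \code{cuf_amplicon}.
#' @param depth number of reads.
#' @param noise a \code{cuf_noise}.
#' @param seed integer seed.
#' @return A \code{cuf_reads}: character vector of reads plus provenance
#'   (seed, depth, error rate).
#' @export
sequence_reads <- function(amplicon, depth, noise = noise_model(), seed = 1L) {
  stopifnot(depth >= 1)
  if (length(amplicon$seq) == 0L) stop("empty amplicon pool", call. = FALSE)
  depth <- as.integer(depth)
  p_err <- read_error_rate(noise)
  reads <- with_seed(seed, {
    counts <- as.vector(rmultinom(1, depth, amplicon$weight))
    nz <- counts > 0L
    templ <- rep(amplicon$seq[nz], counts[nz])
    if (p_err > 0) mutate_reads(templ, p_err) else templ
  })
  structure(list(reads = reads,
                 provenance = list(seed = seed, depth = depth, p_err = p_err)),
            class = "cuf_reads")
}

# Apply i.i.d. per-base substitutions (to a uniform different base) to a
# character vector of equal-length reads.
mutate_reads <- function(reads, p_err) {
  if (length(reads) == 0L) return(reads)
  len <- nchar(reads[1])
  m <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
              nrow = len)
  hit <- which(runif(length(m)) < p_err)
  if (length(hit)) {
    # uniform among the three other bases
    cur <- m[hit]
    repl <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L), "",
                   USE.NAMES = FALSE)
    m[hit] <- repl
  }
  apply(m, 2, paste0, collapse = "")
}

#' @export
print.cuf_reads <- function(x, ...) {
  cat(sprintf("read set: %d reads of %d nt (p_err = %.4g, seed %s)\n",
              length(x$reads), if (length(x$reads)) nchar(x$reads[1]) else 0L,
              x$provenance$p_err, x$provenance$seed))
  invisible(x)
}

#' Write / read a read set as FASTQ
#'
#' Reads carry a constant placeholder quality (the simulator does not
#' model per-base quality); FASTQ I/O goes through Biostrings.
#'
#' @param reads a \code{cuf_reads}.
#' @param path FASTQ file path.
#' @param quality_char constant quality character written for every base.
#' @return \code{read_reads_fastq} returns a \code{cuf_reads};
#'   \code{write_reads_fastq} returns \code{path} invisibly.
#' @export
write_reads_fastq <- function(reads, path, quality_char = "I") {
  x <- Biostrings::DNAStringSet(reads$reads)
  names(x) <- sprintf("read%06d", seq_along(x))
  quals <- Biostrings::BStringSet(strrep(quality_char, nchar(reads$reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  structure(list(reads = as.character(unname(x)),
                 provenance = list(seed = NA, depth = length(x), p_err = NA)),
            class = "cuf_reads")
}

#' Write / read a pool as JSON
#'
#' Serializes sequences, copy counts, state and the design in one JSON
#' document (suited to the materialized desk-scale pools).
#'
#' @param pool a \code{cuf_pool}.
#' @param path file path.
#' @return \code{read_pool} returns a \code{cuf_pool}.
#' @export
write_pool <- function(pool, path) {
  jsonlite::write_json(
    list(state = pool$state,
         design = pool$design$segments[, c("name", "kind", "length", "sequence")],
         entries = data.frame(seq = pool$seq, count = pool$count)),
    path, auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- x$design
  seg$sequence[!nzchar(seg$sequence) | is.na(seg$sequence)] <- NA
  new_pool(x$entries$seq, x$entries$count, x$state,
           new_design(as.data.frame(seg, stringsAsFactors = FALSE)))
}
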