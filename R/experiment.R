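#' Operate a pool once: challenge, sequence, filter
#'
#' Convenience wrapper running one full challenge-response operation:
#' selection PCR, finite-depth sequencing, and constant-region filtering
#' with output extraction.
#'
#' @param pool a \code{cuf_pool}.
#' @param ch a \code{cuf_challenge} or challenge string.
#' @param depth sequencing depth (reads).
#' @param noise a \code{cuf_noise}.
#' @param seed integer seed for sequencing.
#' @param max_mismatch adapter filter stringency.
#' @return A \code{cuf_output_table} (the response).
#' @export
operate <- function(pool, ch, depth = 2e4, noise = noise_model(), seed = 1L,
                    max_mismatch = 2L) {
  amp <- select_amplify(pool, ch, noise = noise)
  rd <- sequence_reads(amp, depth, noise, seed)
  filter_and_extract(rd, pool$design, max_mismatch)
}

# Challenge string read off an existing pool template, so that at least
# one perfect match is guaranteed. Uses the default balanced split.
template_challenge <- function(pool, idx, n) {
  d <- pool$design
  n_fw <- min(ceiling(n / 2), d$input_lengths[1])
  n_rv <- n - n_fw
  i1 <- segment_substr(pool$seq[idx], d, "input1")
  i2 <- segment_substr(pool$seq[idx], d, "input2")
  paste0(substr(i1, 1L, n_fw),
         if (n_rv > 0L) substr(i2, nchar(i2) - n_rv + 1L, nchar(i2)) else "")
}

# Substitute one base of a challenge string (Levenshtein distance 1).
mutate_challenge <- function(input, pos = 1L) {
  b <- substr(input, pos, pos)
  repl <- setdiff(DNA_BASES, b)[1]
  paste0(substr(input, 1L, pos - 1L), repl,
         substr(input, pos + 1L, nchar(input)))
}

#' Build an experiment plan
#'
#' A plan is one challenge string per planned response; repeated strings
#' are replicate operations of the same challenge ("like" pairs), distinct
#' strings are "unlike" pairs. The truth matrix is symmetric with a
#' "same" diagonal.
#'
#' @param inputs character vector of challenge strings, one per response.
#' @return A \code{cuf_plan}: the response table and truth matrix.
#' @export
experiment_plan <- function(inputs) {
  stopifnot(length(inputs) >= 2L)
  truth <- outer(inputs, inputs,
                 function(a, b) ifelse(a == b, "same", "different"))
  ids <- make.unique(paste0("r", seq_along(inputs)))
  dimnames(truth) <- list(ids, ids)
  structure(list(table = data.frame(id = ids, input = inputs,
                                    stringsAsFactors = FALSE),
                 truth = truth),
            class = "cuf_plan")
}

#' @export
print.cuf_plan <- function(x, ...) {
  same <- sum(x$truth[upper.tri(x$truth)] == "same")
  tot <- sum(upper.tri(x$truth))
  cat(sprintf("experiment plan: %d responses over %d challenges; %d like / %d unlike pairs\n",
              nrow(x$table), length(unique(x$table$input)), same, tot - same))
  invisible(x)
}

#' Plan a like/unlike similarity assessment
#'
#' Builds a plan of replicated and distinct challenges against one pool,
#' mirroring the structure of a full similarity assessment: challenges
#' are read off pool templates (so each has at least one perfect match),
#' some challenges are replicated (like pairs), and part of the
#' singletons are Levenshtein-distance-1 neighbours of the replicated
#' challenges -- the hardest discrimination cases. The default geometry
#' (replicate groups 9, 5, 5, 3, 2, 2 plus 13 singletons = 39 responses)
#' yields 61 like and 680 unlike comparisons among the 741 pairs.
#'
#' @param pool a \code{cuf_pool}.
#' @param n_input challenge length in bases.
#' @param group_sizes replicate count per replicated challenge.
#' @param n_singletons challenges run only once.
#' @param n_dl1 how many singletons are distance-1 mutants of replicated
#'   challenges (capped at \code{min(n_singletons, length(group_sizes))}).
#' @param seed integer seed for template picks.
#' @return A \code{cuf_plan}.
#' @export
similarity_plan <- function(pool, n_input = 8L,
                            group_sizes = c(9L, 5L, 5L, 3L, 2L, 2L),
                            n_singletons = 13L, n_dl1 = 4L, seed = 1L) {
  n_groups <- length(group_sizes)
  n_dl1 <- min(n_dl1, n_singletons, n_groups)
  n_pick <- n_groups + (n_singletons - n_dl1)
  idx <- with_seed(seed, sample.int(length(pool$seq), n_pick))
  picked <- unique(template_challenge(pool, idx, n_input))
  while (length(picked) < n_pick) {   # regenerate on (unlikely) collisions
    seed <- seed + 1L
    idx <- with_seed(seed, sample.int(length(pool$seq), n_pick))
    picked <- unique(template_challenge(pool, idx, n_input))
  }
  group_ch <- picked[seq_len(n_groups)]
  singles <- picked[-seq_len(n_groups)]
  dl1 <- vapply(seq_len(n_dl1),
                function(i) mutate_challenge(group_ch[i], pos = i),
                "")
  experiment_plan(c(rep(group_ch, times = group_sizes), singles, dl1))
}

#' Run an experiment plan end to end
#'
#' Operates every planned response on the pool (selection PCR, sequencing
#' at the given depth, filtering), extracts k-mer profiles and MinHash
#' signatures, and compares all response pairs: weighted Jaccard
#' similarity, relative Hamming distance between signatures, and the
#' fuzzy-extractor same/different verdict. Accuracy is the fraction of
#' off-diagonal verdicts agreeing with the plan's truth matrix.
#'
#' @param pool a \code{cuf_pool}.
#' @param plan a \code{cuf_plan}.
#' @param noise a \code{cuf_noise}.
#' @param depth sequencing depth per response.
#' @param sig_params a \code{cuf_sig_params}.
#' @param fe a \code{cuf_fe_params}.
#' @param seed master seed; per-response sequencing seeds and enrollment
#'   seeds are derived substreams.
#' @param max_mismatch adapter filter stringency.
#' @return A \code{cuf_experiment}: matrices \code{similarity},
#'   \code{hamming}, \code{verdict}, \code{truth}; scalar
#'   \code{accuracy}; and per-class pair summaries \code{like} /
#'   \code{unlike} (Jaccard and Hamming values).
#' @export
run_experiment <- function(pool, plan, noise = noise_model(), depth = 2e4,
                           sig_params = signature_params(),
                           fe = fe_params(), seed = 1L, max_mismatch = 2L) {
  tab <- plan$table
  nr <- nrow(tab)
  seeds <- derive_seeds(seed, 2L * nr)
  profiles <- vector("list", nr)
  sigs <- vector("list", nr)
  for (i in seq_len(nr)) {
    ot <- operate(pool, tab$input[i], depth, noise, seeds[i], max_mismatch)
    profiles[[i]] <- extract_kmers(ot, sig_params)
    sigs[[i]] <- minhash_signature(profiles[[i]], sig_params)
  }
  sim <- matrix(1, nr, nr, dimnames = dimnames(plan$truth))
  ham <- matrix(0, nr, nr, dimnames = dimnames(plan$truth))
  verdict <- matrix("same", nr, nr, dimnames = dimnames(plan$truth))
  for (i in seq_len(nr - 1L)) {
    for (j in (i + 1L):nr) {
      sim[i, j] <- sim[j, i] <- weighted_jaccard(profiles[[i]], profiles[[j]])
      ham[i, j] <- ham[j, i] <- relative_hamming(sigs[[i]], sigs[[j]])
      v <- classify_pair(sigs[[i]], sigs[[j]], fe, seeds[nr + i])
      verdict[i, j] <- verdict[j, i] <- v
    }
  }
  ut <- upper.tri(sim)
  is_like <- plan$truth[ut] == "same"
  structure(list(
    similarity = sim, hamming = ham, verdict = verdict, truth = plan$truth,
    accuracy = mean(verdict[ut] == plan$truth[ut]),
    like = list(n = sum(is_like), jaccard = sim[ut][is_like],
                hamming = ham[ut][is_like]),
    unlike = list(n = sum(!is_like), jaccard = sim[ut][!is_like],
                  hamming = ham[ut][!is_like]),
    signatures = sigs
  ), class = "cuf_experiment")
}

#' @export
print.cuf_experiment <- function(x, ...) {
  cat(sprintf(paste0(
    "CUF experiment: %d responses, %d like / %d unlike pairs\n",
    "  accuracy vs truth: %.4f\n",
    "  like   pairs: Jaccard [%.3f, %.3f], rel. Hamming mean %.3f\n",
    "  unlike pairs: Jaccard [%.3f, %.3f], rel. Hamming mean %.3f\n"),
    nrow(x$similarity), x$like$n, x$unlike$n, x$accuracy,
    min(x$like$jaccard), max(x$like$jaccard), mean(x$like$hamming),
    min(x$unlike$jaccard), max(x$unlike$jaccard), mean(x$unlike$hamming)))
  invisible(x)
}
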