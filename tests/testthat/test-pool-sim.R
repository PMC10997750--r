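test_that("masterpool synthesis is uniform, complete and deterministic", {
  d <- default_design(1)
  p <- synthesize_masterpool(d, 1000, seed = 7)
  expect_equal(length(p$seq), 1000L)
  expect_true(all(p$count == 1))
  expect_equal(p$state, "copiable")
  expect_true(all(nchar(p$seq) == d$seq_length))
  # constant segments fixed, random segments present
  expect_equal(unique(cufsim:::segment_substr(p$seq, d, "adapter5")),
               d$segments$sequence[3])
  expect_identical(synthesize_masterpool(d, 1000, seed = 7)$seq, p$seq)
  expect_false(identical(synthesize_masterpool(d, 1000, seed = 8)$seq, p$seq))
  expect_error(synthesize_masterpool(d, 1e9, seed = 1), "cap")
})

test_that("random positions are i.i.d. uniform over the four bases", {
  d <- default_design(1)
  p <- synthesize_masterpool(d, 1e5, seed = 19)
  out <- cufsim:::segment_substr(p$seq, d, "output")
  # fraction of A at a fixed random position: 0.25 within a binomial bound
  first <- substr(out, 1, 1)
  expect_equal(mean(first == "A"), 0.25, tolerance = 0.04)  # ~0.01 absolute
  counts <- table(substr(out, 7, 7))
  expect_equal(as.numeric(counts / sum(counts)), rep(0.25, 4),
               tolerance = 0.04)
})

test_that("subpool sampling is without replacement and conserves entries", {
  d <- default_design(1)
  p <- synthesize_masterpool(d, 1000, seed = 1)
  s <- sample_subpool(p, 100, seed = 2)
  expect_equal(length(s$seq), 100L)
  expect_true(all(s$seq %in% p$seq))
  expect_equal(anyDuplicated(s$seq), 0L)
  expect_setequal(sample_subpool(p, 1000, seed = 3)$seq, p$seq)
  expect_equal(length(sample_subpool(p, 1, seed = 4)$seq), 1L)
  expect_error(sample_subpool(p, 2000, seed = 5), "cannot draw")

  # two independent 100-draws from 1000 overlap ~10 in expectation
  overlaps <- vapply(1:40, function(i) {
    a <- sample_subpool(p, 100, seed = 100 + i)$seq
    b <- sample_subpool(p, 100, seed = 900 + i)$seq
    length(intersect(a, b))
  }, numeric(1))
  se <- sd(overlaps) / sqrt(length(overlaps))
  expect_lt(abs(mean(overlaps) - 10), 3 * se + 1e-9)
})

test_that("amplification multiplies copy counts with the stated mean gain", {
  d <- default_design(1)
  p <- synthesize_masterpool(d, 400, seed = 1)
  means <- vapply(1:10, function(i)
    mean(amplify_pool(p, 16000, seed = i)$count), numeric(1))
  expect_equal(mean(means), 16000, tolerance = 0.05)
  expect_setequal(amplify_pool(p, 16000, seed = 1)$seq, p$seq)
  # mean gain 1: counts unchanged in expectation
  expect_equal(mean(amplify_pool(p, 1, seed = 2)$count), 1, tolerance = 0.15)
})

test_that("proliferation chains amplifications and preserves the sequence set", {
  d <- default_design(1)
  p <- synthesize_masterpool(d, 200, seed = 5)
  gens <- proliferate(p, 5, mean_copies = 20, seed = 9)
  expect_length(gens, 5L)
  expect_named(gens, paste0("P", 1:5))
  for (g in gens) expect_setequal(g$seq, p$seq)
  # copy counts grow along the chain
  expect_gt(mean(gens[[5]]$count), mean(gens[[1]]$count))
  # one generation equals a single amplify_pool with the same substream seed
  g1 <- proliferate(p, 1, mean_copies = 20, seed = 9)[[1]]
  expect_identical(g1$count,
                   amplify_pool(p, 20, seed = cufsim:::derive_seeds(9, 1))$count)
})

test_that("the uncopiable state truncates handles and blocks global PCR", {
  d <- default_design(1)
  p <- synthesize_masterpool(d, 300, seed = 2)
  locked <- make_uncopiable(p)
  expect_equal(locked$state, "uncopiable")
  seg <- locked$design$segments
  expect_equal(seg$length[seg$name == "handle5"], 7L)
  expect_equal(seg$length[seg$name == "handle3"], 6L)
  expect_equal(nchar(locked$seq[1]), d$seq_length - (20 - 7) - (20 - 6))

  expect_error(amplify_pool(locked, 100, seed = 1), class = "cuf_state_error")
  expect_error(sample_subpool(locked, 10, seed = 1), class = "cuf_state_error")
  expect_warning(again <- make_uncopiable(locked), "already")
  expect_identical(again, locked)

  # operation is still possible in the locked state
  ch <- cufsim:::template_challenge(locked, 1, 4)
  amp <- select_amplify(locked, ch, noise = noise_free())
  expect_gt(amp$n_matching, 0)
  ot <- filter_and_extract(sequence_reads(amp, 100, noise_free(), 1),
                           locked$design)
  expect_gt(ot$n_passing, 0)
})

test_that("selection PCR weights match copy counts and the off-target split", {
  d <- default_design(1)
  rand <- cbind(c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG"),
                c(strrep("ACGTACG", 3), strrep("TGCATGC", 3), strrep("GGGCCCA", 3)),
                c("TTTTTTTTT", "AAAAAAAAA", "CCCCCCCCC"))
  p <- make_pool(d, rand, counts = c(3, 1, 1))

  # single perfect match, no off-target: weight 1
  amp <- select_amplify(p, challenge("AATT", d), noise = noise_free())
  expect_equal(amp$n_matching, 1L)
  expect_equal(amp$weight, 1)
  expect_equal(cufsim:::segment_substr(amp$seq, d, "input1"), "AAAAAAAAAA")

  # off-target fraction shared among non-matching templates by copy count
  amp2 <- select_amplify(p, challenge("AATT", d),
                         noise = noise_model(offtarget_fraction = 0.1))
  expect_equal(sum(amp2$weight), 1)
  expect_equal(amp2$weight[match(p$seq[1], amp2$seq)], 0.9)
  expect_equal(amp2$weight[match(p$seq[2], amp2$seq)], 0.05)

  # no match and no off-target: empty-response error
  expect_error(select_amplify(p, challenge("GGGG", d), noise = noise_free()),
               class = "cuf_empty_response")
  # no match but off-target on: background-only response
  amp3 <- select_amplify(p, challenge("GGGG", d),
                         noise = noise_model(offtarget_fraction = 0.01))
  expect_equal(amp3$n_matching, 0L)
  expect_equal(sum(amp3$weight), 1)
})

test_that("distance-1 challenges select disjoint template sets", {
  d <- default_design(1)
  p <- synthesize_masterpool(d, 4000, seed = 13)
  ch <- cufsim:::template_challenge(p, 1, 4)
  for (pos in 1:4) {
    ch2 <- cufsim:::mutate_challenge(ch, pos)
    m1 <- cufsim:::matching_templates(p$seq, challenge(ch, d), d)
    m2 <- cufsim:::matching_templates(p$seq, challenge(ch2, d), d)
    expect_false(any(m1 & m2))
  }
})

test_that("matching-template counts follow Binomial(N, 4^-n)", {
  d <- default_design(1)
  n_in <- 3L
  N <- 2000L
  counts <- vapply(1:200, function(i) {
    p <- synthesize_masterpool(d, N, seed = 5000 + i)
    sum(cufsim:::matching_templates(p$seq, challenge("ACG", d), d))
  }, numeric(1))
  expected <- N / 4^n_in
  se <- sqrt(expected * (1 - 4^-n_in) / length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("sequencing conserves depth and reproduces the closed-form error rate", {
  d <- default_design(1)
  p <- synthesize_masterpool(d, 50, seed = 3)
  ch <- cufsim:::template_challenge(p, 5, 6)
  amp <- select_amplify(p, ch, noise = noise_free())

  # all-zero noise, single amplicon: depth identical reads
  r0 <- sequence_reads(amp, 25, noise_free(), seed = 1)
  expect_length(r0$reads, 25L)
  expect_equal(length(unique(r0$reads)), 1L)

  nm <- noise_model()
  r <- sequence_reads(amp, 1e4, nm, seed = 2)
  expect_length(r$reads, 10000L)
  template <- amp$seq[which.max(amp$weight)]
  tchars <- strsplit(template, "")[[1]]
  mm <- vapply(strsplit(r$reads, ""), function(x) sum(x != tchars), numeric(1))
  p_err <- 1 - (1 - 2e-4)^25 + 1e-3
  expect_equal(read_error_rate(nm), p_err)
  total_bases <- 1e4 * nchar(template)
  ci <- 3 * sqrt(p_err * (1 - p_err) / total_bases)
  expect_lt(abs(mean(mm) / nchar(template) - p_err), ci)
})

test_that("reads survive a FASTQ round trip", {
  d <- default_design(1)
  p <- synthesize_masterpool(d, 20, seed = 4)
  amp <- select_amplify(p, challenge("", d), noise = noise_free())
  r <- sequence_reads(amp, 50, noise_model(), seed = 6)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(r, path)
  r2 <- read_reads_fastq(path)
  expect_identical(r2$reads, r$reads)
})

test_that("pools survive a JSON round trip", {
  d <- default_design(2)
  p <- synthesize_masterpool(d, 15, seed = 8)
  p <- amplify_pool(p, 50, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_pool(p, path)
  p2 <- read_pool(path)
  expect_identical(p2$seq, p$seq)
  expect_equal(p2$count, p$count)
  expect_equal(p2$state, p$state)
  expect_identical(p2$design$segments, p$design$segments)
})
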