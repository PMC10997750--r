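rand_sig <- function(L = 256L, params = signature_params(L = L)) {
  structure(list(bits = sample(0:1, L, replace = TRUE),
                 fingerprint = params$fingerprint),
            class = "cuf_signature")
}

flip_bits <- function(s, idx) {
  s$bits[idx] <- 1L - s$bits[idx]
  s
}

test_that("the Reed-Muller code encodes/decodes all messages noiselessly", {
  for (m in c(4L, 5L, 8L)) {
    msgs <- expand.grid(rep(list(0:1), m + 1L))
    take <- if (nrow(msgs) > 64) sample(nrow(msgs), 64) else seq_len(nrow(msgs))
    for (i in take) {
      msg <- as.integer(msgs[i, ])
      cw <- cufsim:::rm1_encode(msg, m)
      expect_length(cw, 2L^m)
      dec <- cufsim:::rm1_decode(cw, m, t = 2L^(m - 2L) - 1L)
      expect_true(dec$ok)
      expect_equal(dec$msg, msg)
    }
  }
})

test_that("decoding corrects every pattern within the radius (exhaustive, L = 16)", {
  m <- 4L; t <- 3L
  set.seed(5)
  msg <- sample(0:1, m + 1L, replace = TRUE)
  cw <- cufsim:::rm1_encode(msg, m)
  patterns <- c(list(integer(0)),
                lapply(1:16, function(i) i),
                combn(16, 2, simplify = FALSE),
                combn(16, 3, simplify = FALSE))
  for (idx in patterns) {
    rec <- cw
    rec[idx] <- 1L - rec[idx]
    dec <- cufsim:::rm1_decode(rec, m, t)
    expect_true(dec$ok)
    expect_equal(dec$msg, msg)
  }
})

test_that("beyond-radius patterns never return the transmitted codeword (L = 16)", {
  m <- 4L; t <- 3L
  set.seed(6)
  msg <- sample(0:1, m + 1L, replace = TRUE)
  cw <- cufsim:::rm1_encode(msg, m)
  # weights t+1 .. L-t-1: bounded-distance decoding cannot land on cw
  for (w in (t + 1L):(16L - t - 1L)) {
    for (rep in 1:20) {
      idx <- sample(16L, w)
      rec <- cw
      rec[idx] <- 1L - rec[idx]
      dec <- cufsim:::rm1_decode(rec, m, t)
      expect_false(dec$ok && identical(dec$msg, msg))
    }
  }
})

test_that("fe_params enforces the unique-decoding radius bound", {
  p <- fe_params()
  expect_equal(p$L, 256L)
  expect_equal(p$t, 63L)
  expect_error(fe_params(L = 256, t = 64), "L/4 - 1")
  expect_error(fe_params(L = 100, t = 10), "power of 2")
})

test_that("enrollment round-trips and produces 256-bit keys", {
  set.seed(21)
  p <- fe_params()
  s <- rand_sig()
  b <- fe_generate(s, p, seed = 1)
  expect_match(b$key, "^[0-9a-f]{64}$")   # 256 bits of hex
  expect_identical(fe_reproduce(s, b, p), b$key)

  b2 <- fe_generate(s, p, seed = 2)
  expect_false(identical(b2$key, b$key))
  expect_false(identical(b2$helper$offset, b$helper$offset))
  expect_identical(fe_reproduce(s, b2, p), b2$key)
  # determinism in the seed
  expect_identical(fe_generate(s, p, seed = 1)$key, b$key)
})

test_that("keys survive noise within the radius and reject unlike signatures", {
  set.seed(31)
  p <- fe_params()
  s <- rand_sig()
  b <- fe_generate(s, p, seed = 3)

  # ~0.1 * 256 = 25 flipped bits: the like-input operating point
  s_like <- flip_bits(s, sample(256, 25))
  expect_identical(fe_reproduce(s_like, b, p), b$key)

  # sampled radius contract at L = 256, t = 63
  for (w in c(1, 30, 63)) {
    s2 <- flip_bits(s, sample(256, w))
    expect_identical(fe_reproduce(s2, b, p), b$key)
  }
  for (w in c(64, 100, 128, 192)) {
    s2 <- flip_bits(s, sample(256, w))
    expect_false(identical(fe_reproduce(s2, b, p), b$key))
  }

  # an independent random signature never reproduces the key
  for (i in 1:50) {
    r <- fe_reproduce(rand_sig(), b, p)
    expect_false(identical(r, b$key))
  }
})

test_that("decoding failure is a value, not an exception", {
  set.seed(41)
  p <- fe_params()
  s <- rand_sig()
  b <- fe_generate(s, p, seed = 1)
  s_far <- flip_bits(s, sample(256, 128))
  expect_no_error(res <- fe_reproduce(s_far, b, p))
  expect_true(is.na(res) || is.character(res))
})

test_that("classify_pair separates like from unlike operating points", {
  set.seed(51)
  p <- fe_params()
  s <- rand_sig()
  expect_equal(classify_pair(s, s, p), "same")
  expect_equal(classify_pair(s, flip_bits(s, sample(256, 25)), p), "same")
  expect_equal(classify_pair(s, rand_sig(), p), "different")

  # numeric misclassification bounds at flip probabilities 0.1 / 0.5:
  # P(like rejected) = P(Binom(256, 0.1) > 63), P(unlike accepted) =
  # P(Binom(256, 0.5) <= 63); both far below 1e-6
  expect_lt(pbinom(63, 256, 0.1, lower.tail = FALSE), 1e-6)
  expect_lt(pbinom(63, 256, 0.5), 1e-6)
})

test_that("helper offsets look uniform and bundles survive JSON", {
  set.seed(61)
  p <- fe_params()
  bits <- unlist(lapply(1:40, function(i)
    fe_generate(rand_sig(), p, seed = i)$helper$offset))
  freq <- mean(bits)
  se <- sqrt(0.25 / length(bits))
  expect_lt(abs(freq - 0.5), 4 * se)

  b <- fe_generate(rand_sig(), p, seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_key_bundle(b, path)
  b2 <- read_key_bundle(path)
  expect_identical(b2$key, b$key)
  expect_identical(b2$helper$offset, b$helper$offset)
  # withholding the key keeps only public data
  write_key_bundle(b, path, include_key = FALSE)
  expect_true(is.na(read_key_bundle(path)$key))
})

test_that("mismatched parameter fingerprints are refused", {
  p <- fe_params()
  s <- rand_sig()
  b <- fe_generate(s, p, seed = 1)
  expect_error(fe_reproduce(s, b, fe_params(t = 32)), "parameters")
  s_other <- rand_sig(params = signature_params(hash_seed = 9))
  expect_error(fe_reproduce(s_other, b, p), "enrolled")
})
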