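# cufsim

Simulation and digital readout of **chemical unclonable functions (CUFs)**
built from operable random DNA (orDNA) pools.

A CUF is a large pool of DNA molecules whose random segments were laid down
by stochastic chemical synthesis, arranged in a fixed segmented layout

```
handle5 — input1 — adapter5 — output — adapter3 — input2 — handle3
```

so the randomness stays addressable by PCR. A *challenge* (an n-base input)
is mapped to a primer pair that selectively amplifies the templates whose
random input positions carry exactly those bases; the amplified 21-nt
output segments, read by sequencing, form the *response*. The pool thus
computes an unpredictable but reproducible input → output map — the
chemical analogue of a physical unclonable function — with 4^n possible
challenge-response pairs and an expected N/4^n perfectly matching templates
in a pool of N sequences.

The package is aimed at people studying DNA-based security primitives and
molecular information systems. It provides:

* **Simulator** — library design, masterpool synthesis, urn subsampling,
  global amplification and proliferation (daughter generations), the
  irreversible *uncopiable* state (handles truncated, global PCR refused,
  operation still possible), selection PCR with an off-target background,
  and multinomial finite-depth sequencing with a per-base substitution load
  `p_err = 1 − (1 − 2e-4)^25 + 1e-3 ≈ 0.6%`.
* **Readout pipeline** — constant-region read filtering, output extraction,
  frequency tables and positional base content; weighted k-mer profiles;
  weighted Jaccard similarity `J_w = Σ min(a_x, b_x) / Σ max(a_x, b_x)`;
  256-bit 1-bit-minwise **MinHash** signatures whose expected relative
  Hamming distance is `(1 − J)/2` (0 for like, 0.5 for unlike responses);
  and a code-offset **fuzzy extractor** (Reed-Muller RM(1,8),
  bounded-distance radius t = 63) that maps noisy signatures to stable
  256-bit keys with public helper data.
* **Capacity analytics** — CRP counts, expected matches, coupon-collector
  sequencing depth, proliferation-tree evaluation capacity, resynthesis
  cost and pool entropy, plus an experiment harness comparing like/unlike
  response pairs against a truth matrix.

See `vignettes/cufsim-methods.Rmd` for the model, parameter rationale and
limitations.

## Worked example

```r
library(cufsim)

design <- default_design(seed = 1)               # 40 random nt: 10 + 21 + 9
pool   <- synthesize_masterpool(design, 2e5, seed = 7)
cuf    <- sample_subpool(pool, 1e5, seed = 11)   # one CUF instance

ch    <- "ACGTTACG"                              # 8-base challenge
resp1 <- operate(cuf, ch, depth = 2e4, noise = noise_model(), seed = 101)
resp2 <- operate(cuf, ch, depth = 2e4, noise = noise_model(), seed = 102)
resp1
#> output table: 564 distinct 21-mers, 19990/20000 reads passing
head(frequency_table(resp1, 10), 4)
#>                sequence count frequency
#> 1 ATGTCTATATTGGAGCTTTAC  4486 0.2244122
#> 2 AGATGCCATTTTCCCTAATAT  4419 0.2210605
#> 3 GATTACCAAGCACGCGGTAAA  4382 0.2192096
#> 4 GAGATTGGCAGGAATCGAATT  4336 0.2169085
```

The challenge selected 4 matching templates out of 100,000; their outputs
dominate the read set, with the remaining mass spread over sequencing-error
variants and the 1% off-target background. Two independent operations of
the same challenge agree closely, and a single changed input base yields an
unrelated response:

```r
p1 <- extract_kmers(resp1); p2 <- extract_kmers(resp2)
weighted_jaccard(p1, p2)                          # 0.941  (like pair: >= 0.8)

s1 <- minhash_signature(p1); s2 <- minhash_signature(p2)
relative_hamming(s1, s2)                          # 0      (like pair)

bundle <- fe_generate(s1, fe_params(), seed = 5)  # enroll: key + helper
fe_reproduce(s2, bundle)                          # identical 256-bit key:
#> "3739a2c15fe2eb133f5da6f2085eba16e4fb1a038c20f0260cca9d15e2ecd336"

s3 <- minhash_signature(extract_kmers(
  operate(cuf, "ACGTTACC", depth = 2e4, seed = 103)))   # distance-1 input
relative_hamming(s1, s3)                          # 0.512  (unlike pair)
classify_pair(s1, s3)                             # "different"
```

Capacity arithmetic at real-system scales:

```r
crp_count(13)                    # 67108864 challenge-response pairs
expected_match_count(1e8, 13)    # ~1.49 matching templates
coupon_depth(2.6e10)$depth       # ~24x sequencing depth to read a pool once
evaluation_capacity(200, 5, 200) # 6.4e13 operations from 5 proliferations
resynthesis_cost(2.6e10, 100, 1e-5)  # 2.6e7 USD to re-synthesize
pool_entropy(6e16, 40)$exabytes  # 0.6 exabyte of chemical entropy
```

A thin command-line front end over the same functions lives at
`inst/cli/cuf.R` (subcommands `design`, `synth`, `subpool`, `amplify`,
`lock`, `challenge`, `readout`, `sign`, `compare`, `enroll`, `verify`,
`capacity`).

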