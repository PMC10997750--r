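---
title: "Methods: simulating and reading out DNA chemical unclonable functions"
author: "cufsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and reading out DNA chemical unclonable functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cufsim)
```

## The system being modeled

A chemical unclonable function (CUF) is a very large pool of randomly
synthesized DNA used as a physical source of entropy for challenge-response
cryptography. Each molecule follows a fixed segmented layout — *operable
random DNA* (orDNA):

```
handle5 — input1 — adapter5 — output — adapter3 — input2 — handle3
```

Constant segments (handles, adapters) are identical across all molecules;
`input1`, `output` and `input2` are synthesized from equimolar base mixes and
are therefore random and unknown, 40 nt in total by default (10 + 21 + 9).
A *challenge* is an n-base input string mapped to a primer pair: each primer
is a constant flank plus its share of the challenged bases, so selection PCR
exponentially amplifies exactly those templates whose random input positions
carry the challenged bases. The amplified output segments, read by
sequencing, are the *response*. Because the pool was made by a random
process, responses are unpredictable yet reproducible — the defining
property of an unclonable function.

The package implements (i) a stochastic simulator of the pool's life cycle
(synthesis, urn subsampling, global amplification and proliferation, the
irreversible "uncopiable" state, selection PCR, finite-depth sequencing) and
(ii) the digital readout pipeline that turns noisy reads into similarity
scores and stable 256-bit keys (constant-region filtering, k-mer profiles,
weighted Jaccard, MinHash signatures, fuzzy extraction), plus (iii) the
analytic capacity arithmetic for the scales that cannot be materialized.

## Statistical model of one operation

Given a pool with copy counts $c_i$ and a challenge of length $n$, selection
assigns template $i$ the weight

$$w_i \propto \begin{cases}(1-\phi)\, c_i & \text{input positions match}\\
\phi\, c_i & \text{otherwise}\end{cases}$$

normalized to sum 1, where $\phi$ is the off-target fraction (default 0.01).
Sequencing draws `depth` reads multinomially from $w$ and substitutes each
base independently with probability

$$p_{err} = 1-(1-\mu)^{c} + e_{seq},$$

the accumulated PCR substitution load ($\mu = 2\times10^{-4}$ per base per
duplication over $c = 25$ effective doublings) plus the sequencing error
($e_{seq} = 10^{-3}$), about 0.6% per base in total. The number of
templates matching a random challenge is $\mathrm{Binomial}(N, 4^{-n})$ with
mean $N/4^n$; the experiment harness therefore pairs a $10^6$-sequence pool
with 8-base challenges (≈15 expected matches), the same matching regime as a
$10^8$-sequence pool challenged with 13 bases (≈1.5) but at desk scale.

**Lazy PCR noise.** Mutant molecules are never materialized into pools —
at ~16,000 copies per sequence that would be prohibitive — and the
substitution load is applied per read at sequencing time instead. This
preserves the observable (the mutant read fraction) exactly, at the cost of
ignoring jackpot mutations from early PCR cycles (a mutation arising in
cycle 1 would be correlated across reads; here all reads err independently).

**Deterministic selection weights.** The post-selection weights are an
exact function of copy counts; replicate-to-replicate variation arises from
the multinomial depth draw, the substitution noise and the off-target reads.
Amplification stochasticity (unequal draws of unique sequences) enters
through the lognormal per-template gain of `amplify_pool()` (shape
$\sigma = 0.5$), not through selection itself.

**Continuous copy counts.** Copy counts are positive reals: they act only
as relative abundances in later multinomial draws, the lognormal gain is
continuous anyway, and rounding would bias small mean gains upward.

## Readout pipeline and its parameters

| parameter | default | role |
|---|---|---|
| `max_mismatch` | 2 | substitutions tolerated per 18-nt adapter in read filtering |
| `k` | 10 nt | k-mer length; $4^k \gg$ distinct outputs, one substitution corrupts ≤ 10 of 12 windows |
| `abundance_min` | 2 | absolute window-count floor for the MinHash set |
| `abundance_min_rel` | 0.005 | k-mer count floor as a fraction of passing reads |
| `L` | 256 bits | signature length |
| `t` | 63 bits | fuzzy-extractor decode radius |
| `depth` | 2×10⁴ | reads per operation (desk-scale operating point) |

Filtering is positional: both adapters must match at their designed
coordinates with at most `max_mismatch` substitutions each. The noise model
contains no indels, so alignment would add cost without information; with
defaults the pass fraction is $P(\mathrm{Binom}(18, p_{err})\le 2)^2 \approx
0.999$ per read.

Weighted Jaccard similarity
$J_w = \sum_x \min(a_x,b_x) / \sum_x \max(a_x,b_x)$ is computed on
depth-normalized k-mer frequencies, so unequal sequencing depths cancel.
The MinHash signature instead operates on the abundance-filtered k-mer
*set*: per hash seed, the minimal-hash k-mer is reduced to one bit (parity
of an independent secondary hash), giving bit-agreement probability
$(1+J)/2$ for plain Jaccard $J$ — hence expected relative Hamming distance
$0$ for identical sets and $0.5$ for unrelated ones. Hashing is a
seed-stable 64-bit FNV-1a/splitmix64 construction implemented in C++, so
signatures are bit-identical across runs and platforms; ties on equal hash
values resolve to the lexicographically smallest k-mer.

**Why a relative abundance floor.** A fixed absolute floor stops filtering
errors once depth grows: at depth $2\times10^4$ over ~15 matching templates,
a *specific* substitution (position, target base) recurs
$\approx 1333 \times p_{err}/3 \approx 2.7$ times, so error k-mers flood a
"count ≥ 2" filter and like-pair Hamming distances degrade to ~0.35. True
k-mers carry a per-read share of about $1/m$ for $m$ matching templates
(typically 0.03–0.1); recurrent errors sit around $10^{-4}$. The default
relative floor of 0.005 of passing reads separates the two by an order of
magnitude on each side, and the effective threshold
$\max(\texttt{abundance\_min},\ \texttt{abundance\_min\_rel}\cdot
n_{passing})$ degrades gracefully at low depth.

## Fuzzy extractor

The key stage must map two *similar* signatures (same challenge, noisy
readout) to the *identical* 256-bit key, and unrelated signatures to
unrelated keys. We use a code-offset secure sketch over the first-order
Reed-Muller code RM(1, 8): length 256, dimension 9, minimum distance 128.
Enrollment draws a uniform codeword $c$ and publishes the offset
$s \oplus c$ plus a salt; the key is SHA-256 of the codeword's message and
the salt. Reproduction decodes $s' \oplus \mathrm{offset}$ by fast Hadamard
transform and then *verifies* that the decoded codeword lies within radius
$t$ of the received word (bounded-distance decoding), returning an explicit
"no match" value otherwise, so pair classification is total.

The radius default is $t = 63 = L/4 - 1$, the largest value for which
decoding within the radius is mathematically unique (any $t \ge 64$ would
admit ambiguous weight-64 patterns, since no length-256 binary code can
have minimum distance above 128 at nontrivial dimension). The operating
points sit far from the boundary: like-input signature pairs concentrate
near 0–0.1·L flipped bits, unlike pairs near 0.5·L, and the misclassification
bounds $P(\mathrm{Binom}(256, 0.1) > 63)$ and $P(\mathrm{Binom}(256, 0.5)
\le 63)$ are both below $10^{-6}$. The radius contract is tested
exhaustively at a reduced code length (L = 16, all patterns of weight ≤ 3)
and by sampling at L = 32 and L = 256.

A known limitation: RM(1, 8) has dimension 9, so the sketch's message space
— and hence the entropy of the key *given the helper data* — is 9 bits.
The 256-bit key format is a convenience of the interface, not a security
claim; a production system would concatenate several code blocks or use a
higher-dimension BCH-type code. The package's scope is the interface
behavior (stable keys, total same/different classification), which this
construction satisfies with a provable radius.

## What the synthetic data does and does not emulate

The generator reproduces: i.i.d. uniform random bases at random positions;
urn subsampling without replacement; lognormal amplification gains; exact
input matching in selection with a constant off-target fraction;
multinomial finite-depth sequencing with independent substitutions; and the
copiable→uncopiable transition (handles truncated to 7 and 6 residual
defined bases, global amplification refused, operation still permitted).

It does **not** emulate: indels or quality-score structure in reads;
sequence-dependent amplification bias (the real abundance distributions are
shaped by unknown biases; the lognormal gain is a stand-in); primer
thermodynamics, so challenges that would fail chemically (extreme GC, hairpins)
succeed in silico; template exhaustion over repeated operations; or
cross-contamination between operations. Passing tests therefore demonstrate
the correctness and noise tolerance of the *readout and key pipeline* under
a plausible noise model — not that any particular wet-lab protocol will
achieve the same separation.

Constant segments are synthetic, seed-generated sequences; the pipeline is
agnostic to their content, only to their lengths and positions. The input
segment lengths (10 + 9) follow from the 40 total random nucleotides minus
the 21-nt output; a 13-base challenge splits 7 + 6 across the two primers
by the balanced-split default. All of these are configurable.

## Problem sizes and numerical choices

The reference experiment (also recomputed by `scripts/acceptance.R`)
synthesizes a $10^6$-sequence pool and runs 39 responses over 19 distinct
8-base challenges — replicate groups of 9, 5, 5, 3, 2, 2 plus 13 singletons,
four of which are Levenshtein-distance-1 neighbours of replicated
challenges — yielding 61 like and 680 unlike pairwise comparisons at depth
$2\times10^4$. These sizes keep a full run in the low minutes on one core
while preserving the expected-match regime of the full-scale system.
Larger scales ($10^8$–$2.6\times10^{10}$ sequences, $6\times10^{16}$-strand
masterpools) are handled analytically by the capacity module
(`crp_count()`, `expected_match_count()`, `coupon_depth()`,
`evaluation_capacity()`, `resynthesis_cost()`, `pool_entropy()`).

Degenerate inputs are defined errors, not silent results: an empty
challenge matches everything (it reads the unselected pool); a challenge
with no matching template and zero off-target raises a classed
empty-response error; an empty filtered k-mer set points the user at the
abundance threshold; comparing signatures or helper data produced under
different parameter fingerprints is refused. Frequency tables break count
ties lexicographically so output is deterministic.

All randomness flows from explicit integer seeds through one guarded
`with_seed()` mechanism that restores the caller's RNG state; independent
operations receive independent derived substreams, and the MinHash hash
family is fixed (not process-randomized), so every pipeline stage is exactly
reproducible.
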