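Package: cufsim
Title: Simulation and Readout of DNA-Based Chemical Unclonable Functions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing, simulating and reading out chemical
    unclonable functions (CUFs) built from operable random DNA (orDNA)
    pools. Provides the segmented library design that interleaves constant
    handles and adapters with random input and output segments, a
    stochastic simulator of pool synthesis, urn subsampling, PCR
    amplification and proliferation, selection PCR and finite-depth
    sequencing with realistic error rates, and the digital readout
    pipeline: constant-region read filtering, output k-mer profiling,
    weighted Jaccard similarity, 1-bit minwise (MinHash) signatures and a
    code-offset fuzzy extractor that turns noisy signatures into stable
    256-bit keys. Analytic helpers reproduce the capacity and security
    arithmetic of such systems (challenge-response-pair counts, expected
    template matches, coupon-collector sequencing depth, resynthesis cost
    and pool entropy), and an experiment harness evaluates same/different
    discrimination over planned challenge sets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    digest,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
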