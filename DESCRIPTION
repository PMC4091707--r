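Package: tfscape
Title: Biophysical Fitness Landscape Inference for Transcription Factor Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to infer fitness landscapes for transcription factor (TF)
    binding sites from collections of genomic sites and additive TF-DNA energy
    matrices. Implements the Fermi-Dirac occupancy fitness family and its
    exponential limit, the mutation-selection-drift steady state over binding
    energies, neutral energy spectra from mono-/dinucleotide Markov background
    models via transfer-matrix projection, grid-search maximum-likelihood fits
    with AICc model selection and degeneracy diagnostics, nonparametric
    landscape inversion, forward Wright-Fisher simulation for validating the
    monomorphic steady-state assumptions, permutation and rank-correlation
    screens for site-specific selection, and a seeded synthetic-data generator
    that emulates all required inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    pracma,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
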