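Package: genclock
Title: Generation-Interval Inference from Archaic Fragment Decay and
    Mutation Accumulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers historical human generation intervals from two
    independent genomic clocks: the recombination clock, read from the
    length decay of introgressed Neanderthal fragments, and the mutation
    clock, read from parental-age-dependent accumulation and spectrum
    shifts of derived alleles. Provides a synthetic cohort generator
    (exponential tract-length decay under one-pulse, two-pulse and
    dilution demographies; Poisson mutation counts with age-dependent
    trinucleotide spectra), a two-state Poisson window HMM for ancestry
    calling, BED-style interval arithmetic, bootstrap and permutation
    resampling statistics, recombination-map rescaling and physical-to-
    genetic length conversion, 96- and 9-type mutation spectrum
    classification, pedigree-regression generation-time estimators,
    sex-specific mutation statistics (X-to-A ratio, clustered C>G
    enrichment), and per-type regression comparison against trio data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
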