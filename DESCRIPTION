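Package: rdnacn
Title: Ribosomal DNA Copy Number and Methylation by Simulated Quantitative Hybridization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying human ribosomal DNA (rDNA) copy number and
    hypermethylated-copy content with non-radioactive quantitative
    hybridization (NQH) and methylation-sensitive restriction analysis
    (MSRA). Provides an in-silico model of the 43-kb rDNA repeat unit with
    configurable restriction sites (Csp6I, HpaII, MspI), per-copy
    methylation-state digestion, synthetic dot-blot membrane rendering with
    a calibrated noise model, densitometric quantification against
    calibration standards, computation and inversion of the methylation
    index M with 1M/2M/3M classification, synthetic leukocyte cohorts with
    survivor-truncation structure, cohort-level dispersion statistics, and
    a replicative-senescence model in which only hypermethylated rDNA
    copies are lost.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
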