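Package: rnaiAdapt
Title: Adaptive Protein Evolution and Selective Sweeps in RNAi Pathway Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Inference stack for detecting elevated adaptive protein evolution
    and recent selective sweeps in gene classes across species.
    McDonald-Kreitman count tabulation from codon alignments with NG86-style
    site counting, two-epoch demography plus gamma DFE estimation of alpha and
    omega_A from paired site frequency spectra, a cross-species hierarchical
    Bayesian Poisson model of polymorphism and divergence counts (selection
    effects), random-effects meta-analysis of per-gene omega_A with known
    measurement error, composite-likelihood-ratio sweep scans with
    simulation-based significance and length-weighted enrichment tests, and the
    nSL haplotype statistic. A synthetic-data module generates every input the
    pipeline consumes with known truth, so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rjags,
    coda,
    vcfR,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    lme4,
    metafor,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
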