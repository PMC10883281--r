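Package: hotspotprop
Title: Hotspot Propensity of Somatic Mutational Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of somatic mutational hotspots (genomic positions
    recurrently mutated to the same alternate allele across samples),
    estimation of the intrinsic propensity of mutational signatures to form
    hotspots via controlled subsampling, and closed-form expected-hotspot
    models of increasing resolution (trinucleotide profile, binned mutation
    rates, CpG-methylation aware), together with the associated enrichment
    statistics (signature fold changes inside versus outside hotspots,
    feature-window pileup enrichment with a composition-aware randomisation
    null, methylated-CpG odds ratios) and a fully seeded synthetic-data
    generator that emulates the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    MASS,
    pracma,
    signal,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
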