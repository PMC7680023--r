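Package: holopop
Title: Population Genomics of Holobiont Transcriptome Variants
Version: 0.1.0
Authors@R:
    person("Holopop", "Developers", email = "holopop@example.org",
           role = c("aut", "cre"))
Description: Downstream population-genomic analysis of variants called from a
    holobiont (host plus algal symbiont) transcriptome. Classifies reference
    contigs into host and symbiont compartments from BLAST hit tables, applies
    a four-step variant filter cascade, detects clonal ramets from multilocus
    genotypes, separates neutral from putatively adaptive loci with a
    covariance-corrected differentiation statistic (XtX) calibrated against
    pseudo-observed data, and quantifies population structure (AMOVA-style
    Fst with permutation tests, PCA) and diversity (Ho, Hs) per compartment.
    Includes a synthetic-data generator emulating a dual-compartment,
    four-population design so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
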