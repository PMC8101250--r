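Package: temob
Title: Population Dynamics of Transposable-Element Insertion Polymorphisms
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genotypes and filters transposable-element insertion
    polymorphisms (TIPs) across large selfing-plant accession panels from
    per-sample candidate calls, summarises their folded site frequency
    spectra, dates insertions from local haplotype divergence, estimates the
    TE insertion substitution rate and the fraction of insertions eliminated
    by selection from pairwise TIP-versus-SNP divergence, quantifies
    recurrent gene targeting and carrier versus non-carrier expression
    impacts against permutation and resampling nulls, and models very recent
    transposition as a Poisson function of genotype, climate and their
    interaction, with forecasting under future climates. A synthetic-cohort
    generator emulates the statistical structure of every required input so
    the whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
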