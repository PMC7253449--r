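Package: uORFscan
Title: Annotation and Selection Analysis of uORF-Perturbing 5'UTR Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of 5'UTR variants that create
    upstream start codons (uAUGs) or remove upstream open reading frame
    (uORF) stop codons. Provides exhaustive enumeration of uAUG-creating
    SNVs and small deletions and of stop-removing SNVs on spliced
    transcript models, classification of their translational consequence
    (uORF created/elongated, out-of-frame overlapping ORF, CDS elongation)
    with Kozak-context strength, the mutability-adjusted proportion of
    singletons (MAPS) selection statistic with context-dependent mutation
    rate calibration, bootstrap confidence intervals and permutation
    p-values, base-level conservation comparisons, disease-variant
    enrichment tests, a nine-class gene-level triage of sensitivity to
    uORF-perturbing variation, and a synthetic-data generator so the whole
    pipeline runs and is validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
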