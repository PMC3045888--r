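Package: estmine
Title: EST Transcriptome Mining: Clustering, SNP Discovery and Digital
    Differential Expression
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for mining expressed sequence tag (EST) collections the
    way classic cDNA-library transcriptome surveys did: read trimming
    (adapter, polyA/T, quality) and bacterial-contaminant screening from
    similarity hit tables; greedy overlap clustering of 5' ESTs into
    contigs with majority-rule consensus calls; ORF/UTR annotation with GC
    and GC3 composition profiling; haplotype-filtered SNP detection in
    contig alignments with transition/transversion classification,
    synonymy labelling and KA/KS estimation; digital differential
    expression from per-library EST counts via the exact Audic-Claverie
    test and the multi-library R statistic, followed by correlation-based
    hierarchical clustering of expression profiles; hypergeometric term
    enrichment and an orthologous-family prevalence screen. A seeded
    synthetic EST-library generator with full ground truth drives testing
    and power evaluation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    ape
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Transcriptomics, SNP, GeneExpression, Clustering, Software
RoxygenNote: 7.3.3
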