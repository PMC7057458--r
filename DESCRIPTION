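Package: InversionMiner
Title: Feature-Mining Detection of Genomic Inversions from Paired-End
    Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls genomic inversions from coordinate-sorted paired-end
    alignments by mining alignment signatures around candidate breakpoints.
    Extracts fifteen numeric features (read-pair orientation, one-end-unmapped
    pairs, soft-clipped reads, insert-size concordance, mapping-quality bins,
    unique versus multiple placement, edit-distance classes) from insert-size
    padded breakpoint windows, ranks them by a chi-square score against the
    inversion/wild-type label, and classifies candidate sites merged from
    upstream structural-variant callers with a linear support vector machine
    trained on simulated inversions. Includes a paired-end read-pair simulator
    that reproduces inversion alignment signatures, breakpoint-threshold
    benchmark evaluation, and a repeated k-fold cross-validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    VariantAnnotation,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StructuralVariation, VariantDetection, Classification,
    Sequencing, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'InversionMiner-package.R'
    'utils.R'
    'alignments.R'
    'candidates.R'
    'classifier.R'
    'evaluation.R'
    'features.R'
    'methods-accessors.R'
    'selection.R'
    'simulator.R'
    'workflow.R'
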