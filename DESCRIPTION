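Package: TRAscan
Title: Transcription Regulatory Area Mutation Analysis for Paired
    Tumor Timepoints
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives transcription regulatory areas (TRAs) from ENCODE-style
    transcription factor binding site (TFBS) cluster intervals, applies
    read-support and allele-frequency filters to paired diagnosis/relapse
    somatic variant calls after germline subtraction, classifies variants as
    common or acquired between timepoints, annotates coding consequences
    against gene models and a genome sequence, attributes TRA alterations to
    the transcription regulators bound at each mutated base, computes
    per-regulator involvement rates and ratios, and integrates the resulting
    gene sets with expression-derived differential-expression and
    transcript-variant gene sets. A synthetic-data module generates every
    input format with planted, machine-readable ground truth so the whole
    pipeline is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Genetics, Epigenetics, SomaticMutation,
    FunctionalGenomics, Sequencing
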