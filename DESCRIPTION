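Package: twinsom
Title: Somatic Mutation Detection and Validation in Monozygotic Twin
    Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection of low-allele-fraction somatic single-nucleotide
    variants from paired exome-style sequencing of monozygotic co-twins,
    where one twin serves as the matched control for the other. Implements
    the post-caller filter cascade (multi-copy-region and indel-proximity
    exclusion, base-quality/depth thresholds, flank-homology scoring,
    control-identity exclusion), read-level classification of
    alt-supporting base-calls against seven reliability criteria (RBSM),
    difficult sequence-context detection, high-confidence candidate
    selection, deep-amplicon allele-fraction validation against a
    Phred-derived error threshold, and the accompanying statistics:
    monozygosity concordance at credible SNV sites, Fisher contingency
    tests on base-call counts, post hoc threshold analysis, and the
    strand-collapsed mutation spectrum. A synthetic twin-data generator
    produces reference sequences, paired alignments, candidate tables and
    amplicon counts with the artifact structure the filters target, so the
    whole pipeline is testable without access to restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
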