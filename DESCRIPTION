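Package: itcombine
Title: Intersect-Then-Combine Filtering and Benchmarking of Somatic Variant Calls
Version: 0.1.0
Authors@R: person("ITC", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing of tumour-normal somatic SNV and indel calls from
    Mutect2 (GATK 3.5 era) and Strelka v1. Implements caller-specific optimized
    admission rules (including a tumour/normal VAF-ratio filter and relaxed
    alt-allele-in-normal bound), representation-aware variant matching through
    left-alignment against a reference, the intersect-then-combine (ITC) set
    algebra (per-caller intersection across two alignment pipelines, union
    across callers), and a benchmarking engine reporting sensitivity and false
    positives per megabase against a truth set restricted to confident regions.
    A synthetic dilution-series generator emits caller-dialect VCFs with
    controllable error structure so the whole workflow is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
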