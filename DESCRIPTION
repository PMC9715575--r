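Package: pansv
Title: Pan-Genome Structural Variant Consensus Calling and
    Presence-Absence Variation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for pan-genome structural variant (SV)
    analysis against a single pivot reference genome. Harmonizes SV calls
    from two whole-genome-alignment callers (an Assemblytics-style BED
    dialect and a SyRI-style TSV dialect) across pairwise and reciprocal
    alignment directions into consensus presence-absence variants (PAVs),
    copy-number variants, inversions, and small indels; merges
    per-accession PAVs into nonredundant pan-genome loci with a
    presence/absence matrix, VCF export, and a sequence-graph pan-genome;
    computes sliding-window PAV density, hotspot and group-differential
    regions, GWAS-region overlap, and transposable-element association;
    classifies gene families into core/non-core/specific sets with
    permutation accumulation curves and hypergeometric term enrichment;
    annotates SVs relative to gene models; and tests PAV-trait
    co-segregation. A seeded synthetic-genome simulator plants
    truth-tracked SVs and emits every downstream input so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    VariantAnnotation,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
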