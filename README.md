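# pansv

Pan-genome structural-variant (SV) analysis against a single pivot
reference genome, for crop genomics groups comparing chromosome-scale
assemblies of multiple accessions (the motivating system is a panel of
hot and sweet pepper genomes compared to one high-quality reference).
`pansv` takes the output of two whole-genome-alignment SV callers — an
Assemblytics-style BED dialect and a SyRI-style TSV dialect, each run
in both the pairwise and the reciprocal alignment direction — and turns
them into a harmonized, analysis-ready pan-genome of
presence–absence variants (PAVs).

## What it computes

**Dual-caller consensus.** Per accession, each caller's candidate set
is the union of its pairwise calls and its reciprocalized
reciprocal-direction calls (reciprocal alignment recovers insertions,
which genome alignment detects more sensitively as deletions).
Candidates are matched one-to-one across callers: interval calls at
reciprocal overlap ≥ 0.5, insertion breakpoints within 100 bp with
size ratio ≥ 0.5. Matched calls become consensus variants:

- **PAV** (presence–absence variant): Insertion/Deletion
  (Assemblytics) × INS/DEL/HDR (SyRI) consensus, size ≥ 50 bp.
- **Small indel**: the same consensus restricted to 5–49 bp.
- **CNV**: Deletion/Tandem_contraction (Assemblytics) ×
  DUPAL/HDR/CPL (SyRI), each required in *both* alignment directions.
- **INV** (≥ 1 kb) and **SNP**: taken from SyRI INVAL and SNP calls.

**PAV landscape.** Per-accession PAVs are merged into nonredundant
pan-genome loci (single-linkage at 80% reciprocal overlap / 100-bp
breakpoint window), giving a locus × accession presence/absence
matrix, a VCF 4.2 export, and a sequence-graph pan-genome (pivot
backbone + allele nodes, GFA 1.0) whose accession paths spell the
accession genomes.

**Window statistics.** PAV density in 1-Mb sliding windows with 200-kb
steps; hotspot regions as the top 1% of windows genome-wide (ties
included, merged); hot-vs-sweet differential regions as the top 5% of
the gap in group-mean PAV counts; overlap of GWAS intervals with ±1-Mb
flanked regions; Spearman association between PAV density and
transposable-element (TE) coverage.

**Pan-gene families.** Orthogroup tables are classified into core
(present in all *n* genomes), non-core (2 to *n*−1) and specific
(exactly 1) families; pan/core accumulation curves are averaged over
permuted genome orderings (`pan(k) = |∪ first k|`,
`core(k) = |∩ first k|`), with an exact closed form
`E[pan(k)] = Σ_f (1 − C(n−m_f, k)/C(n, k))` as cross-check; term
enrichment is a one-sided hypergeometric test with
Benjamini–Hochberg adjustment.

**SV annotation and traits.** Every SV is labelled genic / 5′ (within
1 kb upstream of the start codon, strand-aware) / intergenic; Pfam
domains are ranked by distinct gene counts within region sets;
candidate-gene PAVs are tested for co-segregation with phenotypes by
the two-sided Fisher exact test, with the Bonferroni threshold utility
`−log10(α / n_markers)` for GWAS plots.

**Synthetic cohorts.** A seeded simulator plants a non-overlapping
pool of truth-tracked SVs (deletions, insertions, copy losses,
inversions, small indels, SNPs) on a multi-chromosome pivot, derives
carrier accessions per variant, and emits every downstream input —
accession FASTA, both caller dialects in both directions (with
configurable false-negative, jitter and label-confusion noise), GFF3
gene models, repeat BED, orthogroup tables, phenotypes — so the whole
pipeline is testable offline against planted truth.

## Worked example

```r
library(pansv)

cfg   <- sim_config(seed = 42, n_chromosomes = 2, chrom_length = 1e6,
                    n_accessions = 4, n_genes = 40)
pivot <- simulate_pivot(cfg)
truth <- plant_svs(pivot, cfg)

calls <- harmonize_accession(
  emit_caller_calls(truth, "assemblytics", "pairwise",   "acc01"),
  emit_caller_calls(truth, "assemblytics", "reciprocal", "acc01"),
  emit_caller_calls(truth, "syri",         "pairwise",   "acc01"),
  emit_caller_calls(truth, "syri",         "reciprocal", "acc01"),
  accession = "acc01")
table(calls$sv_class)
#>         CNV         INV     PAV_DEL     PAV_INS SMALL_INDEL         SNP
#>           3           2          10           9          13           4
```

Each consensus call records which caller/direction combinations
support it, e.g. the first PAV deletion of acc01 spans
chr01:10,018–12,807 (2,789 bp) with support
`assemblytics:pairwise,assemblytics:reciprocal,syri:pairwise,syri:reciprocal`.
Merging all four accessions' PAVs gives the nonredundant pan-genome:

```r
all_calls <- do.call(rbind, lapply(cfg$accessions, function(acc)
  harmonize_accession(
    emit_caller_calls(truth, "assemblytics", "pairwise",   acc),
    emit_caller_calls(truth, "assemblytics", "reciprocal", acc),
    emit_caller_calls(truth, "syri",         "pairwise",   acc),
    emit_caller_calls(truth, "syri",         "reciprocal", acc),
    accession = acc)))
pav  <- all_calls[all_calls$sv_class %in% c("PAV_DEL", "PAV_INS"), ]
loci <- merge_nonredundant(pav)
m    <- build_pa_matrix(loci, cfg$accessions)
loci$loci[1:3, c("locus_id", "chrom", "start", "end", "sv_type", "n_members")]
#>   locus_id chrom start   end sv_type n_members
#> 1 PAV00001 chr01 10018 12807     DEL         2
#> 2 PAV00002 chr01 58649 58649     INS         3
#> 3 PAV00003 chr01 99757 99757     INS         2
m[1:3, ]
#>          acc01     acc02     acc03     acc04
#> PAV00001 "present" "present" "absent"  "absent"
#> PAV00002 "present" "present" "present" "absent"
#> PAV00003 "present" "present" "absent"  "absent"
```

39 loci are recovered here; each row of the matrix is a candidate
marker. A perfectly co-segregating deletion in a 6-carrier vs
4-non-carrier panel gives concordance 1 and the smallest p the panel
can support, `1/C(10,6)`:

```r
ct <- cosegregation_test(rep(c(TRUE, FALSE), c(6, 4)),
                         rep(c(TRUE, FALSE), c(6, 4)))
c(concordance = ct$concordance, p = signif(ct$p, 4))
#> concordance           p
#>    1.000000    0.004762
bonferroni_threshold(0.05, 13146)
#> [1] 5.4198
```

A command-line front end is installed with the package
(`system.file("scripts", "pansv", package = "pansv")`) with
`simulate`, `harmonize`, `pangenome` and `run` subcommands; `run`
executes the whole simulate → harmonize → pan-genome → windows →
pan-gene → annotate → trait pipeline into an output directory with an
MD5 manifest.

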