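---
title: "Methods: consensus SV calling and PAV landscape analysis with pansv"
author: "pansv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus SV calling and PAV landscape analysis with pansv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pansv)
```

# The analysis model

`pansv` implements a reference-anchored ("pivot") pan-genome SV
analysis. All accession genomes are compared to one high-quality pivot
assembly; every variant lives on pivot coordinates. The package's core
assumption is that a variant is trustworthy when two independent
whole-genome-alignment callers agree on it, and that insertion-type
variation must be interrogated in *both* alignment directions, because
alignment detects a missing segment far more sensitively when it is
missing from the query (a deletion) than when it is extra in the query
(an insertion). Running the alignment reciprocally turns each
insertion into a deletion in the swapped frame; `reciprocalize()`
projects those calls back onto the pivot by exchanging the coordinate
frames and the direction-dependent labels
(Deletion↔Insertion, DEL↔INS, tandem/repeat expansion↔contraction,
CPL↔DUPAL). The operation is an involution, which the tests assert.

## Coordinates

All internal coordinates are 0-based, half-open. 1-based inclusive
coordinates appear only at the GFF3, VCF and SyRI-dialect file
boundaries and are converted exactly once, at parse/write time. An
insertion is a zero-width interval (`start == end`) carrying its
alternate length; a deletion is a non-empty interval with no alternate
sequence. A single internal convention avoids the off-by-one drift
that plagues multi-format pipelines.

## What counts as a "common call"

The callers do not emit identical breakpoints, so consensus needs a
matching criterion. `match_params()` exposes the three knobs:

| parameter | default | role |
|---|---|---|
| `min_reciprocal_overlap` | 0.5 | interval calls: `overlap/len` must reach this in *both* intervals |
| `max_breakpoint_dist` | 100 bp | insertions: breakpoint distance bound |
| `min_size_ratio` | 0.5 | insertions: `min(size)/max(size)` bound |

There is no community-standard intersection criterion for this step,
so these defaults are this package's choice, documented here and
configurable everywhere. 50% reciprocal overlap is the conventional
`bedtools`-style reciprocal intersection; 100 bp is generous relative
to breakpoint jitter observed for assembly-based callers but narrow
relative to variant spacing. Matching is greedy one-to-one by
decreasing score (reciprocal overlap, or scaled breakpoint proximity),
with deterministic tie-breaking by start coordinate then record id:
reproducibility is preferred over optimal bipartite matching, and a
brute-force oracle test bounds the difference (exact agreement on
random jittered instances).

Consensus coordinates are taken from the Assemblytics-dialect member
of a matched pair; a single deterministic representative is required, and that dialect
is conventionally run first in this kind of dual-caller workflow.

## Variant classes

* **PAV**: both-caller consensus of Insertion/Deletion (Assemblytics
  dialect) with INS/DEL/HDR (SyRI dialect), size ≥ 50 bp. The 50-bp
  floor is the complement of the 5–49-bp small-indel bin; it is
  exposed as `pav_min_size`.
* **Small indel**: the same consensus logic with size in [5, 49] bp.
* **CNV**: Assemblytics Deletion/Tandem_contraction matched between
  the pairwise and reciprocalized directions, crossed with SyRI
  DUPAL/HDR/CPL matched between its two directions. Requiring both
  directions *within* each caller before crossing callers is what
  separates copy-number signal from plain PAVs.
* **INV** (≥ 1 kb) and **SNP**: single-caller classes from SyRI INVAL
  and SNP records; sub-1-kb INVAL records are dropped and counted.

`harmonize_accession()` runs the classes in order PAV → small indel →
CNV → INV/SNP and removes source records consumed by an earlier class
from later candidate pools, so no input record contributes to two
emitted classes. HDR records are accepted for both PAV and CNV
candidacy in both orientations; the exclusion rule resolves any
double-counting deterministically in favour of the PAV class.

# Nonredundant loci, matrix, graph, VCF

Cross-accession merging uses single-linkage clustering under the same
matching criterion but at 80% reciprocal overlap for deletions —
stricter than the within-accession 0.5, because all calls already
share the pivot frame, so residual disagreement is caller jitter
rather than alignment ambiguity. The locus representative is the
member with the lower-median size (ties to the smaller start):
deterministic, robust to single outlier members. Because clustering is
single-linkage over *all* calls, two final loci of the same type can
never satisfy the criterion against each other (a test asserts this).

The presence/absence matrix distinguishes `absent` (call set existed,
no member) from `missing` (no call set for that accession): downstream
genotype analyses need the distinction even though merged call sets
rarely preserve it.

The pan-genome graph splits the pivot backbone at every locus
breakpoint; deletions add bypass edges, insertions add alternate
nodes. Nested loci are linearized by keeping the larger locus (the
behaviour of full graph constructors on nested variation is out of
scope). The defining invariant, asserted on truth-derived loci, is
that every accession path spells that accession's simulated sequence
exactly, and the pivot path spells the pivot.

VCF export writes symbolic `<DEL>` records with `END`/`SVLEN`,
sequence-resolved insertions when the inserted sequence is known
(`<INS>` with `SVLEN` otherwise; the 0-based breakpoint is kept in a
declared `BP0` INFO key because a left-anchored `POS` alone cannot
distinguish a breakpoint at position 0 from one at position 1), one
sample column per accession and `GT` 1 for carriers. Write → read →
write is byte-identical, and an independent VCF reader
(`VariantAnnotation::readVcf`) parses the output in a test.

# Window statistics

The density track uses 1-Mb windows advanced in 200-kb steps, the
customary geometry for chromosome-scale PAV density in large plant
genomes. With these defaults every interior base lies in exactly five
windows. Variant-to-window assignment defaults to the **midpoint
rule** (count a variant in every window containing its midpoint, the
breakpoint for insertions) because it gives every variant identical
track mass — five interior windows — regardless of its size, so large
deletions do not dominate the track. An overlap rule is available for
comparison.

Hotspots are the top 1% of windows *genome-wide* (not per chromosome,
since hotspots are reported genome-wide), using the type-1 empirical
quantile with ties included (`>=`), then merging overlapping or
bookended selected windows. With fewer than 100 windows the 99%
quantile degenerates to the maximum; the function warns. Terminal
windows shorter than 1 Mb are kept and flagged rather than dropped.

The hot-vs-sweet differential track is the per-window gap between
group means of per-accession PAV counts. Selection uses the absolute
gap by default — a hotspot of either polarity is of interest — with a
signed mode available. GWAS intervals are compared against the top
regions extended by ±1 Mb and labelled contained / overlapping /
disjoint with bp overlaps and a Jaccard index. TE association reports
per-window TE bp fractions (total and per class) and Spearman rank
correlations, overall and restricted to a region set; zero TE coverage
yields `NA` with a degeneracy flag rather than a number.

# Pan-gene analysis

Presence means at least one gene in the accession column; paralog
counts never affect the class. Core requires presence in all genomes,
specific in exactly one, non-core otherwise; the softcore count
(present in ≥ n−1) supports the common "at least n−1 genomes"
convention used for presence-pattern figures alongside the strict
all-genomes core. Accumulation curves average over 100 random
orderings by default; the count is seeded and configurable,
and for ≤ 8 genomes the implementation switches to exhaustive
enumeration whenever the requested permutations reach `n!`. The exact
expectation
`E[pan(k)] = Σ_f (1 − C(n−m_f, k)/C(n, k))`,
`E[core(k)] = Σ_f C(m_f, k)/C(n, k)`
is implemented separately (`expected_curves()`) and used as an
independent cross-check. Term enrichment replaces an external web
service with a one-sided hypergeometric upper-tail test and
Benjamini–Hochberg adjustment; terms with fewer than three set genes
are skipped by default.

# SV context and traits

The 5′ region is implemented strictly as the 1-kb window immediately
upstream of the start codon, strand-aware — an operational definition
that needs no UTR annotation, only CDS extremities. Genic takes precedence
over 5′ when an SV spans both, making the three labels mutually
exclusive — matching bar-chart categories that partition SVs.
Insertions are located by their breakpoint; a breakpoint exactly at a
gene boundary is outside the gene (the inserted sequence sits between
the flanking bases). Genes without CDS have no defined start codon and
are excluded from 5′ logic with a warning.

Co-segregation binarizes phenotypes as erect (code 1) versus not
(codes 3 and 6) by default — intermediates group with pendent because
the erect class is the putatively monogenic one — and reports the better of the two
carrier-polarity concordances plus the two-sided Fisher exact p
(probability mass of all tables with fixed margins no more likely
than the observed one; `stats::fisher.test`, verified in the tests
against a full hypergeometric enumeration for n ≤ 20). Fisher's exact
test is conservative on small discrete tables: on null simulations
with 200 accessions the realized type-I error sits slightly below the
nominal 5%, which the tests assert within a 2.5–7.5% band. The
Bonferroni utility computes `−log10(α/n)`; with α = 0.05 and a
13,146-marker chip panel it gives 5.42.

# The synthetic cohort generator

The generator is first-class, tested code, and defines the cohort
conditions under which everything else is validated.

**What it emulates.** A multi-chromosome pivot (uniform A/C/G/T,
no N runs), non-overlapping strand-aware gene models with marked start
codons, repeat intervals covering a target fraction (default 0.3) in
LTR-like and DNA-transposon classes, and a pool of segregating
variants: PAV deletions/insertions (50–5000 bp), copy losses
(100–2000 bp), inversions (1–10 kb), small indels (5–49 bp) and SNPs,
at default rates totalling ~20 events per accession per Mb — so the
default 2 × 5 Mb, 8-accession cohort plants roughly 200 events per
accession. Variants are drawn once, placed without overlap
genome-wide, and each accession carries each variant independently
with probability 0.5 (`carrier_prob`); group-enrichment directives
plant additional variants carried by every member of one accession
group, which is how group-differential clusters and density hotspots
are planted. Shared carriers are what make cross-accession merging,
presence/absence genotypes and co-segregation meaningful; they also
mirror real panels, where most PAVs segregate among accessions rather
than being private.

**Placement guard band.** Planted events keep at least 150 bp of
clearance — more than the 100-bp insertion-matching window — so two
distinct planted events can never satisfy the consensus matching
criterion against each other. Without this, exact-recovery properties
are ill-posed: the consensus logic has no defined semantics for
distinct events closer than its own matching window, which is also why
nested or overlapping truth events are excluded outright.

**Caller emission.** Each dialect/direction file is derived from truth
exactly (classes a dialect does not report — inversions and SNPs for
the Assemblytics dialect — are omitted from its files), then degraded
by a seeded noise model: per-file false-negative dropout, rounded
Gaussian breakpoint jitter in both coordinate frames, and annotation
confusion within the dialect's vocabulary. Noiseless emission followed
by parsing is lossless per dialect, and the binomial dropout rate is
verified against its expectation. The noise defaults are free
parameters, not estimates of any real caller's error profile.

**What it does not emulate.** Alignment artifacts (spurious calls,
systematic breakpoint bias near repeats), realistic repeat families,
nested/overlapping SVs, translocations, polyploidy or heterozygosity,
and sequencing reads. Passing tests therefore demonstrate the
correctness of the consensus/landscape logic under clean and
moderately noisy call sets, not robustness to pathological alignment
behaviour on real multi-gigabase genomes.

# Numerical and design choices

* Deterministic everywhere: one seed in `sim_config()`/`run_config()`
  fixes every byte of output; the pipeline writes an MD5 manifest and
  two identical runs hash identically.
* Greedy matching, clustering representatives, quantile ties, pattern
  sorts and domain-ranking ties all have explicit deterministic
  tie-break rules (documented on each function).
* Quantile thresholds use the type-1 (inverse-ECDF) empirical
  quantile so selection is a rank rule with ties included, never an
  interpolated value.
* Degenerate inputs return flagged values rather than errors where a
  flag is more useful: constant phenotype → p = 1 with
  `degenerate = TRUE`; zero TE coverage → `NA` correlation with a
  flag; empty inputs → empty, correctly-typed results.
* Duplicate consensus calls (possible when jitter breaks the
  within-caller direction merge) are deduplicated by largest support,
  then largest size, then smallest start.

## Problem sizes used by the test suite

The suite validates at sizes chosen to exercise every code path while
keeping a full run in the low minutes on one core: the headline
recovery cohort at 2 chromosomes × 5 Mb with 8 accessions (~1,400
planted events), noise-robustness and recovery sweeps over 10 seeds at
1–2 Mb × 4–6 accessions, oracle-equivalence batches of up to a few
hundred features per instance, and exhaustive 720-ordering pan-gene
enumeration at 6 genomes. `scripts/acceptance.R` re-runs the same
computations from scratch under a caller-provided seed.

# Known limitations

* Consensus semantics for nested or overlapping events are undefined
  by design; real pepper-scale genomes contain such regions and would
  need pre-filtering or a richer event model.
* The graph pan-genome is a minimal PAV graph (no inversion or CNV
  alleles on the graph, no index structures, no read mapping).
* CNV calling is annotation-class consensus; it does not estimate
  copy number, only consensus copy-loss/duplication segments.
* Reciprocal projection relies on the paired query coordinates carried
  in each record; records without them are rejected rather than
  re-aligned.
* The Fisher/hypergeometric machinery assumes accession-level
  presence/absence; it does not model heterozygous carriers (an F1
  hybrid accession is exactly such a case and is out of scope).
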