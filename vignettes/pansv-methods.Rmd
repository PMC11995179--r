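---
title: "Methods: pan-gene classification, SV catalogs, stratification scans and marker-panel prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-gene classification, SV catalogs, stratification scans and marker-panel prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pansv)
```

pansv implements the downstream stages of a multi-assembly pan-genome
study of a livestock species: classifying gene families by occupancy,
building a nonredundant structural-variant (SV) catalog from two
detection sources, scanning SV genotypes for population stratification,
joining the scan with expression and chromatin evidence, and comparing
SNP, SV and combined marker panels for association and genomic
prediction. Every stage can be exercised on data from the bundled
generator, which records its planted ground truth.

This vignette explains the models, the defaults and their units, the
numerical conventions, and the design decisions that were genuinely
open. It reports no numbers that the test suite or the acceptance
script do not themselves compute.

## Coordinates and formats

All intervals are held internally as 0-based half-open `[start, end)`;
insertion and translocation breakpoints are width-0 points evaluated as
the single base at the breakpoint. On disk the package writes the
field's conventions: GFF3 is 1-based inclusive (via `rtracklayer`),
BED is 0-based half-open, and VCF `POS` is `start + 1`. `SVLEN` is
written negative for deletions and positive otherwise; internal lengths
are absolute. VCF output is re-read through `vcfR`, an independent
parser, in the round-trip tests.

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed
once, not tuned per analysis.

* **Presence/absence matrix** (`simulate_pangenome()`): 14 genomes;
  class proportions default to core 38.94%, dispensable 60.09%,
  private 0.97%. Class counts are apportioned by largest-remainder
  rounding so they always sum to the family total. Core rows are
  all-ones, private rows have a single one, dispensable occupancy is
  uniform on 2..n−1. Uniform occupancy is a neutral choice — real
  occupancy spectra are typically U-shaped — but it leaves every
  classification boundary exercised.
* **Annotation** (`simulate_annotation()`): non-overlapping gene models
  with 1–5 exons (300–1200 bp), introns of 300–2500 bp and 50–150 bp
  UTRs at the transcript ends; at least 2.5 kb between genes so 2-kb
  flanks never collide. TE intervals (log-normal lengths around
  ~1 kb) are labelled LTR or non-LTR (35:65), may overlap genes, and
  are placed uniformly.
* **Two SV callsets** (`simulate_sv_callsets()`): true variants have
  types DEL/INS/INV/TRA with proportions 0.53/0.435/0.017/0.018 and
  sizes from a binned mixture whose mode is the 101–500 bp bin with
  ~91% below 5 kb, matching the canonical SV size spectrum. Variants
  are spaced at least 2001 bp apart — beyond every merge tolerance —
  so that identity is unambiguous and the merge oracle can demand
  perfect precision and recall. A `shared_fraction` of variants
  appears in both callsets; the second callset carries uniform
  breakpoint jitter up to ±`jitter_bp` (default 20 bp, additionally
  capped at 30% of the variant length) and ±15% insertion-size jitter,
  both inside the default matching tolerances by construction.
* **Population genotypes** (`simulate_population_genotypes()`): three
  populations of 72, 112 and 62 samples (a cold-adapted group, a
  hot-adapted group and a commercial outgroup). Baseline allele
  frequencies are Beta(0.8, 0.8) — a U-shaped folded spectrum typical
  of SV panels — shared across populations; a `divergent_fraction`
  (default 5%) of loci instead gets the target population forced at
  least 0.6 apart from the others. Genotypes are Hardy–Weinberg draws;
  the frequency spectrum and missingness of a real genotyped SV panel
  are not knowable here, so these defaults are stated choices, not
  inferences.
* **Phenotypes** (`simulate_phenotypes()`): y = Σ xβ + e with
  standard-normal QTL effects; the residual is orthogonalised against
  the genetic values and rescaled so the realized genetic-variance
  fraction equals `h2` exactly. QTLs can be restricted to one marker
  class (`qtl_class = "SV"`) to create signal invisible to a SNP
  panel.
* **Expression** (`simulate_expression()`): negative-binomial counts
  (dispersion 0.1) for control and stress groups of `n_expr_reps = 10`
  samples each; planted DEGs carry a multiplicative 2^`deg_log2fc`
  effect with random sign, placed preferentially within 5 kb of
  supplied SVs. The group size of 10 was fixed at design time so the
  exact rank-sum test's minimum attainable p-value,
  2/choose(2n, n) ≈ 1.1e-5, sits well below the BH-adjusted 0.05 cut
  at the default gene count; the source study does not state its
  RNA-seq group sizes.

One global seed feeds per-stage child seeds at fixed offsets, so a
stage's output does not change when an unrelated stage's configuration
does. Identical configurations give byte-identical outputs.

What the generator does **not** emulate: linkage disequilibrium decay
along the chromosome (marker dosages are independent given their
frequencies), population admixture and relatedness, read-level noise,
and occupancy/frequency spectra estimated from real data. Passing
recovery tests therefore demonstrates correctness of the algorithms
under their stated assumptions, not calibration on real pig data.

## Assembly QC arithmetic and telomere scan

`qv_to_error_rate()`, `error_rate_to_qv()` and `implied_accuracy()` are
the Phred identities QV = −10·log10(e) and accuracy = 100·(1−e),
mutual inverses on (0, 1]. `telomere_scan()` counts non-overlapping
occurrences of the telomere motif (vertebrate TTAGGG) and of its
reverse complement in a terminal window (default 100 kb) at each end of
each sequence; non-overlapping counting makes density = motif bp /
window bp interpretable as the covered fraction of the window. The
telomere call threshold (default density ≥ 0.1) is a convention knob —
the underlying study does not print its cutoff — and ambiguous bases
never match.

## Pan-gene classification and accumulation curves

Occupancy over n genomes partitions families: present in all n = core,
in exactly 1 = private, otherwise dispensable. Per-genome composition
reports each genome's class percentages *of the families it contains*;
because every genome holds all core families but only part of the
dispensable set, per-genome core percentages systematically exceed the
global core share — both views are emitted.

Accumulation curves add genomes in random order; pan(k) is the union
and core(k) the intersection of the first k genomes' family sets.
All n! orderings are enumerated when n! ≤ 40,320 (n ≤ 8), otherwise
`n_permutations` (default 1000) sampled orderings are used; means of
the exhaustive and sampled estimates are compared against a brute-force
enumerator in the tests. Class-wise metric contrasts (expression, CDS
length, Ka/Ks, π) use two-sided Wilcoxon rank-sum tests — exact when
both groups have ≤ 25 values without ties, normal approximation with
continuity correction otherwise — BH-adjusted across class pairs.

## SV catalog construction

`merge_callsets()` collapses records describing the same variant:
same type, and reciprocal overlap ≥ 0.5 for DEL/INV; breakpoints
within 100 bp *and* size ratio ≥ 0.7 for INS; both breakpoints within
1 kb for TRA. These thresholds follow widespread SV-merging practice
and are exposed as arguments, since the source study's exact criteria
are not printed. Matching is greedy best-first (largest overlap
quality, then smallest breakpoint distance, then input order; each
record used once), which makes the result deterministic and symmetric
in the number of merged records. Collapsed records keep the first
(alignment) callset's coordinates and carry both source labels.
Records below 50 bp (the conventional SV floor) are dropped on ingest.

Region annotation labels every SV by the highest-precedence feature
any of its bases overlaps: splice_region > exon > utr5 > utr3 >
intron > upstream2kb > downstream2kb > intergenic. "Exon" means coding
exon (CDS): if whole exons were used, the UTR labels beneath them
would be unreachable. Splice regions extend 8 bp into the intron and
3 bp into the exon at each internal junction — the standard
effect-annotation convention, since the study is silent. Flanks are
strand-aware. TE origin is decided by coverage: a deletion is a TE-PAV
when TE annotation covers ≥ 50% of the deleted interval, classed by
majority overlap; insertions are only testable when an annotation of
the inserted sequence itself is supplied, and are flagged untestable
otherwise.

## The stratification scan

Per-population allele frequencies are counted over non-missing
genotypes; loci missing above 50% or empty in any population are
dropped with a log entry. The default FST estimator is frequency-only,

FST = (p1 − p2)² / (p1 + p2 − 2·p1·p2),

defined as 0 where both populations are fixed; it lies in [0, 1] by
construction. A Weir–Cockerham estimator with sample-size correction is
available for sensitivity analysis (clipped to [0, 1]).

The di statistic for the target population is the sum over pairs
(target, j) of the FST standardized across loci within the pair:
di(l) = Σ_j (FST_l,j − mean_j) / sd_j. The underlying study's exact
definition lives in unavailable supplementary methods, so the standard
di construction is used, with the estimator and the sd convention
(sample sd, n−1, by default; denominator-n selectable) exposed as
arguments. Pairs with zero sd contribute nothing; di is invariant to
adding a constant to a pair's FST values.

Selection takes the top fraction q (default 5%): the threshold is the
k-th largest score with k = ceiling(q·n), and all loci at or above it
are selected, so ties come along and at least ceiling(q·n) loci are
always returned — a reproducible, conservative-inclusive rule. Gene
overlap uses half-open intersection after expanding genes by a window.

## Integration with expression and chromatin

`filter_degs()` applies strict thresholds |log2FC| > 0.59 and
padj < 0.05, mirroring the printed inequality. `candidate_svs()`
requires a locus to be selected *and* to intersect a DEG's gene
interval padded ±5 kb — strand-ignored, since the phrase "upstream or
downstream" is symmetric; whether the window should anchor on gene
boundaries or TSS/TES is unstated, and gene boundaries were chosen.
Peak support is plain half-open intersection with differential-peak
intervals. The dosage-effect test contrasts the expression of genes
with SVs in functional regions (2-kb flanks, intron, exon, splice
region, UTRs) against genes without, per tissue, with a two-sided
rank-sum test. Genotype-frequency contrasts default to carrier
(dominant) coding — the fraction of samples with dosage ≥ 1 — with
recessive and allelic codings selectable, because the published
"genotype frequencies" do not state their coding; the two populations
are compared with a two-sided Fisher exact test.

The stand-in DE test for synthetic counts uses median-of-ratios
normalization, a per-gene rank-sum test (exact where group sizes and
ties permit) and BH adjustment, with log2 fold-changes of group means
plus a 0.5 pseudocount. It is deliberately plain: it exists so the
integration stage is testable end to end, not as a general-purpose DE
method.

## GWAS, LD and genomic selection

`gwas_scan()` fits least-squares y ~ dosage per marker after excluding
markers with MAF < 0.01 or missingness > 0.1 and mean-imputing the
rest; covariates, when given, are projected out of both sides
(Frisch–Waugh), so no structure correction is applied by default — the
intended context is a designed F2 cross. `ld_profile()` computes R² as
the squared Pearson correlation of dosage vectors for SNPs within a
half-open ±500 kb window around each SV.

`gs_cross_validate()` uses ridge regression on standardized dosages —
the penalized form of GBLUP with a genomic relationship built from the
same markers — with the shrinkage chosen by inner cross-validation
over a fixed log-spaced grid (10² down to 10⁻⁴ on block-normalized
predictors). Outer fold assignments are shared across panels, so
accuracy differences are paired. Accuracy is the Pearson correlation
of predicted and observed phenotype in held-out folds.

A combined panel passed as two blocks (SNP and SV) is fitted as a
*weighted two-kernel* model: each block is standardized and scaled to
a unit-trace relationship, and the relative block weight is chosen on
the grid {0, 0.25, 0.5, 0.75, 1} by the same inner CV. Plain ridge on
the concatenated matrix systematically penalizes the minority class:
when all QTLs sit on SV loci, the many uninformative SNP columns
dilute the genomic relationship and the combined panel falls well
below the SV-only panel, which contradicts the qualitative behaviour
the combined panel is meant to show (adding a marker class should not
cost accuracy). Weighted kernel combination is standard
genomic-prediction practice and lets the combined model fall back on
whichever class carries signal.

## Problem sizes and numerical choices

The bundled tests and the acceptance script run on scaled-down
instances chosen as the package's own defaults: presence matrices of
up to 25,472 families over 14 genomes, SV callsets of 200–800 records,
a 5,000-locus scan over 246 samples in three populations, and genomic
selection on 540 individuals with 600 SNP and 120 SV markers (QTLs on
SVs only, h² = 0.5, 20 QTLs, 5-fold outer CV). Degenerate inputs are
rejected rather than coerced: empty catalogs, all-zero family columns,
single populations, constant phenotypes and sub-50 bp records raise
errors; all-missing loci and sub-2-gene groups are skipped with a
message. Greedy-merge ties break by overlap, then breakpoint distance,
then input order, so results are reproducible to the byte.

## Known limitations

* Marker dosages are exchangeable within a population — there is no LD
  map — so LD summaries on synthetic panels reflect the null, not a
  decaying profile.
* The di reconstruction, the merge tolerances, the splice-region
  extents, the 5-kb anchor and the carrier coding are documented
  substitutes for supplementary-only details of the source study;
  each is a parameter, not a constant.
* The GWAS has no kinship/mixed-model correction and the GS model is
  ridge/GBLUP only; haplotype methods and Bayesian variable-selection
  models are out of scope.
* Insertion TE origin requires an annotation of the inserted sequence;
  without one the insertion share of TE-PAVs is reported untestable
  rather than guessed.
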