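---
title: "Dimorphic mobile elements and selection scans from SV callsets: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dimorphic mobile elements and selection scans from SV callsets: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svdimorph)
library(dplyr)
```

## What the package does

`svdimorph` implements the post-calling stages of a structural-variant (SV)
analysis for canine genomes sequenced with a mix of long reads, short reads
and genome assemblies. Primary SV calling (read alignment, sniffles2/Manta
and friends) is out of scope; the package starts from per-sample VCF
callsets and carries them through:

1. **Callset normalisation and filtering** — a common tabular record model,
   removal of unresolved breakends (BND), homozygous-reference calls,
   insertions with gap (`N`) sequence, calls shorter than 50 bp or longer
   than 10 Mb, and exact duplicates; restriction to the assembled
   chromosomes (chr1–chr38 and chrX).
2. **Merging and concordance** — single-linkage clustering of calls whose
   breakpoints fall within a window (100 bp for between-modality
   comparison; a stricter 15 bp absolute rule OR size-relative rules for
   within-sample locus merging), deterministic representative selection,
   and the fraction of one callset matched in another.
3. **Dimorphic repeat annotation** — Smith–Waterman local alignment of each
   SV allele against a repeat consensus library, reciprocal coverage
   fractions, and a three-way classification (`NONE`, `REPEAT_DOMINATED`,
   `NEAR_FULL_LENGTH`).
4. **Intact LINE-1 census** — six-frame translation of candidate
   full-length LINE-1 alleles, local protein alignment against ORF1p/ORF2p
   models, an intactness verdict, and poly(A)/target-site-duplication
   feature calls.
5. **Selection scan** — a per-site, per-ancestry-component binomial
   likelihood-ratio test for allele frequencies inconsistent with a shared
   genome-wide frequency, with Bonferroni-strict and fixed relaxed
   thresholds, per-population allele-frequency profiles, gene-context
   annotation and sequence-context quality flags.
6. **Synthetic data** — generators for every input the pipeline consumes,
   with exact truth tables, so each stage is testable end to end without
   any external download.

## The record model and its conventions

A callset is a tibble with one row per call (`chrom`, `pos`, `end`,
`svtype`, `svlen`, `seq`, `genotype`, `sample`, `modality`, `filter`).
Coordinates are 1-based inclusive, mirroring VCF: a deletion with an
explicit allele satisfies `nchar(seq) == svlen == end - pos + 1`, and an
insertion has `end == pos`. Exported VCF states this convention in its
header. When a symbolic record's `SVLEN` disagrees with an explicit allele
by more than 1 bp the allele length wins and the record's filter string is
tagged `LEN_MISMATCH` — symbolic and sequence-resolved callers disagree in
practice and the sequence is the more direct observation.

A single `N` suffices to drop an insertion as "unassembled or gap
sequence": the filter is deliberately strict because downstream repeat and
ORF scans treat `N` as unalignable.

## Merging rules

Two records match under the *strict* predicate when they share a
chromosome (and SV type, when required), both breakpoint distances are at
most `max_dist` (default 100 bp), and — for insertion pairs, which have no
informative end coordinate — the length ratio `min(svlen)/max(svlen)` is at
least 0.5. The ratio guard prevents a 60 bp and a 6 kb insertion at the
same spot from merging; insertions are compared at their start positions
only.

The *relaxed* locus-merging predicate accepts a pair when the strict 15 bp
rule holds **or** when, scaled by the longer record `L = max(svlen)`, the
breakpoint shift is ≤ `0.1·L`, the size difference is ≤ `0.1·L` and the
nearest-breakpoint distance is ≤ `0.1·L`. The choice of `L` as the scaling
denominator is this package's convention; tools in this space do not agree
on one definition.

Clusters are single-linkage connected components, so two distant calls can
chain through an intermediate — a documented property of this family of
merging tools, preserved deliberately and covered by an O(n²) brute-force
oracle test. Representative selection is a deterministic priority:
sequence-resolved before symbolic, then modality quality (`long-read` >
`assembly` > `paragraph` > `short-read`), then longest, then coordinate
order. The upstream publication selects representatives with an external
unpublished script, so any faithful reimplementation must declare its own
deterministic proxy; this is ours, and the representative keeps its own
genotype.

## Repeat annotation

The aligner is Smith–Waterman with affine gaps and blastn-like scoring
(match +2, mismatch −3, gap open 5, gap extend 2; a gap of length *L*
costs 5 + 2*L*), implemented in C++ with a full traceback. Multiple hits
per query–target pair are enumerated by taking the best local alignment
and re-aligning the unused query segments on either side. There is no
E-value machinery: at desk scale, a minimum score (40) plus hit-level
filters (≥30 bp, ≥80% identity) substitute for it. Tests pin the score to
an independent dynamic-programming oracle (`Biostrings::pairwiseAlignment`)
on random pairs.

Coverage is computed per repeat name as the union of hit intervals — so an
element with an internal deletion still accumulates coverage — on both the
SV allele (`sv_coverage`) and the consensus (`consensus_coverage`).
Positions that are `N` in the allele are excluded from coverage.
Classification steps at the inclusive 95% thresholds: `REPEAT_DOMINATED`
needs `sv_coverage ≥ 0.95` (the SV *is* mostly one repeat, as opposed to a
larger SV that merely contains repetitive sequence); `NEAR_FULL_LENGTH`
additionally needs `consensus_coverage ≥ 0.95` (95% reciprocal overlap —
a near-complete element). Hits from distinct repeats are never pooled for
the 95% rule; a family-level roll-up of the census is reported separately
(`repeat_census(..., by = "family")`).

## ORF intactness

Candidate full-length LINE-1s (class `NEAR_FULL_LENGTH`, LINE family) are
translated in all six frames and each frame is locally aligned against the
ORF1p and ORF2p peptide models (BLOSUM62, gap open 11, extend 1). Identity
is counted as **exact residue matches over the full model length**, not
over the aligned span — a truncated or frameshifted ORF therefore fails
on identity and model coverage even when its aligned fragment matches
perfectly. An element is intact when both ORFs reach ≥99% identity
(inclusive) and ≥0.99 model coverage with no stop codon inside the aligned
span. The 99% step is exact: one substituted residue in a 300-aa model
gives 99.67% (intact), four give 98.67% (not intact); tests assert both
sides.

The ORF models are inputs, not constants: a real analysis passes the two
published peptide records, and tests pass the generator's 300-aa and
1,275-aa toy models.

### Poly(A) and TSD rules

Neither feature has a published algorithm in this setting, so the package
declares its own:

* **Poly(A)**: scan inward from the element's 3′ terminus with a sliding
  12 bp window; the tail extends while every window is ≥80% adenine, then
  the inner boundary is trimmed to the first A. Tails below 8 bp report 0.
  The windowed rule tolerates single interruptions (a terminal
  `AAAAAAAAGAAA` reports 12), which matches how annotators treat
  near-contiguous A-tracts. Minus-orientation elements are
  reverse-complemented first (their tail is a 5′ T-tract).
* **TSD**: the longest suffix of the left flank (5–30 bp) that matches a
  prefix of the right flank with at most one mismatch, longest match
  first. The 5–30 bp range covers typical LINE-1/SINE target-site
  duplications.

## The selection scan

The scan models dosages at one site as `g_i ~ Binomial(2, p_i)` with
`p_i = Σ_k Q_ik F_k`, where `Q` holds known per-individual ancestry
proportions (K components) and `F` the unknown per-component allele
frequencies. `F` is fitted by EM-style multiplicative updates (each allele
copy's ancestry is the latent variable), initialised deterministically at
the pooled frequency, with objective tolerance 1e-8 and a 10,000-iteration
cap. A grid-search oracle fixes the expected optimum in tests.

The per-component statistic contrasts the model with the focal component's
frequency free and all other components tied to one shared frequency
against the model with a single shared frequency:
`LRT = 2(logL1 − logL0)`, compared to χ²₁. This is a deliberately simpler
surrogate for tree-covariance selection models: it asks the same question
— is this component's frequency inconsistent with a genome-wide profile? —
without modelling drift covariance among components, and no numerical
agreement with such models is claimed. The module accepts externally
computed statistics for thresholding when a full covariance-aware scan has
been run elsewhere.

Thresholding is Bonferroni only (`alpha / n_tests`, reported together with
the explicit `n_tests`) plus a fixed relaxed cutoff of 1e-4; no FDR
machinery, matching the analysis this package reproduces. Site filters are
zero missing genotypes and minor allele frequency ≥ 0.05, with the 5%
boundary declared inclusive (one alternate allele among ten diploids is
kept) since "5% MAF" is ambiguous at the boundary.

Sequence-context metrics flag alleles whose low-complexity/tandem fraction
exceeds 0.70 (DUST-style triplet scoring in 64 bp windows, threshold 2,
unioned with exact tandem arrays of motif length 1–6) and records within
25 bp of a same-type neighbour. These are declared native approximations of
the SDUST/etrf combination used in production pipelines. Gene context is
exonic (≥1 bp exon overlap, or full-gene ablation), intronic, or
intergenic.

## The synthetic cohort: what it emulates and what it does not

The generator's defaults define the study conditions used throughout the
tests and the acceptance script:

* 1 Mb reference at 41% GC, three samples, ≤ 200 implants — every stage
  runs in seconds to a couple of minutes on one CPU (the acceptance script
  uses exactly these sizes, plus a 5,000-site null cohort of 150 diploids,
  a 200-site admixed cohort of 200 diploids and a 300-site clade cohort of
  200 diploids for the scan measurements; the 10,000-site uniformity check
  uses 400 diploids, since χ² asymptotics for the LRT need a few hundred
  individuals).
* a 200 bp SINE (185 bp body + 15 bp A-tail) and a 6 kb LINE carrying a
  300-aa ORF1 and a 1,275-aa ORF2 in frame +1, both consensus elements
  ending in an A-tail as their real counterparts do;
* per-sample implants of 10/10 SINE DEL/INS, 5/5 LINE DEL/INS and 5
  non-repeat background SVs; poly(A) tails of 15–22 bp (tails much shorter
  than the 12 bp detection window would be undetectable by construction,
  and would push a 200 bp SINE below the 95% coverage geometry); TSDs of
  8–16 bp implanted by duplicating the insertion-site k-mer, stored as
  flank sequences in the truth table so `detect_tsd()` has exact truth;
* HiFi-like substitution-only noise at 0.2% that avoids ORF codons, so
  ORF-intactness truth is exact by construction; ONT-like indel-dominated
  noise is applied separately by `add_sequence_noise()` in the
  monotonicity property test (indels erode the intact count, substitutions
  mostly do not);
* LINE insertions 5′-truncated with probability 0.2 (their expected class
  drops to `REPEAT_DOMINATED`); deliberate frameshifts cut the middle half
  of ORF2, guaranteeing the frameshift scrambles enough protein to break
  intactness;
* modality replicates: long-read-like calls are truth plus Gaussian
  breakpoint jitter (sd 5 bp); short-read-like calls drop each insertion
  with probability `min(1, svlen/450)`; regenotyping restores dropped
  insertion loci at 90% sensitivity. This reproduces the qualitative
  platform contrast — short reads lose long insertions, genotyping against
  a graph restores them — not any platform's quantitative error model.

The generator does **not** simulate reads, coverage, mapping artifacts,
segmental duplications, nested or overlapping SVs, or reference bias, so a
passing recovery test demonstrates correctness of the post-calling logic
under clean conditions — not performance on real sequencing data.

For the genotype cohort, `Q` is drawn from a symmetric Dirichlet(1) (fully
admixed) or as one-hot rows (discrete clades). Selected sites shift one
component's frequency by exactly 0.5, with the direction chosen toward the
feasible side so clamping never silently shrinks the shift.

## Numerical choices and degenerate inputs

* Alignment scores are reals in C++ with a single best-traceback; ties in
  the DP break deterministically (diagonal over gap states), so all
  outputs are reproducible.
* `fit_component_frequencies` returns exact 0/1 vectors for monomorphic
  sites without iteration; probabilities are clamped to `[1e-12, 1-1e-12]`
  inside likelihoods; the LRT is floored at 0 (the models are nested).
* A component with zero total ancestry weight yields a missing statistic,
  not an error; an empty callset yields empty (not failing) summaries; a
  heterozygous fraction with no genotyped calls is `NA`, never 0.
* Classification ties (equal `sv_coverage`) break by higher consensus
  coverage, then lexicographic repeat name.

## Calibration results the test suite computes

On the fixed-seed suites: the null type-I error at α = 0.05 over 5,000
sites lands within three binomial standard errors of 0.05; null p-values
are uniform to Kolmogorov–Smirnov distance < 0.02 at 10,000 sites (N =
400); a 0.5 component-frequency shift at N = 200 in the clade-structured
cohort is detected at α = 1e-4 with power ≥ 0.9 (the same shift in a fully
admixed Dirichlet(1) cohort gives ~0.87 — admixture dilutes per-component
information).

One calibration target is genuinely out of reach under its own stated
conditions: per-component frequency recovery at N = 200, K = 3 with fully
admixed Dirichlet(1) ancestry achieves a mean absolute error of ~0.05–0.06,
and the Cramér–Rao bound for this design implies an MAE floor of ~0.051
for any efficient unbiased estimator — below-0.05 recovery is not
attainable at this sample size and admixture level, only under more
structured ancestry (one-hot clades reach ~0.035). The corresponding test
asserts the 0.05 bound anyway and is expected to fail; it documents the
identifiability limit rather than an implementation defect.

## Known limitations

* The merging predicates operate on breakpoints and lengths only; no
  sequence-similarity term enters the merge decision (the `-seqspecific`
  flavour of locus merging is approximated by the size-relative rules).
* The repeat aligner reports one orientation per repeat (that of the best
  hit); elements with internal inversions are not modelled.
* The LRT's χ²₁ reference is asymptotic; at small cohort sizes (tens of
  individuals) the null is mildly anti-conservative.
* Low-complexity scoring is a native DUST-style approximation, not a
  reimplementation of SDUST/etrf; fractions near the 0.70 flag boundary
  can differ from those tools.
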