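---
title: "Multiregion exome analysis of intratumoral heterogeneity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiregion exome analysis of intratumoral heterogeneity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ithexome)
```

## The study design this package models

`ithexome` analyses whole-exome sequencing of *sample trios*: for each
patient, a non-tumor control, a sample from the tumor center and a sample
from the tumor periphery. Comparing the somatic mutations of the two tumor
regions quantifies intratumoral heterogeneity (ITH): mutations present in
both regions are *common* (trunk), mutations validated as present in only
one region are *private* (branch). The same trio design supports a
read-depth copy-number comparison of the two regions against a panel of
reference exomes.

All stages run on tabulated evidence (per-sample depth, variant-read count
and mapping quality per site; per-bin read counts for coverage). Read
alignment, variant calling itself and consequence prediction happen
upstream and are out of scope: this package models the decision rules that
turn candidate calls into a reproducible ITH analysis.

## Somatic filtering

Candidate SNVs are kept only when, in the tumor region under test:

1. mapping quality ≥ 20,
2. variant allele frequency ≥ 5%,
3. total depth ≥ 10 in both tumor and non-tumor sample,
4. ≥ 2 tumor variant reads,
5. ≤ 1 non-tumor variant read,
6. no candidate indel within 5 bp, and
7. not more than 2 SNVs in any 10-bp window.

Candidate indels use their own four rules: depth ≥ 20 in both samples,
VAF ≥ 10%, ≥ 5 variant reads, and zero variant reads in the non-tumor
sample. Known polymorphisms (a site list consumed as a file) and sites
outside exon/splice-site intervals are excluded.

Design choices where the rules leave room:

* **Reasons are exhaustive.** Every violated rule is recorded; nothing
  short-circuits. Reject audits are part of the package's test surface
  (the cascade is checked against an independent brute-force
  re-implementation on random evidence).
* **The window rule removes all SNVs in an offending window**, not just
  the excess. Removing all is the unique order-independent choice.
* **Indel proximity** is measured to the indel's leftmost affected base
  (the VCF anchoring norm).
* **Rules are evaluated per tumor region independently.** A site may pass
  in the periphery and fail in the center; clonality is decided later by
  cross-interrogation, not by the filter.

Thresholds live in `filter_config()` and are all inclusive exactly as
stated above.

## Clonality classification

A mutation passing filters in both regions is common outright. One passing
in a single region is *cross-interrogated*: the other region's raw
evidence is checked for supporting reads. Presence requires ≥ 2 variant
reads at depth ≥ 10 — two reads mirrors the somatic-evidence minimum of
the filter itself and guards against single-read sequencing error; with
depth < 10 the mutation is labeled `unresolved`, because absence cannot be
asserted without coverage.

Candidates absent from the other region are confirmed against orthogonal
per-site AF re-measurements (a pyrosequencing-style assay): a private call
is *confirmed* when the harboring region's AF exceeds the non-tumor AF by
≥ 5 percentage points while the other region's does not; *refuted* (and
relabeled common) when both regions exceed; *failed* (and relabeled
`unresolved`, the likely-artifact outcome) when the harboring region
itself does not exceed; and *untested* (kept private) when no measurement
exists. `failed` is a deliberate extension of the confirmation vocabulary:
a binary confirmed/refuted cannot express the artifact case that
validation exists to catch.

Summary statistics report, per sample, common/private counts, the private
fraction, and median VAFs. The median VAF of a private mutation uses the
harboring region; for a common mutation the mean of the two regions' VAFs
enters the median (the convention is not fixed by the analysis being
modeled, so the symmetric choice is used and exposed here).

Substitution spectra collapse the 12 ordered single-base changes onto the
6 strand-paired classes (C>T/G>A, C>A/G>T, C>G/G>C, T>C/A>G, T>A/A>T,
T>G/A>C). The CpG fraction is computed among C>T/G>A events only: a C>T
with G immediately 3′ of the mutated C, or a G>A with C immediately 5′,
on the plus strand. Records lacking context are excluded from both
numerator and denominator and counted separately.

## Driver tiering

A curated gene list (recurrently mutated genes, high-frequency biliary
tract genes, cancer gene census) is matched against non-synonymous
mutations. Matched mutations are tiered with strict precedence:

* `high_confidence` — the exact amino-acid change is known, or its SIFT
  score is < 0.05 (strict), or it was promoted by manual review;
* `putative` — the residue lies within 5 amino acids (inclusive) of a
  known mutation in the same gene;
* `unknown` — gene match only.

Proximity is measured in **amino-acid residues**, not base pairs: every
affected record is annotated at residue level, and residue distance is the
unit the tier labels themselves use. Splice-site and frameshift records
without a parseable residue can reach tiers only via exact string match or
manual promotion. "Known mutation" means the exact (gene, amino-acid
change) pair; same-position-different-change coincidences are counted
separately in the call attributes rather than silently upgraded.

The packaged knowledge-base files are **synthetic stand-ins** (see
`inst/extdata/*_synthetic.tsv`): the original curated extracts are not
redistributable, so the fixtures were constructed to carry the same
structure and to let the packaged driver table re-derive its tiers from
its stated reasons.

## Read-depth copy-number model

A panel of at least 10 reference exomes, each scaled to the panel's mean
total count, yields per-bin expected coverage mean and SD. The panel
absorbs capture, GC and library biases, so no explicit bias regression is
performed; the synthetic generator correspondingly shares one
multiplicative per-bin bias field between panel and samples.

A sample is scaled to the same target total and then **recentered by the
median per-bin ratio to the expected mean**. The recentering matters: a
large copy-number event contributes to the sample's total count, and pure
total-count scaling would drag the diploid baseline off zero by several
percent — enough to flood a 2-SD screen with false bins. The median over
the (diploid-majority) bins pins the baseline instead; the profile remains
invariant to uniform scaling of a sample's counts.

Bins deviating by ≥ 2 SD from the model mean, in runs of ≥ 5 consecutive
same-sign bins, form segments (`min_bins = 5` suppresses isolated
outliers; the method calls *regions*, not single bins). Each segment's
mean percent deviation is interpreted against the copy-state grid
cn ∈ {0, …, 4} via the closed form

```
expected_deviation(cn, t) = 100 · t · (cn − 2) / 2
```

with `t` the tumor content (1 for germline calling): +50% for a
heterozygous duplication in pure material, +30% at 60% tumor content. If
exactly one clonal state matches within the concordance tolerance, that
state is called; otherwise every mathematically consistent interpretation
at a smaller clonal fraction — subclonal in the tumor, or carried by the
non-tumor fraction — is listed and the call is `ambiguous` (a +20%
deviation at 60% purity lists both a subclonal duplication at fraction
0.4 and a non-tumor heterozygous duplication). The tolerance defaults to
`max(10, mean(100 · min_sd · sd/mean))` over the segment's bins, coupling
it to panel noise, and is compared strictly.

Masking: bins with near-zero panel coverage lose both deviation and
z-score; bins with zero panel SD (a degenerate, noise-free panel) keep
their deviation but are uncallable. Median smoothing over tumbling 5-Mb
windows is presentation-only — calling always operates on unsmoothed
deviations. Center/periphery comparison disjoins the two segment sets and
flags every interval where the calls differ.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream stage is validated.

* **Scale.** Four trios plus a 10-sample reference panel on a 3 × 60 Mb
  genome with 100-kb coverage bins and regularly spaced 300-bp exons —
  large enough to resolve multi-megabase events with hundreds of bins,
  small enough for seconds-scale tests.
* **Mutations.** ~24–41 common non-synonymous mutations per trio, 0–14
  private, ~9–14 silent; all clonal (cancer-cell fraction 1). One trio
  carries a hypermutator peripheral region: an inflated private count with
  a C>A/G>T-dominated spectrum and a planted private MSH6 missense
  mutation, emulating a mismatch-repair-deficient region. Planted driver
  mutations (KRAS, IDH1, EPHA2, BAP1, SRC, MSH6) receive their field
  notation so the driver stage has realistic input.
* **Spectrum.** Default class weights put 0.48 on C>T/G>A with 0.45 of
  those at CpG; the five remaining classes share the rest with transitions
  favored (0.18 on T>C/A>G), a standard shape for C>T-dominated solid
  tumors. The hypermutator weights move the mode to C>A/G>T (0.45).
  Trinucleotide contexts are written directly at planting time — context,
  not sequence, is what downstream consumes — which makes the CpG
  bookkeeping exactly testable.
* **Purity.** Central 0.35–0.45, peripheral 0.45–0.55 per trio: the
  peripheral sample is slightly purer, reflecting stronger desmoplasia in
  the tumor center, and the mean sits near the histology-estimated tumor
  content of the modeled study (~47%). Expected VAF follows
  `purity · ccf · multiplicity / (purity · local_cn + (1 − purity) · 2)`,
  so a clonal het mutation at purity 0.5 sits near VAF 0.25.
* **Noise.** Per-site depth is negative-binomial around a mean of 109
  (the modeled cohort's mean target coverage) with extra-Poisson
  dispersion 0.01; variant reads are binomial given depth and expected
  VAF plus Poisson spurious reads at 10⁻³ per base; per-bin coverage uses
  dispersion 10⁻³ (a few percent CV on ~10⁵-read bins, typical of exome
  bins after normalization); orthogonal AF re-measurements add truncated
  Gaussian noise with SD 0.02. Dispersion 0 is the exact noise-free limit
  (draws equal their means), which gives the end-to-end identity used in
  testing: with all noise at zero, the filter passes exactly the planted
  somatic set.
* **Truth.** Every cohort serializes its full ground truth (mutation
  clonality, CNV segments, purities), sufficient to score any stage
  without re-running the generator.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: alignment and mapping artifacts beyond a
scalar mapping quality, strand bias, germline contamination of the normal,
subclonal mutations (all planted events are clonal within their region),
focal or high-level amplifications beyond cn 4, GC-dependent bias that
differs between panel and sample, and real genome architecture
(segmental duplications, low-complexity regions).

## Problem sizes and numerical conventions

Tests and property checks run at deliberately chosen sizes: spectrum and
CpG recovery at 10,000 planted events (three binomial SDs); private
fractions {0, 0.10, 0.583} pooled over 20 seeded cohorts; copy-number
recovery over 50 seeded replicates of ≥ 5-Mb events at purity 0.4 with
success defined as correct state and breakpoint error ≤ 1 bin. Clinical
descriptive means round half-up to one decimal (matching the printed
convention of the modeled tables; base R's round-half-even would differ).
Coordinates are 1-based inclusive in memory and in TSV artifacts, 0-based
half-open in BED/bedGraph exports, converted only at the file boundary.
Output headers carry the package version and a config checksum; no
timestamps, so identical config and seed reproduce byte-identical
artifacts.

## Known limitations

* Clonality is binary per region; there is no cancer-cell-fraction
  clustering, phylogeny, or mutational-signature deconvolution.
* The copy-number caller has bin-level resolution, a cn 0–4 grid, and no
  allele-fraction (BAF) evidence; amplifications above cn 4 surface as
  `ambiguous` with the nearest grid states.
* Exome-based coverage calling carries no information about non-coding
  regions; breakpoints are only as precise as the bin width.
* The driver knowledge base is a packaged synthetic fixture; swap in
  institutional extracts via `compile_driver_list()` for real use.
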