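---
title: "Methods: paired tumor-normal panel analysis for CNS tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired tumor-normal panel analysis for CNS tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliopanel)
```

`gliopanel` analyzes targeted DNA panel sequencing of CNS tumors from
per-locus paired read counts. This vignette documents the statistical
models, the thresholds and their provenance, the simulator that stands in
for patient data, and the design choices made where the published assay
description left the procedure open.

## Input model and panel

The pipeline's atomic input is a `PairedSiteCounts` row: chromosome,
1-based position, ref/alt alleles, tumor ref/alt read counts, matched
normal ref/alt counts and mean base quality. Everything upstream
(alignment, deduplication, pileup) is out of scope; everything downstream
is deterministic given these counts.

The packaged panel (`default_panel()`) defines 57 genes, 19 of which carry
intronic SNP backbones for gene-level CNV assessment, plus SNP backbones
on 3 chromosomal arms (1p, 19q, 10q) and 4 whole chromosomes (6, 7, 10,
17). Only the core neurooncology markers of the list are publicly
documented; the remainder pads the list with standard neurooncology panel
genes and the config is flagged `reconstructed: true` so provenance stays
honest. The identity of the third arm is not documented; we ship 10q
(PTEN context, where 10q LOH is diagnostically meaningful) — it is a
config choice, not a claim. Chromosome 17's backbone is laid out on both
sides of the centromere so that derived 17p/17q calls (isodicentric 17q)
are available. Intervals are 0-based half-open internally and in BED;
positions are 1-based at the counts/VCF boundary, matching each format's
standard.

One deliberate deviation from a literal round-trip reading: BED cannot
carry gene roles or SNP backbones, so the identity round-trip is provided
by the YAML exporter (`export_panel()` → `load_panel()`), while
`export_bed()` exports intervals and backbone positions for genome
browsers and intersection tools.

## Somatic small-variant calling

Both samples are genotyped from VAF bands (hom-ref < 0.05, het 0.05–0.90,
hom > 0.90) and tumor alt-read enrichment is tested with a one-sided
Fisher exact test on the 2×2 table (tumor alt/ref vs normal alt/ref),
computed as the exact hypergeometric tail. A site is **somatic** when

* normal VAF ≤ 0.05 (`max_normal_vaf_for_somatic`),
* tumor VAF ≥ 0.10 (`min_vaf_somatic`, inclusive at the boundary), and
* one-sided p < 0.05 (`p_threshold`).

The 10 % VAF floor is the assay's sensitivity-defining constant; the
false-positive filter re-applies it and additionally requires ≥ 4 tumor
alt reads and mean base quality ≥ 20. These two auxiliary defaults are
documented knobs (`caller_thresholds()`), not published constants. No
multiple-testing correction is applied across loci — the per-site
threshold matches the source tool chain's behavior and is stated here as
a limitation. This caller is a behavioral approximation of a paired
pileup genotyper, not a re-implementation of any specific tool.

Diagnostic hotspots (TERT promoter −124/−146, IDH1 R132, IDH2 R172, BRAF
V600, H3F3A K27/G34) are additionally re-reported threshold-free with
their raw VAFs (`hotspot_report()`), so a low-coverage or sub-threshold
hotspot is never silently dropped.

Germline calls are flagged `MUTGER` when rare in the reference population
(non-Finnish European MAF < 0.01 **and** < 5 homozygotes, both strict);
common polymorphisms are suppressed. Effect classification (`TRU`
truncating vs `MUT` missense-type) uses indel-length arithmetic
(frameshift vs in-frame) plus an optional annotation column for
stop-gain/splice consequences, which cannot be derived from counts alone;
promoter variants are `MUT`. Every indel carries a `needs_visual_review`
flag, mirroring routine IGV review practice.

## LOH detection

Site eligibility reads the published filter verbatim: normal VAF within
[0.30, 0.60] (closed interval — "between 30 and 60 %" read inclusively),
strictly more than 20 alt reads in the normal and strictly more than 20
total tumor reads. For eligible sites the ratio r = VAF_tumor /
VAF_normal calls LOH when r > 1.35 or r < 0.67, both strict. The ratio
uses the alt-allele VAF as emitted, without folding to minor-allele
frequency: deviation in either direction is caught by the two-sided
bounds, and the eligibility window excludes VAF 0, so r is always
defined.

Region aggregation is **this package's rule**, because the published
description stops at the site level: a region needs ≥ 5 eligible SNPs to
be informative (otherwise NA), and is LOH when ≥ 60 % of its eligible
SNPs are LOH. Both knobs live in `loh_params()`. 1p/19q codeletion is the
tri-state conjunction of the two arm calls.

## Copy-number analysis

Per-locus log2 ratios are library-size normalized:
log2((t_d/T)/(n_d/N)) with T, N the sample-wide depth sums, loci with
< 10 normal reads dropped, and values clamped to ±4. A consequence worth
stating: when a large fraction of the genome is aberrant, normalization
shifts all ratios by a constant. This is exactly why calls are made
relative to a per-sample baseline, and why the baseline is
shift-equivariant (a property test asserts it). Simulator closed-form
checks therefore compare contrasts against copy-neutral loci rather than
absolute means.

Segmentation is a seeded, permutation-tested recursive binary split: the
best split maximizes the two-sample t statistic; it is accepted when a
permutation p-value (499 permutations, seeded; minimum attainable p
0.002) is below 0.01 and both sides keep ≥ 5 loci. This is an intentional
simplification of circular binary segmentation that keeps the package
dependency-free at this stage and bit-reproducible; users with their own
segmenter can pass a SEG file, which is used verbatim.

The per-sample baseline operationalizes "size-sorted segments, LOH
considered": segments overlapping LOH-called regions are excluded (an
allele loss shifts depth and would drag the baseline), remaining segments
are sorted by genomic length descending and accumulated until ≥ 50 % of
total segmented length, and the baseline is their length-weighted median
log2 ratio. If exclusion leaves < 50 % (e.g. genome-wide LOH) the
exclusion is dropped and reported (`used_loh_exclusion = FALSE`). The
stopping fraction, the weighting and the median are this package's
operationalization — the published description names only the
size-sorting and the LOH input — and all are exposed. A documented
consequence of any per-sample baseline: in a genome where 60 % of the
covered length sits at a pervasive single-copy loss, that loss *is* the
baseline and the remaining normal regions are called gained relative to
it (a unit test pins this behavior).

Thresholds are interpreted on the log2 scale, where the published
constants match conventional practice:

| level  | BALANCED        | AMP / DEL                  | HIGHCOPY / HOMDEL |
|--------|-----------------|----------------------------|-------------------|
| region | \|Δ\| ≤ 0.4     | strictly beyond ±0.4       | —                 |
| gene   | \|Δ\| < 0.5     | 0.5 ≤ \|Δ\| ≤ 1 (inclusive)| strictly beyond ±1|

Boundary placement follows the published wording: regions change state
strictly beyond ±0.4 ("more than"), genes are relevant *from* |Δ| = 0.5
("starting with a cut-off of"), and escalation to HIGHCOPY/HOMDEL is
strict beyond ±1. Whole-chromosome interpretation rules (7 gain + 10
loss) require non-partial calls; mixed-state regions are reported with a
`partial` flag (AMPp/DELp vocabulary) and routed to review rather than
auto-interpreted.

## Rule engine

The interpretation layer is a pure function of the case profile
(gene categories, region states, hotspot flags). Decision order for
gliomas: H3K27M → midline glioma WHO IV; IDH-mutant + 1p/19q codeleted →
oligodendroglioma; IDH-mutant → astrocytoma with a CDKN2A-homozygous-loss
grading flag; IDH-wildtype with TERTp, EGFR HIGHCOPY or 7+/10− → diffuse
astrocytic glioma with molecular features of glioblastoma, WHO IV —
restricted to diffuse-glioma histology; the same markers under pilocytic
histology yield a review flag, not a reclassification. BRAF V600E without
high-grade markers flags the ganglioglioma / pediatric-type LGG
differential. Conflicting markers (IDH + K27M) produce a note, never an
exception, and every evidence entry cites only alterations actually
present in the profile.

Medulloblastoma subgrouping gives WNT precedence (CTNNB1 mutation or
monosomy 6) over SHH (PTCH1/SUFU/SMO alteration, or TERT-promoter
mutation alone — SHH-specific in this entity; switchable via
`tertp_implies_shh`), subdivided by somatic TP53 status; 17q gain,
isodicentric 17q and chromosome 7 gain support — but never assign — the
non-WNT/non-SHH group. The eight packaged reference profiles
(`mb_reference_profiles()`) regression-lock the rules at 1 WNT / 4 SHH /
3 non-WNT/non-SHH; the per-case TP53 status of the SHH cases is not
publicly printed, so the fixtures leave it unset and the subgroup
defaults to the TP53-wildtype branch.

Meningioma risk reporting flags the unfavorable constellation (1p loss,
CDKN2A loss, TERTp) and the favorable mutation profile (TRAF7, KLF4,
AKT1, SMO); CNV complexity counts non-balanced region calls plus relevant
gene CNVs, with `high_complexity` at ≥ 7 events — an operating choice
anchored to observed high-risk cases, explicitly not a validated clinical
cut-off. Therapy annotation emits entries for non-germline alterations in
genes carrying `targetable`/`resistance` roles in the panel config;
MUTGER never emits.

## The simulator: what it emulates and what it does not

`simulate_case()` draws locus depth from a negative binomial
(`mean_depth` 500, dispersion 0.05 by default — amplicon panels are
overdispersed), scales tumor depth by the local copy ratio
((1−ρ)·2 + ρ·C)/2, and draws alt counts binomially around the purity
mixture VAF ((1−ρ)·g + ρ·a) / ((1−ρ)·2 + ρ·C). Backbone SNPs are
heterozygous with probability 0.5; for CNV/CN-LOH events the alt allele
sits on the affected haplotype with probability 1/2 per SNP. FFPE
deamination is modeled as tumor-only C>T artifacts (2 % of quiet loci,
mean VAF 3 % — deliberately below the 10 % filter so the filter is
exercised). Defaults are the assay's stated operating point
(microdissected FFPE tumors, matched blood normals, deep amplicon
coverage); where no value is stated (dispersion, artifact rate) they are
fixed once at values realistic for such assays.

Not modeled: read-level errors, mapping or strand artifacts, GC bias,
tumor-in-normal contamination, subclonal CNV mixtures, and multi-allelic
sites. Passing the recovery tests therefore demonstrates correctness of
the *calling logic under the stated count model*, not clinical
performance on real FFPE libraries — the published real-data concordance
figures (e.g. LOH 90 %/97 % against an orthogonal array) are not
reproducible from synthetic data and are not claimed.

## Determinism and numerical conventions

Every stochastic step (simulation, segmentation permutations) consumes an
explicit seed through an RNG-state-preserving wrapper, so identical
inputs give bit-identical outputs; the test suite asserts byte-identity
of two full pipeline runs, the analogue of re-running an assay in
independent cycles and demanding identical reports. Percentages are
rounded half-up to the printed precision (whole percent for cohort
tables, one decimal for coverage). Degenerate inputs: zero-coverage sites
are `ambiguous`, never errors; empty regions yield NA calls; the
purity-mixture VAF at a zero denominator returns the flagged convention
value (1 if mutant material is retained, else 0).

## Test problem sizes

The suite runs at desk scale by choice: exhaustive Fisher verification
over all 2×2 tables with n ≤ 40 (135,751 tables against an
log-binomial enumeration oracle); Monte-Carlo closed-form checks on
250-SNP toy chromosomes; parameter recovery on 25 simulated replicates
per scenario (LOH at purity 0.6, CNV at 0.8, both at depth 500, ≥ 30
SNPs per region) against sensitivity/specificity floors of 0.95/0.95
(LOH), 0.90/0.95 (CNV) and 0.95 (SNV, with zero sub-10 %-VAF survivors);
the whole suite completes in well under a minute.

## Known limitations

* Gene list beyond the documented core is reconstructed; swap in a real
  panel YAML for production use.
* The caller handles one alt allele per site and does no realignment or
  strand-bias modeling.
* Region LOH aggregation and the baseline stopping rule are documented
  stand-ins where the published description is silent.
* Diagnoses are advisory strings with evidence trails, not clinical
  verdicts; WHO grading is emitted only where the rules print it.
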