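# gliopanel

Paired tumor–normal DNA panel analysis for CNS tumors, starting from
per-locus read counts.

Neuropathology labs increasingly need one assay that reports, per case, the
small variants (IDH1/2, TP53, TERT promoter, BRAF, H3F3A, …), the
loss-of-heterozygosity status of diagnostic chromosomal arms (1p/19q), and
copy-number changes (EGFR high-copy amplification, CDKN2A homozygous loss,
chromosome 7 gain + 10 loss) that current integrated CNS-tumor diagnostics
require. `gliopanel` implements the computational tail of such a targeted
amplicon assay as a tested R pipeline: it consumes a table of tumor and
matched-normal allele counts per panel locus and produces somatic calls,
LOH and CNV calls, an integrated diagnostic interpretation, therapy
annotations, and an oncoprint-style alteration matrix — plus a purity-aware
simulator so that every stage can be exercised and validated without
patient data.

## Methods at a glance

* **Somatic small variants.** Per locus, tumor alt-read enrichment against
  the matched normal is tested with a one-sided Fisher exact test
  (hypergeometric tail). A site is somatic when the normal VAF is ≤ 0.05,
  the tumor VAF ≥ 0.10 and p < 0.05; a false-positive filter removes calls
  with VAF < 10 %, < 4 alt reads, or low base quality.
* **LOH.** Heterozygous SNPs are selected from the normal (VAF 30–60 %,
  > 20 alt reads in normal, > 20 total tumor reads). The ratio
  r = VAF_tumor / VAF_normal calls LOH when r > 1.35 or r < 0.67 (strict);
  a region is LOH when ≥ 60 % of its ≥ 5 informative SNPs are LOH.
* **CNV.** Library-size-normalized log2 tumor/normal depth ratios are
  segmented by a permutation-tested recursive binary split; the per-sample
  baseline is the length-weighted median of the largest segments
  (size-sorted, LOH-excluded, accumulated to 50 % of covered length).
  Regions are balanced within baseline ± 0.4; genes are called from
  |Δ| ≥ 0.5, escalating to HIGHCOPY / HOMDEL beyond |Δ| > 1.
* **Interpretation.** A rule engine maps the per-case alteration profile to
  integrated diagnoses (H3K27M midline glioma; oligodendroglioma,
  IDH-mutant and 1p/19q-codeleted; IDH-mutant astrocytoma with CDKN2A
  grading flag; IDH-wildtype glioma with molecular glioblastoma features
  via TERTp / EGFR HIGHCOPY / 7+10−), medulloblastoma subgroups
  (WNT > SHH ± TP53 > non-WNT/non-SHH), meningioma risk flags, and
  targetable / resistance annotations from panel gene roles.

The packaged default panel covers 57 genes (19 with intronic SNP backbones
for CNV/LOH), 3 chromosomal arms (1p, 19q, 10q) and 4 whole chromosomes
(6, 7, 10, 17). The gene list is a documented reconstruction around the
core published markers (`reconstructed: true` in the YAML).

## Worked example

Simulate an oligodendroglioma-like case (70 % purity, depth 500: IDH1 R132
and TERT-promoter mutations, single-copy 1p and 19q losses) and run the
full pipeline:

```r
library(gliopanel)
panel <- default_panel()
events <- list(
  somatic_event("SNV", "IDH1_R132",   ccf = 1),
  somatic_event("SNV", "TERTp_C228T", ccf = 1),
  somatic_event("CNV_loss", "1p",  copies = 1),
  somatic_event("CNV_loss", "19q", copies = 1))
sim    <- simulate_case(panel, sim_config(purity = 0.7, mean_depth = 500, seed = 42), events)
report <- run_case(sim$counts, panel, context = "diffuse_glioma",
                   case_id = "case_01", seed = 42)
report
#> <case_report> case_01 (diffuse_glioma)
#>   somatic calls: 2 | LOH regions: 1p, 19q
#>   CNV baseline 0.083 | non-balanced regions: 1p, 19q
#>   diagnosis: oligodendroglioma, IDH-mutant and 1p/19q-codeleted
```

The two hotspot mutations are recovered near their expected mixture VAF of
0.7/2 = 0.35, and both arms are LOH in every informative SNP:

```r
subset(report$hotspots, name %in% c("IDH1_R132", "TERTp_C228T"))
#>          name t_vaf n_vaf t_depth
#>   TERTp_C228T 0.348     0     374
#>     IDH1_R132 0.371     0     464
subset(report$loh_regions, region %in% c("1p", "19q"))
#>   region n_eligible n_loh status
#>       1p         25    25    LOH
#>      19q         12    12    LOH
```

`report$qc$pct_at_depth` gives the percentage of panel loci covered at
1…1000 reads; `write_report_bundle(report, "out/", panel)` writes the VCF,
TSVs, SEG, oncoprint and JSON report. A thin command-line wrapper with
`simulate`, `run-all`, `panel-validate` and `panel-export-bed` subcommands
is installed at `system.file("cli", "gliopanel.R", package = "gliopanel")`.

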