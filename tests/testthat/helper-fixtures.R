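# Shared fixtures: all built in code, no stored data.

# Minimal panel with configurable SNP backbone density, for Monte-Carlo and
# segmentation tests where the default panel's per-region SNP count is too
# small.
toy_panel <- function(n_snps = 250) {
  cfg <- list(
    panel_name = "toy", genome_build = "hg19", reconstructed = TRUE,
    centromeres = list(chr1 = 125000000L, chr2 = 93300000L),
    genes = list(
      list(name = "GENE1", chrom = "chr1",
           intervals = list(list(start = 1000000L, end = 1100000L)),
           coverage_mode = "CDS", intronic_cnv_snps = TRUE,
           roles = list("diagnostic"),
           backbone_snps = as.integer(seq(1005000, 1095000, length.out = 10))),
      list(name = "GENE2", chrom = "chr2",
           intervals = list(list(start = 5000000L, end = 5050000L)),
           coverage_mode = "CDS", intronic_cnv_snps = FALSE,
           roles = list("targetable"))
    ),
    regions = list(
      list(name = "chr1", kind = "chromosome", chrom = "chr1",
           snp_loci = as.integer(round(seq(2e6, 240e6, length.out = n_snps)))),
      list(name = "chr2", kind = "chromosome", chrom = "chr2",
           snp_loci = as.integer(round(seq(6e6, 230e6, length.out = n_snps))))
    ),
    hotspots = list(
      list(name = "HS1", gene = "GENE1", chrom = "chr1", pos = 1050000L))
  )
  panel_from_config(cfg)
}

# Independent oracle for the one-sided Fisher test: explicit enumeration of
# the hypergeometric tail from log-binomial coefficients (no phyper).
fisher_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  k1 <- a + c             # total alt (column margin)
  r1 <- a + b             # tumor reads (row margin)
  ks <- max(0, k1 - (c + d)):min(r1, k1)
  logp <- lchoose(r1, ks) + lchoose(n - r1, k1 - ks) - lchoose(n, k1)
  sum(exp(logp[ks >= a]))
}

# Paired count row constructor for threshold tests.
site_row <- function(t_ref, t_alt, n_ref, n_alt, ref = "A", alt = "G",
                     mean_baseq = 36, chrom = "chr1", pos = 1000) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             t_ref = t_ref, t_alt = t_alt, n_ref = n_ref, n_alt = n_alt,
             mean_baseq = mean_baseq, stringsAsFactors = FALSE)
}

# LOH site rows at a controlled tumor/normal VAF ratio using exact counts.
loh_row <- function(ratio, n_vaf = 0.5, depth = 10000) {
  n_alt <- round(n_vaf * depth)
  t_alt <- round(ratio * n_vaf * depth)
  site_row(t_ref = depth - t_alt, t_alt = t_alt,
           n_ref = depth - n_alt, n_alt = n_alt)
}
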