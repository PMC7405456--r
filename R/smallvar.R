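# Paired tumor-normal small-variant calling on per-locus counts.

#' Caller thresholds
#'
#' @param min_coverage minimum total reads per sample to attempt a call.
#' @param min_vaf_somatic minimum tumor VAF for a somatic call (inclusive);
#'   default 0.10, the sensitivity-defining knob of the assay.
#' @param max_normal_vaf_for_somatic maximum normal VAF compatible with a
#'   somatic call.
#' @param p_threshold per-site one-sided Fisher p threshold (no
#'   multiple-testing correction across loci, matching the source tooling).
#' @param min_alt_reads minimum tumor alt reads surviving the FP filter.
#' @param min_baseq minimum mean base quality surviving the FP filter.
#' @return a `caller_thresholds` list.
#' @export
caller_thresholds <- function(min_coverage = 8, min_vaf_somatic = 0.10,
                              max_normal_vaf_for_somatic = 0.05,
                              p_threshold = 0.05, min_alt_reads = 4,
                              min_baseq = 20) {
  stopifnot(min_coverage >= 0, min_vaf_somatic >= 0, min_vaf_somatic <= 1,
            max_normal_vaf_for_somatic >= 0, max_normal_vaf_for_somatic <= 1,
            p_threshold > 0, p_threshold <= 1, min_alt_reads >= 0, min_baseq >= 0)
  structure(list(min_coverage = min_coverage, min_vaf_somatic = min_vaf_somatic,
                 max_normal_vaf_for_somatic = max_normal_vaf_for_somatic,
                 p_threshold = p_threshold, min_alt_reads = min_alt_reads,
                 min_baseq = min_baseq), class = "caller_thresholds")
}

#' One-sided Fisher exact test for a 2x2 count table
#'
#' Table layout: row 1 = tumor (alt `a`, ref `b`), row 2 = normal (alt `c`,
#' ref `d`). Returns the exact hypergeometric upper-tail probability of
#' observing at least `a` tumor alt reads given the margins, i.e. the
#' one-sided p-value for alt-allele enrichment in the tumor. Vectorized.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return p-value(s) in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop_bad("counts must be non-negative")
  # P(X >= a), X ~ Hypergeometric(white = a+b, black = c+d, drawn = a+c)
  phyper(a - 1, m = a + b, n = c + d, k = a + c, lower.tail = FALSE)
}

vaf <- function(alt, ref) ifelse(alt + ref == 0, NA_real_, alt / (alt + ref))

#' Call somatic status for paired per-locus counts
#'
#' Genotypes normal and tumor from VAF bands (hom-ref < 0.05, het 0.05-0.90,
#' hom > 0.90) and tests tumor alt enrichment with a one-sided Fisher exact
#' test. A site is `somatic` when the normal looks reference
#' (n_vaf <= `max_normal_vaf_for_somatic`), the tumor carries the variant at
#' `min_vaf_somatic` or above, and the enrichment p-value is below
#' `p_threshold`; `germline` when the normal itself is variant; `ambiguous`
#' when coverage is insufficient or the evidence is intermediate. This is a
#' deliberately simple count-based paired caller, not a re-implementation of
#' any specific third-party genotyper. Vectorized over sites.
#'
#' @param sites data.frame with columns chrom, pos, ref, alt, t_ref, t_alt,
#'   n_ref, n_alt and optionally mean_baseq.
#' @param thresholds a [caller_thresholds()].
#' @return `sites` with added columns t_vaf, n_vaf, p_value, status,
#'   category, filtered, filter_reason, needs_visual_review.
#' @export
call_somatic <- function(sites, thresholds = caller_thresholds()) {
  th <- thresholds
  if (is.null(sites$mean_baseq)) sites$mean_baseq <- 36
  t_tot <- sites$t_ref + sites$t_alt
  n_tot <- sites$n_ref + sites$n_alt
  sites$t_vaf <- vaf(sites$t_alt, sites$t_ref)
  sites$n_vaf <- vaf(sites$n_alt, sites$n_ref)
  sites$p_value <- fisher_exact_2x2(sites$t_alt, sites$t_ref,
                                    sites$n_alt, sites$n_ref)

  low_cov <- t_tot < th$min_coverage | n_tot < th$min_coverage |
    t_tot == 0 | n_tot == 0
  germline <- !low_cov & sites$n_vaf >= 0.05
  somatic <- !low_cov & !germline &
    sites$n_vaf <= th$max_normal_vaf_for_somatic &
    sites$t_vaf >= th$min_vaf_somatic &
    sites$p_value < th$p_threshold
  reference <- !low_cov & !germline & !somatic & sites$t_vaf < th$min_vaf_somatic

  sites$status <- "ambiguous"
  sites$status[reference] <- "reference"
  sites$status[germline] <- "germline"
  sites$status[somatic] <- "somatic"
  sites$category <- ifelse(somatic, "MUT", "none")
  sites$filtered <- FALSE
  sites$filter_reason <- ""
  sites$needs_visual_review <- nchar(sites$ref) != nchar(sites$alt)
  sites
}

#' False-positive filter for somatic calls
#'
#' Removes likely artifacts: tumor VAF below `min_vaf_somatic` (default 10
#' percent, inclusive pass at the boundary), fewer than `min_alt_reads`
#' tumor alt reads, or mean base quality below `min_baseq`. Only somatic
#' calls are filtered; other rows pass through unchanged.
#'
#' @param calls output of [call_somatic()].
#' @param thresholds a [caller_thresholds()].
#' @return `calls` with `filtered`/`filter_reason` populated; filtered calls
#'   have `status` reset to "ambiguous" and `category` to "none".
#' @export
fp_filter <- function(calls, thresholds = caller_thresholds()) {
  th <- thresholds
  som <- calls$status == "somatic"
  reason <- rep("", nrow(calls))
  reason[som & calls$t_vaf < th$min_vaf_somatic] <- "min_vaf"
  r2 <- som & reason == "" & calls$t_alt < th$min_alt_reads
  reason[r2] <- "min_alt"
  r3 <- som & reason == "" & calls$mean_baseq < th$min_baseq
  reason[r3] <- "low_qual"
  hit <- reason != ""
  calls$filtered <- hit
  calls$filter_reason <- reason
  calls$status[hit] <- "ambiguous"
  calls$category[hit] <- "none"
  calls
}

#' Threshold-free hotspot report
#'
#' Re-reports every diagnostic hotspot locus (default: the panel's hotspot
#' table, covering TERT promoter -124/-146, IDH1 R132, IDH2 R172, BRAF V600
#' and H3F3A K27/G34) with raw tumor and normal VAF and depth, regardless of
#' whether the caller emitted a call there. This mirrors a dedicated pileup
#' pass over low-coverage diagnostic sites.
#'
#' @param sites counts data.frame (chrom, pos, t_ref, t_alt, n_ref, n_alt).
#' @param hotspots data.frame with columns name, chrom, pos (default: panel
#'   hotspots).
#' @param min_coverage depth below which the row is flagged `low_coverage`.
#' @return data.frame: name, chrom, pos, t_depth, n_depth, t_vaf, n_vaf,
#'   flag (ok / low_coverage / no_data).
#' @export
hotspot_report <- function(sites, hotspots, min_coverage = 8) {
  if (!nrow(hotspots)) stop_bad("hotspot list is empty")
  key <- paste(sites$chrom, sites$pos)
  idx <- match(paste(hotspots$chrom, hotspots$pos), key)
  off <- is.na(idx)
  if (any(off))
    warning(sprintf("hotspot(s) without count data: %s",
                    paste(hotspots$name[off], collapse = ", ")))
  t_depth <- ifelse(off, 0L, sites$t_ref[idx] + sites$t_alt[idx])
  n_depth <- ifelse(off, 0L, sites$n_ref[idx] + sites$n_alt[idx])
  data.frame(
    name = hotspots$name, chrom = hotspots$chrom, pos = hotspots$pos,
    t_depth = t_depth, n_depth = n_depth,
    t_vaf = ifelse(t_depth > 0, ifelse(off, NA, sites$t_alt[idx]) / t_depth, NA_real_),
    n_vaf = ifelse(n_depth > 0, ifelse(off, NA, sites$n_alt[idx]) / n_depth, NA_real_),
    flag = ifelse(off | (t_depth == 0 & n_depth == 0), "no_data",
                  ifelse(t_depth < min_coverage | n_depth < min_coverage,
                         "low_coverage", "ok")),
    stringsAsFactors = FALSE)
}

#' Flag rare germline variants (MUTGER)
#'
#' A germline call is reported as MUTGER when it is rare in the reference
#' population: non-Finnish European minor allele frequency below 0.01 and
#' fewer than 5 homozygotes (both strict). Common polymorphisms are
#' suppressed (`none`).
#'
#' @param calls output of [call_somatic()] (rows with status "germline" are
#'   considered).
#' @param maf_nfe numeric vector of population minor allele frequencies
#'   (NA = no annotation).
#' @param n_hom integer vector of homozygote counts.
#' @return `calls` with `category` set to "MUTGER" where the rule fires.
#' @export
flag_germline <- function(calls, maf_nfe, n_hom) {
  stopifnot(length(maf_nfe) == nrow(calls), length(n_hom) == nrow(calls))
  miss <- calls$status == "germline" & (is.na(maf_nfe) | is.na(n_hom))
  if (any(miss)) warning(sprintf("%d germline call(s) without population annotation", sum(miss)))
  hit <- calls$status == "germline" & !is.na(maf_nfe) & !is.na(n_hom) &
    maf_nfe < 0.01 & n_hom < 5
  calls$category[hit] <- "MUTGER"
  calls
}

#' Classify variant effect as truncating (TRU) or missense-type (MUT)
#'
#' TRU: stop-gain, frameshift insertion/deletion, canonical splice-site
#' change. MUT: missense, in-frame indel, promoter variant. Stop-gain and
#' splice consequences cannot be derived from counts alone, so an optional
#' annotation column is honoured (`effect` values containing "stopgain",
#' "frameshift" or "splic" are TRU); otherwise the ref/alt length difference
#' decides frameshift vs in-frame, and equal-length substitutions are MUT.
#'
#' @param ref,alt allele strings.
#' @param effect optional annotation strings (annovar-style), NA when absent.
#' @return character vector "TRU"/"MUT".
#' @export
classify_effect <- function(ref, alt, effect = NA_character_) {
  n <- max(length(ref), length(alt))
  effect <- rep_len(effect, n)
  out <- rep("MUT", n)
  len_diff <- abs(nchar(ref) - nchar(alt))
  out[len_diff %% 3 != 0] <- "TRU"
  ann <- !is.na(effect)
  tru_ann <- ann & grepl("stopgain|stop_gain|frameshift|splic", effect, ignore.case = TRUE)
  mut_ann <- ann & grepl("missense|nonsynonymous|inframe|promoter", effect, ignore.case = TRUE)
  out[mut_ann] <- "MUT"
  out[tru_ann] <- "TRU"
  out
}

#' Write somatic calls as a minimal VCF
#'
#' Sites-only VCF 4.2 with FILTER (PASS / min_vaf / min_alt / low_qual) and
#' INFO keys SS (somatic status), TVAF, NVAF, SPV (somatic Fisher p).
#'
#' @param calls output of [call_somatic()]/[fp_filter()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=gliopanel",
           "##INFO=<ID=SS,Number=1,Type=String,Description=\"Somatic status\">",
           "##INFO=<ID=TVAF,Number=1,Type=Float,Description=\"Tumor variant allele frequency\">",
           "##INFO=<ID=NVAF,Number=1,Type=Float,Description=\"Normal variant allele frequency\">",
           "##INFO=<ID=SPV,Number=1,Type=Float,Description=\"One-sided Fisher p, tumor alt enrichment\">",
           "##FILTER=<ID=min_vaf,Description=\"Tumor VAF below minimum\">",
           "##FILTER=<ID=min_alt,Description=\"Too few tumor alt reads\">",
           "##FILTER=<ID=low_qual,Description=\"Mean base quality below minimum\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  filt <- ifelse(calls$filtered, calls$filter_reason, "PASS")
  info <- sprintf("SS=%s;TVAF=%.6g;NVAF=%.6g;SPV=%.6g",
                  calls$status, calls$t_vaf, calls$n_vaf, calls$p_value)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  calls$chrom, as.integer(calls$pos), calls$ref, calls$alt,
                  filt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}
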