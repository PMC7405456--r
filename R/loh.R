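# Loss-of-heterozygosity detection from tumor/normal SNP allele-ratio shifts.

#' LOH filter parameters
#'
#' Site eligibility: normal VAF within \[`n_vaf_lo`, `n_vaf_hi`\] (closed
#' interval), strictly more than `min_n_alt` alt reads in the normal, and
#' strictly more than `min_t_total` total reads in the tumor. An eligible
#' site is LOH when the tumor/normal VAF ratio is strictly above `ratio_hi`
#' or strictly below `ratio_lo`. Region aggregation needs at least
#' `min_informative_snps` eligible sites and calls LOH when the LOH fraction
#' reaches `region_fraction`.
#'
#' @param n_vaf_lo,n_vaf_hi heterozygosity window in the normal (0.30-0.60).
#' @param min_n_alt strict lower bound on normal alt reads (20).
#' @param min_t_total strict lower bound on tumor total reads (20).
#' @param ratio_hi,ratio_lo strict VAF-ratio decision boundaries (1.35, 0.67).
#' @param min_informative_snps minimum eligible SNPs for a region call (5).
#' @param region_fraction LOH fraction among eligible SNPs that calls a
#'   region LOH (0.6). The aggregation rule (fraction and floor) is this
#'   package's own; only the site-level thresholds are assay constants.
#' @return an `loh_params` list.
#' @export
loh_params <- function(n_vaf_lo = 0.30, n_vaf_hi = 0.60, min_n_alt = 20,
                       min_t_total = 20, ratio_hi = 1.35, ratio_lo = 0.67,
                       min_informative_snps = 5, region_fraction = 0.6) {
  stopifnot(n_vaf_lo > 0, n_vaf_lo < n_vaf_hi, n_vaf_hi < 1,
            ratio_lo < 1, ratio_hi > 1, min_n_alt >= 0, min_t_total >= 0,
            min_informative_snps >= 1, region_fraction > 0, region_fraction <= 1)
  structure(list(n_vaf_lo = n_vaf_lo, n_vaf_hi = n_vaf_hi, min_n_alt = min_n_alt,
                 min_t_total = min_t_total, ratio_hi = ratio_hi,
                 ratio_lo = ratio_lo, min_informative_snps = min_informative_snps,
                 region_fraction = region_fraction), class = "loh_params")
}

#' Per-site LOH evaluation
#'
#' Vectorized over sites. Ineligible sites get `ratio = NA` and are never
#' LOH; the eligibility window excludes `n_vaf = 0`, so the ratio is always
#' defined where it is used.
#'
#' @param sites data.frame with t_ref, t_alt, n_ref, n_alt (and any other
#'   columns, which pass through).
#' @param params an [loh_params()].
#' @return `sites` with added columns n_vaf, t_vaf, eligible, ratio, is_loh.
#' @export
loh_site <- function(sites, params = loh_params()) {
  p <- params
  n_tot <- sites$n_ref + sites$n_alt
  t_tot <- sites$t_ref + sites$t_alt
  sites$n_vaf <- vaf(sites$n_alt, sites$n_ref)
  sites$t_vaf <- vaf(sites$t_alt, sites$t_ref)
  sites$eligible <- !is.na(sites$n_vaf) &
    sites$n_vaf >= p$n_vaf_lo & sites$n_vaf <= p$n_vaf_hi &
    sites$n_alt > p$min_n_alt & t_tot > p$min_t_total
  sites$ratio <- ifelse(sites$eligible, sites$t_vaf / sites$n_vaf, NA_real_)
  sites$is_loh <- sites$eligible &
    (sites$ratio > p$ratio_hi | sites$ratio < p$ratio_lo)
  sites
}

#' Aggregate site LOH results to a region call
#'
#' @param site_results output of [loh_site()] for the sites of one region.
#' @param region region name (label only).
#' @param params an [loh_params()].
#' @return one-row data.frame: region, n_eligible, n_loh, status
#'   (LOH / RET / NA).
#' @export
region_loh <- function(site_results, region, params = loh_params()) {
  n_el <- sum(site_results$eligible)
  n_loh <- sum(site_results$is_loh)
  status <- if (n_el < params$min_informative_snps) NA_character_
    else if (n_loh / n_el >= params$region_fraction) "LOH" else "RET"
  data.frame(region = region, n_eligible = n_el, n_loh = n_loh,
             status = status, stringsAsFactors = FALSE)
}

#' Call LOH for every panel region (and derived 17p/17q arms)
#'
#' @param sites counts data.frame covering the panel SNP backbones.
#' @param panel a `panel_def`.
#' @param params an [loh_params()].
#' @param derive_17pq split the chromosome-17 backbone at the centromere and
#'   add derived "17p"/"17q" calls (for isodicentric-17q detection).
#' @return data.frame of region calls (one row per region).
#' @export
call_loh <- function(sites, panel, params = loh_params(), derive_17pq = TRUE) {
  res <- loh_site(sites, params)
  loc <- locate(panel, res$chrom, res$pos)
  out <- list()
  for (r in panel$regions) {
    sel <- loc$type == "region" & loc$target == r$name
    out[[r$name]] <- region_loh(res[sel, , drop = FALSE], r$name, params)
  }
  if (derive_17pq && "chr17" %in% names(panel$regions)) {
    cen <- panel$centromeres[["chr17"]]
    sel17 <- loc$type == "region" & loc$target == "chr17"
    out[["17p"]] <- region_loh(res[sel17 & res$pos <= cen, , drop = FALSE], "17p", params)
    out[["17q"]] <- region_loh(res[sel17 & res$pos > cen, , drop = FALSE], "17q", params)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' 1p/19q codeletion status
#'
#' @param region_calls data.frame of region LOH calls (from [call_loh()]).
#' @return TRUE (both arms LOH), FALSE (both informative, not both LOH) or
#'   NA (either arm uninformative).
#' @export
codeletion_1p19q <- function(region_calls) {
  s <- setNames(region_calls$status, region_calls$region)
  if (!all(c("1p", "19q") %in% names(s)))
    stop_bad("need region calls for both 1p and 19q")
  if (is.na(s[["1p"]]) || is.na(s[["19q"]])) return(NA)
  s[["1p"]] == "LOH" && s[["19q"]] == "LOH"
}
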