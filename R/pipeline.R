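# End-to-end case analysis: smallvar -> loh -> cnv -> interpret -> qc.

#' Run the full analysis for one case
#'
#' Executes paired small-variant calling with FP filtering and hotspot
#' rescue, site and region LOH, copy-number calling against the size-sorted
#' baseline, rule-based interpretation for the given histology context, and
#' coverage QC. Deterministic for fixed inputs and seed.
#'
#' @param counts paired counts data.frame (see [read_counts()]).
#' @param panel a `panel_def`.
#' @param context histology context for the rule engine (see
#'   [case_profile()]).
#' @param case_id case identifier.
#' @param caller a [caller_thresholds()].
#' @param loh a [loh_params()].
#' @param cnv a [cnv_thresholds()].
#' @param seg optional external segments data.frame (bypasses segmentation).
#' @param annotations optional data.frame (chrom, pos, maf_nfe, n_hom,
#'   effect) of population/effect annotations.
#' @param seed seed for the segmentation permutation test.
#' @return a `case_report` list: calls, hotspots, loh_sites, loh_regions,
#'   cnv (ratios/segments/baseline/calls), profile, interpretation, therapy,
#'   qc.
#' @export
run_case <- function(counts, panel, context = "diffuse_glioma",
                     case_id = "case", caller = caller_thresholds(),
                     loh = loh_params(), cnv = cnv_thresholds(), seg = NULL,
                     annotations = NULL, seed = 1L) {
  calls <- fp_filter(call_somatic(counts, caller), caller)
  if (!is.null(annotations)) {
    idx <- match(paste(calls$chrom, calls$pos),
                 paste(annotations$chrom, annotations$pos))
    calls <- flag_germline(calls, annotations$maf_nfe[idx], annotations$n_hom[idx])
    eff <- annotations$effect[idx]
  } else eff <- rep(NA_character_, nrow(calls))
  som <- calls$status == "somatic"
  calls$category[som] <- classify_effect(calls$ref[som], calls$alt[som], eff[som])

  hs <- hotspot_report(counts, panel$hotspots, caller$min_coverage)
  loh_sites <- loh_site(counts, loh)
  loh_regions <- call_loh(counts, panel, loh)
  cnv_res <- call_cnv(counts, panel, loh_calls = loh_regions, seg = seg,
                      thresholds = cnv, seed = seed)
  profile <- build_profile(case_id, context, calls, hs, loh_regions,
                           cnv_res, panel)
  interp <- switch(context,
    medulloblastoma = classify_medulloblastoma(profile),
    meningioma = meningioma_risk(profile),
    diffuse_glioma = , midline_glioma = , pilocytic = classify_glioma(profile),
    NULL)
  therapy <- annotate_therapy(profile, panel)
  depths <- counts$t_ref + counts$t_alt
  qc <- coverage_qc(depths)

  structure(list(case_id = case_id, context = context, calls = calls,
                 hotspots = hs, loh_sites = loh_sites,
                 loh_regions = loh_regions, cnv = cnv_res, profile = profile,
                 interpretation = interp, therapy = therapy, qc = qc,
                 params = list(caller = unclass(caller), loh = unclass(loh),
                               cnv = unclass(cnv), seed = seed)),
            class = "case_report")
}

# Collapse per-site calls + region results into a case_profile for the rules.
build_profile <- function(case_id, context, calls, hotspots, loh_regions,
                          cnv_res, panel) {
  gene_cats <- list()
  add_cat <- function(gene, cat) {
    cur <- gene_cats[[gene]] %||% character()
    if (!cat %in% cur) gene_cats[[gene]] <<- c(cur, cat)
  }
  loc <- locate(panel, calls$chrom, calls$pos)
  keep <- calls$category %in% c("MUT", "TRU", "MUTGER") & loc$type == "gene"
  for (i in which(keep)) add_cat(loc$target[i], calls$category[i])
  gc <- cnv_res$gene_calls
  for (i in seq_len(nrow(gc)))
    if (!is.na(gc$state[i]) && gc$state[i] != "BALANCED")
      add_cat(gc$target[i], gc$state[i])
  # gene-level LOH from site ratios on gene backbones is out of scope here;
  # region LOH drives the region_calls instead.

  region_states <- character()
  for (i in seq_len(nrow(cnv_res$region_calls))) {
    rc <- cnv_res$region_calls[i, ]
    region_states[rc$target] <- rc$state
  }
  # LOH overrides a balanced CNV state (copy-neutral LOH); AMP/DEL kept.
  for (i in seq_len(nrow(loh_regions))) {
    lr <- loh_regions[i, ]
    cur <- unname(region_states[lr$region])
    if (!is.na(lr$status) && lr$status == "LOH" &&
        (length(cur) == 0 || is.na(cur) || cur == "BALANCED"))
      region_states[lr$region] <- "LOH"
  }

  vaf_of <- function(nm) {
    v <- hotspots$t_vaf[hotspots$name == nm]
    if (length(v) && !is.na(v)) v else 0
  }
  mut_at <- function(nm, min_vaf = 0.10) vaf_of(nm) >= min_vaf
  flags <- c(
    IDH1_R132 = mut_at("IDH1_R132"), IDH2_R172 = mut_at("IDH2_R172"),
    TERTp = mut_at("TERTp_C228T") || mut_at("TERTp_C250T"),
    BRAF_V600E = mut_at("BRAF_V600"),
    H3F3A_K27M = mut_at("H3F3A_K27"), H3F3A_G34 = mut_at("H3F3A_G34"))

  case_profile(case_id, context,
               gene_calls = vapply(gene_cats, paste, "", collapse = ";"),
               region_calls = region_states, hotspot_flags = flags)
}

#' Write a case report bundle to a directory
#'
#' Deterministic text outputs: calls VCF + TSV, hotspot TSV, LOH site and
#' region TSVs, SEG file, CNV call TSV, oncoprint TSV and a JSON report.
#'
#' @param report a `case_report` from [run_case()].
#' @param dir output directory (created if needed).
#' @param panel the `panel_def` used (for the oncoprint row frame).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir, panel) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  write_calls_vcf(report$calls, file.path(dir, "calls.vcf"))
  wt(report$calls, "calls.tsv")
  wt(report$hotspots, "hotspots.tsv")
  wt(report$loh_sites[, c("chrom", "pos", "eligible", "ratio", "is_loh")],
     "loh_sites.tsv")
  wt(report$loh_regions, "loh_regions.tsv")
  write_seg(report$cnv$segments, file.path(dir, "segments.seg"))
  wt(rbind(report$cnv$region_calls,
           report$cnv$gene_calls[, c("target", "level", "delta", "state", "partial")]),
     "cnv_calls.tsv")
  write_oncoprint(oncoprint_matrix(list(report$profile), panel),
                  file.path(dir, "oncoprint.tsv"))
  js <- list(case_id = report$case_id, context = report$context,
             baseline = report$cnv$baseline,
             interpretation = report$interpretation,
             therapy = report$therapy,
             qc = report$qc, params = report$params,
             gain7_loss10 = report$cnv$gain7_loss10)
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(dir)
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf("<case_report> %s (%s)\n", x$case_id, x$context))
  cat(sprintf("  somatic calls: %d | LOH regions: %s\n",
              sum(x$calls$status == "somatic"),
              paste(x$loh_regions$region[x$loh_regions$status %in% "LOH"],
                    collapse = ", ")))
  nb <- x$cnv$region_calls
  cat(sprintf("  CNV baseline %.3f | non-balanced regions: %s\n",
              x$cnv$baseline$value,
              paste(nb$target[!is.na(nb$state) & nb$state != "BALANCED"],
                    collapse = ", ")))
  if (!is.null(x$interpretation$label))
    cat("  diagnosis:", x$interpretation$label, "\n")
  if (!is.null(x$interpretation$subgroup))
    cat("  subgroup:", x$interpretation$subgroup, "\n")
  invisible(x)
}
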