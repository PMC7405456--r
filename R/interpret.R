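# Rule engine: integrated diagnoses, medulloblastoma subgroups, meningioma
# risk, therapy annotation, oncoprint matrix.

GENE_VOCAB <- c("TRU", "MUT", "MUTGER", "HIGHCOPY", "AMP", "HOMDEL", "DEL", "LOH")
REGION_VOCAB <- c("AMP", "DEL", "BALANCED", "LOH", "RET")
MUT_CATS <- c("MUT", "TRU")   # somatic mutation categories

#' Build a case alteration profile
#'
#' The profile is the rule engine's only input: per-gene alteration
#' categories (controlled vocabulary TRU, MUT, MUTGER, HIGHCOPY, AMP,
#' HOMDEL, DEL, LOH; multiple events per gene joined with ";"), per-region
#' states (AMP, DEL, BALANCED, LOH, RET or NA), and named hotspot flags
#' (e.g. IDH1_R132, TERTp, BRAF_V600E, H3F3A_K27M).
#'
#' @param case_id case identifier.
#' @param histology_context one of diffuse_glioma, pilocytic, meningioma,
#'   medulloblastoma, midline_glioma, other.
#' @param gene_calls named character vector, gene -> category string.
#' @param region_calls named character vector, region -> state.
#' @param hotspot_flags named logical vector.
#' @return a `case_profile`.
#' @export
case_profile <- function(case_id, histology_context = c("diffuse_glioma",
                         "pilocytic", "meningioma", "medulloblastoma",
                         "midline_glioma", "other"),
                         gene_calls = character(), region_calls = character(),
                         hotspot_flags = logical()) {
  histology_context <- match.arg(histology_context)
  if (length(gene_calls)) {
    toks <- unlist(strsplit(gene_calls[gene_calls != "" & gene_calls != "none"], ";"))
    bad <- setdiff(toks, GENE_VOCAB)
    if (length(bad)) stop_bad("unknown gene category: %s", paste(bad, collapse = ", "))
  }
  if (length(region_calls)) {
    bad <- setdiff(region_calls[!is.na(region_calls)], REGION_VOCAB)
    if (length(bad)) stop_bad("unknown region state: %s", paste(bad, collapse = ", "))
  }
  structure(list(case_id = case_id, histology_context = histology_context,
                 gene_calls = gene_calls, region_calls = region_calls,
                 hotspot_flags = hotspot_flags), class = "case_profile")
}

gene_has <- function(profile, gene, cats = GENE_VOCAB) {
  v <- profile$gene_calls[gene]
  if (is.na(v) || !nzchar(v)) return(FALSE)
  any(strsplit(v, ";")[[1]] %in% cats)
}

region_is <- function(profile, region, states) {
  v <- profile$region_calls[region]
  !is.na(v) && v %in% states
}

flag_on <- function(profile, flag) isTRUE(unname(profile$hotspot_flags[flag]))

idh_mutant <- function(profile) {
  flag_on(profile, "IDH1_R132") || flag_on(profile, "IDH2_R172") ||
    gene_has(profile, "IDH1", MUT_CATS) || gene_has(profile, "IDH2", MUT_CATS)
}

tertp_mut <- function(profile) {
  flag_on(profile, "TERTp") || flag_on(profile, "TERTp_C228T") ||
    flag_on(profile, "TERTp_C250T") || gene_has(profile, "TERT", MUT_CATS)
}

codeleted_1p19q <- function(profile) {
  region_is(profile, "1p", c("LOH", "DEL")) &&
    region_is(profile, "19q", c("LOH", "DEL"))
}

gain7_loss10 <- function(profile) {
  region_is(profile, "chr7", "AMP") && region_is(profile, "chr10", "DEL")
}

ev <- function(rule, alterations) list(rule = rule, alterations = alterations)

#' Integrated diagnosis for diffuse gliomas
#'
#' Decision order: (1) H3F3A K27M defines diffuse midline glioma, WHO grade
#' IV; (2) IDH mutation with 1p/19q codeletion defines oligodendroglioma;
#' (3) IDH mutation without codeletion gives astrocytoma, IDH-mutant, with an
#' unfavorable-grade flag on CDKN2A homozygous loss; (4) IDH-wildtype diffuse
#' glioma with TERT-promoter mutation, EGFR high-copy amplification or
#' combined chromosome 7 gain + 10 loss is reported with molecular features
#' of glioblastoma, WHO grade IV (histology context diffuse_glioma only;
#' pilocytic histology gets a review flag instead); (5) BRAF V600E without
#' high-grade markers flags a ganglioglioma / pediatric-type low-grade glioma
#' differential. Labels are advisory strings with evidence, not a clinical
#' verdict.
#'
#' @param profile a [case_profile()] with glioma histology context.
#' @return list with `label`, `grade`, `evidence` (list of rule/alterations),
#'   `flags`, `confidence_notes`.
#' @export
classify_glioma <- function(profile) {
  stopifnot(profile$histology_context %in%
              c("diffuse_glioma", "midline_glioma", "pilocytic"))
  flags <- character()
  notes <- character()
  k27m <- flag_on(profile, "H3F3A_K27M")
  idh <- idh_mutant(profile)
  if (k27m && idh)
    notes <- c(notes, "conflicting markers: H3K27M and IDH mutation co-occur; review")

  if (k27m) {
    return(list(label = "diffuse midline glioma, H3K27M-mutant",
                grade = "IV",
                evidence = list(ev("H3K27M", "H3F3A_K27M")),
                flags = flags, confidence_notes = notes))
  }
  if (idh) {
    idh_alt <- c("IDH1_R132", "IDH2_R172")[c(flag_on(profile, "IDH1_R132"),
                                             flag_on(profile, "IDH2_R172"))]
    if (!length(idh_alt)) idh_alt <- "IDH1/2 mutation"
    if (codeleted_1p19q(profile)) {
      return(list(label = "oligodendroglioma, IDH-mutant and 1p/19q-codeleted",
                  grade = NA_character_,
                  evidence = list(ev("IDH mutation", idh_alt),
                                  ev("1p/19q codeletion", c("1p", "19q"))),
                  flags = flags, confidence_notes = notes))
    }
    if (gene_has(profile, "CDKN2A", "HOMDEL"))
      flags <- c(flags, "CDKN2A homozygous loss: unfavorable grading factor")
    return(list(label = "astrocytoma, IDH-mutant", grade = NA_character_,
                evidence = list(ev("IDH mutation without 1p/19q codeletion", idh_alt)),
                flags = flags, confidence_notes = notes))
  }
  mol_gbm <- tertp_mut(profile) || gene_has(profile, "EGFR", "HIGHCOPY") ||
    gain7_loss10(profile)
  if (mol_gbm) {
    alts <- c(if (tertp_mut(profile)) "TERTp",
              if (gene_has(profile, "EGFR", "HIGHCOPY")) "EGFR HIGHCOPY",
              if (gain7_loss10(profile)) "chr7 gain + chr10 loss")
    if (profile$histology_context == "diffuse_glioma") {
      return(list(
        label = "diffuse astrocytic glioma, IDH-wildtype, with molecular features of glioblastoma",
        grade = "IV",
        evidence = list(ev("IDH-wildtype with molecular glioblastoma markers", alts)),
        flags = flags, confidence_notes = notes))
    }
    flags <- c(flags, "molecular glioblastoma markers in non-diffuse histology: review")
    return(list(label = sprintf("%s with unusual high-grade molecular markers",
                                profile$histology_context),
                grade = NA_character_,
                evidence = list(ev("high-grade markers outside diffuse-glioma context", alts)),
                flags = flags, confidence_notes = notes))
  }
  if (flag_on(profile, "BRAF_V600E")) {
    flags <- c(flags, "ganglioglioma/pediatric-type LGG differential: histological review")
    return(list(label = "glioma with BRAF V600E, without high-grade markers",
                grade = NA_character_,
                evidence = list(ev("BRAF V600E without high-grade markers", "BRAF_V600E")),
                flags = flags, confidence_notes = notes))
  }
  list(label = "diffuse glioma, not further classifiable by panel markers",
       grade = NA_character_,
       evidence = list(ev("no classifying marker constellation", character())),
       flags = flags, confidence_notes = notes)
}

#' Medulloblastoma molecular subgroup
#'
#' WNT takes precedence: a CTNNB1 mutation or whole-chromosome 6 loss
#' (monosomy 6) assigns WNT even if TERTp is present. Otherwise SHH on any
#' alteration of PTCH1, SUFU or SMO, or (by default) a TERT-promoter
#' mutation, which this assay treats as SHH-specific; the SHH branch is
#' subdivided by somatic TP53 status. Everything else is non-WNT/non-SHH;
#' 17q gain, isodicentric 17q (17p loss with 17q gain) and chromosome 7 gain
#' are recorded as supporting evidence only, not as assignment rules.
#'
#' @param profile a [case_profile()] with medulloblastoma context.
#' @param tertp_implies_shh treat TERTp mutation alone as SHH evidence
#'   (default TRUE).
#' @return list with `subgroup` (WNT, SHH_TP53wt, SHH_TP53mut,
#'   nonWNT_nonSHH) and `evidence`.
#' @export
classify_medulloblastoma <- function(profile, tertp_implies_shh = TRUE) {
  stopifnot(profile$histology_context == "medulloblastoma")
  if (gene_has(profile, "CTNNB1", MUT_CATS) || region_is(profile, "chr6", "DEL")) {
    alts <- c(if (gene_has(profile, "CTNNB1", MUT_CATS)) "CTNNB1",
              if (region_is(profile, "chr6", "DEL")) "monosomy 6")
    return(list(subgroup = "WNT", evidence = list(ev("WNT markers", alts))))
  }
  shh_genes <- c("PTCH1", "SUFU", "SMO")
  shh_hits <- shh_genes[vapply(shh_genes, function(g) gene_has(profile, g), TRUE)]
  tert <- tertp_implies_shh && tertp_mut(profile)
  if (length(shh_hits) || tert) {
    tp53 <- gene_has(profile, "TP53", MUT_CATS)
    alts <- c(shh_hits, if (tert) "TERTp")
    return(list(subgroup = if (tp53) "SHH_TP53mut" else "SHH_TP53wt",
                evidence = list(ev("SHH pathway markers", alts))))
  }
  support <- c(
    if (region_is(profile, "17p", "DEL") && region_is(profile, "17q", "AMP")) "i17q",
    if (region_is(profile, "17q", "AMP") && !region_is(profile, "17p", "DEL")) "17q gain",
    if (region_is(profile, "chr7", "AMP")) "chr7 gain")
  list(subgroup = "nonWNT_nonSHH",
       evidence = list(ev("no WNT/SHH markers; supporting CNVs", support)))
}

#' Meningioma molecular risk report
#'
#' Flags the prognostically unfavorable constellation (1p loss/LOH, CDKN2A
#' loss, TERT-promoter mutation), the favorable mutation profile (TRAF7,
#' KLF4, AKT1, SMO), and counts CNV complexity (non-balanced region calls
#' plus relevant gene-level CNVs); `high_complexity` fires at
#' `complexity_threshold` events or more.
#'
#' @param profile a [case_profile()] with meningioma context.
#' @param complexity_threshold event count that flags high CNV complexity
#'   (default 7; an operating choice anchored to observed high-risk cases,
#'   not a validated clinical cut-off).
#' @return list with `unfavorable`, `favorable` (character vectors),
#'   `cnv_complexity`, `high_complexity`.
#' @export
meningioma_risk <- function(profile, complexity_threshold = 7) {
  stopifnot(profile$histology_context == "meningioma")
  unfav <- c(
    if (region_is(profile, "1p", c("DEL", "LOH"))) "1p loss",
    if (gene_has(profile, "CDKN2A", c("HOMDEL", "DEL"))) "CDKN2A loss",
    if (tertp_mut(profile)) "TERTp mutation")
  fav_genes <- c("TRAF7", "KLF4", "AKT1", "SMO")
  fav <- fav_genes[vapply(fav_genes, function(g) gene_has(profile, g, MUT_CATS), TRUE)]
  n_region <- sum(profile$region_calls %in% c("AMP", "DEL"), na.rm = TRUE)
  cnv_cats <- c("HIGHCOPY", "AMP", "HOMDEL", "DEL")
  n_gene <- sum(vapply(names(profile$gene_calls), function(g)
    gene_has(profile, g, cnv_cats), TRUE))
  complexity <- n_region + n_gene
  list(unfavorable = unfav, favorable = fav, cnv_complexity = complexity,
       high_complexity = complexity >= complexity_threshold)
}

#' Therapy annotation from panel gene roles
#'
#' Every non-germline, non-balanced alteration in a gene carrying the
#' `targetable` role emits a targetable entry; `resistance`-role genes emit
#' resistance entries. MUTGER (rare germline) alterations never emit.
#'
#' @param profile a [case_profile()].
#' @param panel a `panel_def` providing the role table.
#' @return list with data.frames `targetable` and `resistance`
#'   (gene, alteration, rationale).
#' @export
annotate_therapy <- function(profile, panel) {
  rationale_map <- c(EGFR = "EGFR inhibitor class", BRAF = "BRAF/MEK inhibitor class",
                     CDK6 = "CDK4/6 inhibitor class", CDK4 = "CDK4/6 inhibitor class",
                     MET = "multi-kinase inhibitor class", KIT = "multi-kinase inhibitor class",
                     PDGFRA = "multi-kinase inhibitor class", PDGFRB = "multi-kinase inhibitor class",
                     SMO = "SHH pathway inhibitor class", PTCH1 = "SHH pathway inhibitor class")
  roles <- strsplit(setNames(panel$genes$roles, panel$genes$name), ",", fixed = TRUE)
  active <- c("TRU", "MUT", "HIGHCOPY", "AMP", "HOMDEL", "DEL", "LOH")
  tgt <- list(); res <- list()
  gc <- profile$gene_calls
  for (g in names(gc)) {
    cats <- intersect(strsplit(gc[[g]], ";")[[1]], active)
    if (!length(cats)) next
    rl <- roles[[g]] %||% character()
    for (cat in cats) {
      if ("targetable" %in% rl)
        tgt[[length(tgt) + 1]] <- data.frame(gene = g, alteration = cat,
          rationale = unname(rationale_map[g] %|na|% "targetable per knowledge base"),
          stringsAsFactors = FALSE)
      if ("resistance" %in% rl)
        res[[length(res) + 1]] <- data.frame(gene = g, alteration = cat,
          stringsAsFactors = FALSE)
    }
  }
  # hotspot flags may carry targetable events without a gene-call entry
  if (flag_on(profile, "BRAF_V600E") && !gene_has(profile, "BRAF"))
    tgt[[length(tgt) + 1]] <- data.frame(gene = "BRAF", alteration = "MUT",
      rationale = "BRAF/MEK inhibitor class", stringsAsFactors = FALSE)
  empty_t <- data.frame(gene = character(), alteration = character(),
                        rationale = character(), stringsAsFactors = FALSE)
  empty_r <- data.frame(gene = character(), alteration = character(),
                        stringsAsFactors = FALSE)
  list(targetable = if (length(tgt)) do.call(rbind, tgt) else empty_t,
       resistance = if (length(res)) do.call(rbind, res) else empty_r)
}

`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

#' Oncoprint-style alteration matrix
#'
#' Rows are panel genes (panel order) followed by regions; columns are
#' cases. Cells hold semicolon-joined categories from the controlled
#' vocabulary; empty means no alteration. Region states BALANCED/RET/NA are
#' rendered empty.
#'
#' @param profiles list of [case_profile()]s.
#' @param panel a `panel_def` fixing the row order.
#' @return character matrix with dimnames (targets x case ids).
#' @export
oncoprint_matrix <- function(profiles, panel) {
  stopifnot(length(profiles) >= 1)
  rows <- c(panel$genes$name, names(panel$regions))
  cols <- vapply(profiles, `[[`, "", "case_id")
  m <- matrix("", nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  for (p in profiles) {
    gc <- p$gene_calls
    for (g in names(gc)) {
      if (!g %in% rows) stop_bad("gene %s not on panel", g)
      toks <- setdiff(strsplit(gc[[g]], ";")[[1]], c("", "none"))
      bad <- setdiff(toks, GENE_VOCAB)
      if (length(bad)) stop_bad("unknown category: %s", paste(bad, collapse = ","))
      m[g, p$case_id] <- paste(toks, collapse = ";")
    }
    rc <- p$region_calls
    for (r in intersect(names(rc), rows)) {
      v <- rc[[r]]
      if (!is.na(v) && v %in% c("AMP", "DEL", "LOH")) m[r, p$case_id] <- v
    }
  }
  m
}

#' Write / read an oncoprint matrix as TSV
#'
#' @param m matrix from [oncoprint_matrix()].
#' @param path file path.
#' @return for `read_oncoprint`, the matrix (round-trips exactly).
#' @export
write_oncoprint <- function(m, path) {
  df <- data.frame(target = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_oncoprint
#' @export
read_oncoprint <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$target
  m[is.na(m)] <- ""
  m
}

#' Reference medulloblastoma alteration profiles
#'
#' The eight per-case profiles used for regression-locking the subgroup
#' rules: a CTNNB1-mutant/monosomy-6 WNT case; SHH cases driven by a PTCH1
#' loss-of-function mutation plus TERTp, TERTp alone (twice), and a SUFU
#' mutation; and three non-WNT/non-SHH cases carrying isodicentric 17q, 17q
#' gain with chromosome 7 gain, and chromosome 7 gain.
#'
#' @return named list of eight [case_profile()]s (MB_1..MB_8).
#' @export
mb_reference_profiles <- function() {
  mk <- function(id, genes = character(), regions = character(), flags = logical())
    case_profile(id, "medulloblastoma", gene_calls = genes,
                 region_calls = regions, hotspot_flags = flags)
  list(
    MB_1 = mk("MB_1", genes = c(CTNNB1 = "MUT"), regions = c(chr6 = "DEL")),
    MB_2 = mk("MB_2", genes = c(PTCH1 = "TRU;LOH", IDH1 = "MUT"),
              flags = c(TERTp = TRUE, IDH1_R132 = TRUE)),
    MB_3 = mk("MB_3", flags = c(TERTp = TRUE)),
    MB_4 = mk("MB_4", flags = c(TERTp = TRUE)),
    MB_5 = mk("MB_5", genes = c(SUFU = "MUT")),
    MB_6 = mk("MB_6", regions = c(`17p` = "DEL", `17q` = "AMP")),
    MB_7 = mk("MB_7", regions = c(`17q` = "AMP", chr7 = "AMP")),
    MB_8 = mk("MB_8", regions = c(chr7 = "AMP"))
  )
}

#' Table-style alteration frequencies per entity
#'
#' Computes the percentage of cases carrying each alteration from raw
#' counts, rounded half-up to whole percent (the cohort-table reporting
#' convention).
#'
#' @param counts data.frame with columns entity, n_cases, alteration,
#'   n_altered (default: the packaged cohort count table).
#' @return `counts` with an added `frequency_pct` column.
#' @export
alteration_frequencies <- function(counts = NULL) {
  if (is.null(counts))
    counts <- read.table(system.file("extdata", "cohort_alteration_counts.tsv",
                                     package = "gliopanel", mustWork = TRUE),
                         header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(counts$n_altered <= counts$n_cases))
  counts$frequency_pct <- round_half_up(100 * counts$n_altered / counts$n_cases)
  counts
}
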