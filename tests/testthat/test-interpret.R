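test_that("glioma rules reproduce the printed diagnostic constellations", {
  # IDH-wildtype diffuse glioma with TERTp (+ CDK6 AMP): molecular GBM, WHO IV
  p <- case_profile("aA_8", "diffuse_glioma",
                    gene_calls = c(CDK6 = "AMP"),
                    hotspot_flags = c(TERTp = TRUE))
  d <- classify_glioma(p)
  expect_match(d$label, "molecular features of glioblastoma")
  expect_equal(d$grade, "IV")

  # IDH mutation + 1p/19q LOH (+ TERTp): oligodendroglioma
  p <- case_profile("O_1", "diffuse_glioma",
                    region_calls = c(`1p` = "LOH", `19q` = "LOH"),
                    hotspot_flags = c(IDH1_R132 = TRUE, TERTp = TRUE))
  d <- classify_glioma(p)
  expect_match(d$label, "oligodendroglioma, IDH-mutant and 1p/19q-codeleted")

  # IDH mutant without codeletion; CDKN2A HOMDEL raises the grading flag
  p <- case_profile("A_5", "diffuse_glioma",
                    gene_calls = c(CDKN2A = "HOMDEL", TP53 = "MUT"),
                    hotspot_flags = c(IDH1_R132 = TRUE))
  d <- classify_glioma(p)
  expect_match(d$label, "astrocytoma, IDH-mutant")
  expect_true(any(grepl("CDKN2A", d$flags)))

  # H3K27M beats everything
  p <- case_profile("DMG", "midline_glioma",
                    hotspot_flags = c(H3F3A_K27M = TRUE))
  expect_match(classify_glioma(p)$label, "H3K27M")

  # BRAF V600E as sole alteration: ganglioglioma review flag, no GBM label
  p <- case_profile("A_1", "diffuse_glioma",
                    hotspot_flags = c(BRAF_V600E = TRUE))
  d <- classify_glioma(p)
  expect_true(any(grepl("ganglioglioma", d$flags)))
  expect_no_match(d$label, "glioblastoma")

  # chr7 gain + chr10 loss alone also triggers the molecular-GBM rule
  p <- case_profile("A_10", "diffuse_glioma",
                    region_calls = c(chr7 = "AMP", chr10 = "DEL"))
  expect_match(classify_glioma(p)$label, "molecular features of glioblastoma")

  # pilocytic histology with high-grade markers: review, not reclassification
  p <- case_profile("pA_3", "pilocytic", hotspot_flags = c(TERTp = TRUE))
  d <- classify_glioma(p)
  expect_no_match(d$label, "molecular features of glioblastoma")
  expect_true(any(grepl("review", d$flags)))

  # conflicting IDH + K27M: note recorded, no exception
  p <- case_profile("X", "diffuse_glioma",
                    hotspot_flags = c(H3F3A_K27M = TRUE, IDH1_R132 = TRUE))
  d <- classify_glioma(p)
  expect_true(any(grepl("conflict", d$confidence_notes)))
})

test_that("medulloblastoma reference profiles give 1 WNT / 4 SHH / 3 non-WNT/non-SHH", {
  profs <- mb_reference_profiles()
  sub <- vapply(profs, function(p) classify_medulloblastoma(p)$subgroup, "")
  expect_equal(unname(sub["MB_1"]), "WNT")
  expect_equal(sum(grepl("^SHH", sub)), 4)
  expect_equal(sum(sub == "nonWNT_nonSHH"), 3)
  expect_setequal(names(sub)[grepl("^SHH", sub)], c("MB_2", "MB_3", "MB_4", "MB_5"))
})

test_that("WNT precedence and TP53 branch work as specified", {
  # CTNNB1 + TERTp is still WNT
  p <- case_profile("m", "medulloblastoma", gene_calls = c(CTNNB1 = "MUT"),
                    hotspot_flags = c(TERTp = TRUE))
  expect_equal(classify_medulloblastoma(p)$subgroup, "WNT")
  # monosomy 6 alone is WNT
  p <- case_profile("m", "medulloblastoma", region_calls = c(chr6 = "DEL"))
  expect_equal(classify_medulloblastoma(p)$subgroup, "WNT")
  # PTCH1 truncating + somatic TP53 mutation: SHH TP53-mutant
  p <- case_profile("m", "medulloblastoma",
                    gene_calls = c(PTCH1 = "TRU;LOH", TP53 = "MUT"))
  expect_equal(classify_medulloblastoma(p)$subgroup, "SHH_TP53mut")
  # TERTp-only SHH assignment is a config switch
  p <- case_profile("m", "medulloblastoma", hotspot_flags = c(TERTp = TRUE))
  expect_equal(classify_medulloblastoma(p)$subgroup, "SHH_TP53wt")
  expect_equal(classify_medulloblastoma(p, tertp_implies_shh = FALSE)$subgroup,
               "nonWNT_nonSHH")
  # isodicentric 17q is recorded as supporting evidence only
  p <- case_profile("m", "medulloblastoma",
                    region_calls = c(`17p` = "DEL", `17q` = "AMP"))
  r <- classify_medulloblastoma(p)
  expect_equal(r$subgroup, "nonWNT_nonSHH")
  expect_true("i17q" %in% r$evidence[[1]]$alterations)
})

test_that("rule engine evidence never cites absent alterations", {
  all_alts <- function(p) c(names(p$gene_calls), names(p$region_calls),
                            names(p$hotspot_flags)[p$hotspot_flags],
                            "monosomy 6", "i17q", "17q gain", "chr7 gain", "TERTp")
  for (p in mb_reference_profiles()) {
    r <- classify_medulloblastoma(p)
    for (e in r$evidence)
      expect_true(all(e$alterations %in% all_alts(p)), label = p$case_id)
  }
})

test_that("meningioma risk report counts flags and CNV complexity", {
  p <- case_profile("M_4", "meningioma",
                    gene_calls = c(NF2 = "TRU", CDKN2A = "HOMDEL"),
                    region_calls = c(`1p` = "DEL"))
  r <- meningioma_risk(p)
  expect_setequal(r$unfavorable, c("1p loss", "CDKN2A loss"))
  expect_equal(r$cnv_complexity, 2)
  expect_false(r$high_complexity)

  # 14 CNV events: high complexity
  regions <- setNames(rep("DEL", 7), c("1p", "19q", "10q", "chr6", "chr7",
                                       "chr10", "chr17"))
  genes <- setNames(rep("AMP", 7), c("EGFR", "CDK6", "MET", "KIT", "MDM2",
                                     "CDK4", "MYC"))
  p <- case_profile("M_13", "meningioma", gene_calls = genes,
                    region_calls = regions)
  r <- meningioma_risk(p)
  expect_equal(r$cnv_complexity, 14)
  expect_true(r$high_complexity)

  # favorable profile with zero complexity
  p <- case_profile("M_f", "meningioma",
                    gene_calls = c(TRAF7 = "MUT", KLF4 = "MUT"))
  r <- meningioma_risk(p)
  expect_setequal(r$favorable, c("TRAF7", "KLF4"))
  expect_equal(r$cnv_complexity, 0)
  expect_length(r$unfavorable, 0)
})

test_that("therapy annotation respects panel roles and suppresses germline", {
  pan <- default_panel()
  p <- case_profile("sGB_6", "diffuse_glioma",
                    gene_calls = c(MET = "AMP", KIT = "AMP", TP53 = "MUT",
                                   NF1 = "TRU", ATRX = "MUTGER"))
  t <- annotate_therapy(p, pan)
  expect_setequal(t$targetable$gene, c("MET", "KIT"))
  expect_true(all(grepl("kinase", t$targetable$rationale)))
  expect_true("NF1" %in% t$resistance$gene)
  expect_false("TP53" %in% t$targetable$gene)   # no targetable role
  expect_false("ATRX" %in% c(t$targetable$gene, t$resistance$gene))  # MUTGER

  p2 <- case_profile("aA_8", "diffuse_glioma", gene_calls = c(CDK6 = "AMP"))
  t2 <- annotate_therapy(p2, pan)
  expect_equal(t2$targetable$rationale, "CDK4/6 inhibitor class")
})

test_that("oncoprint matrix holds the controlled vocabulary and round-trips", {
  pan <- default_panel()
  p1 <- case_profile("c1", "diffuse_glioma", gene_calls = c(IDH1 = "MUT"))
  m <- oncoprint_matrix(list(p1), pan)
  expect_equal(dim(m), c(57 + 7, 1))
  expect_equal(sum(m != ""), 1)
  expect_equal(m["IDH1", "c1"], "MUT")

  # multi-event cell and region states; round-trip through TSV
  p2 <- case_profile("c2", "diffuse_glioma",
                     gene_calls = c(PTCH1 = "TRU;LOH"),
                     region_calls = c(`1p` = "LOH", chr7 = "BALANCED"))
  m2 <- oncoprint_matrix(list(p1, p2), pan)
  expect_equal(m2["PTCH1", "c2"], "TRU;LOH")
  expect_equal(m2["1p", "c2"], "LOH")
  expect_equal(m2["chr7", "c2"], "")  # balanced renders empty
  f <- tempfile(fileext = ".tsv")
  write_oncoprint(m2, f)
  expect_identical(read_oncoprint(f), m2)

  # all-empty matrix keeps the full frame
  m0 <- oncoprint_matrix(list(case_profile("c0", "other")), pan)
  expect_equal(dim(m0), c(64, 1))
  expect_true(all(m0 == ""))

  # unknown category string errors
  expect_error(case_profile("bad", "other", gene_calls = c(IDH1 = "WEIRD")),
               "unknown gene category")
})

test_that("cohort count table reproduces the printed frequencies", {
  fr <- alteration_frequencies()
  get <- function(ent, alt) fr$frequency_pct[fr$entity == ent & fr$alteration == alt]
  expect_equal(get("astrocytic_glioma_IDHmut", "TP53"), 95)
  expect_equal(get("oligodendroglioma_IDHmut_codel", "CIC"), 79)
  expect_equal(get("oligodendroglioma_IDHmut_codel", "TERTp"), 100)
  expect_equal(get("astrocytic_glioma_IDHwt", "TERTp"), 71)
  expect_equal(get("meningioma", "NF2"), 79)
  expect_equal(get("medulloblastoma", "TERTp"), 38)
})
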