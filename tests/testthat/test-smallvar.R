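test_that("one-sided Fisher p equals the enumeration oracle on canonical tables", {
  cases <- list(c(0, 10, 10, 0), c(10, 0, 0, 10), c(5, 5, 5, 5),
                c(40, 60, 0, 50), c(3, 97, 1, 99), c(7, 3, 2, 8))
  for (cs in cases) {
    got <- fisher_exact_2x2(cs[1], cs[2], cs[3], cs[4])
    expect_equal(got, fisher_oracle(cs[1], cs[2], cs[3], cs[4]), tolerance = 1e-12)
  }
  expect_gte(fisher_exact_2x2(5, 5, 5, 5), 0.5)
  # all-zero margin: only one table possible
  expect_equal(fisher_exact_2x2(0, 0, 5, 7), 1.0)
  expect_equal(fisher_exact_2x2(0, 5, 0, 7), 1.0)
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("Fisher p agrees with fisher.test and is swap-symmetric on random tables", {
  set.seed(42)
  for (i in 1:50) {
    t <- rpois(4, 8)
    got <- fisher_exact_2x2(t[1], t[2], t[3], t[4])
    ref <- stats::fisher.test(matrix(t, 2, byrow = TRUE),
                              alternative = "greater")$p.value
    expect_equal(got, ref, tolerance = 1e-9)
    # simultaneous row + column swap preserves the one-sided tail
    expect_equal(got, fisher_exact_2x2(t[4], t[3], t[2], t[1]), tolerance = 1e-12)
  }
})

test_that("paired somatic calling follows the VAF/normal/significance rule", {
  th <- caller_thresholds()
  r <- call_somatic(site_row(60, 40, 50, 0), th)
  expect_equal(r$status, "somatic")
  expect_equal(r$t_vaf, 0.4)
  expect_lt(r$p_value, 0.05)

  # het normal is germline, never somatic
  r <- call_somatic(site_row(10, 40, 25, 25), th)
  expect_equal(r$status, "germline")

  # tumor VAF 5% is below the 10% sensitivity floor
  r <- call_somatic(site_row(95, 5, 50, 0), th)
  expect_false(r$status == "somatic")

  # VAF exactly 0.10 passes (inclusive boundary)
  r <- call_somatic(site_row(900, 100, 500, 0), th)
  expect_equal(r$status, "somatic")

  # insufficient / zero coverage is ambiguous, not an error
  expect_equal(call_somatic(site_row(3, 1, 50, 0), th)$status, "ambiguous")
  expect_equal(call_somatic(site_row(0, 0, 50, 0), th)$status, "ambiguous")
})

test_that("false-positive filter removes low-VAF, low-alt and low-quality calls", {
  th <- caller_thresholds()
  mk <- function(...) fp_filter(call_somatic(site_row(...), th), th)
  # VAF 0.099 < 0.10: never survives (status already not somatic, stays none)
  r <- mk(901, 99, 1000, 0)
  expect_false(r$status == "somatic")
  # exactly 0.10 passes
  r <- mk(900, 100, 1000, 0)
  expect_equal(r$status, "somatic")
  expect_false(r$filtered)
  # 2 alt reads at high VAF in a shallow tumor: min_alt fires
  r <- mk(8, 2, 500, 0)
  expect_true(r$filtered)
  expect_equal(r$filter_reason, "min_alt")
  expect_equal(r$status, "ambiguous")
  # low base quality
  r <- mk(60, 40, 50, 0, mean_baseq = 15)
  expect_true(r$filtered)
  expect_equal(r$filter_reason, "low_qual")
})

test_that("no somatic call below 10% tumor VAF survives filtering (simulated sites)", {
  set.seed(7)
  n <- 10000
  t_tot <- rpois(n, 300) + 20
  t_alt <- rbinom(n, t_tot, runif(n, 0, 0.3))
  n_tot <- rpois(n, 300) + 20
  n_alt <- rbinom(n, n_tot, 0.01)
  sites <- data.frame(chrom = "chr1", pos = seq_len(n), ref = "A", alt = "G",
                      t_ref = t_tot - t_alt, t_alt = t_alt,
                      n_ref = n_tot - n_alt, n_alt = n_alt, mean_baseq = 36)
  out <- fp_filter(call_somatic(sites), caller_thresholds())
  som <- out$status == "somatic"
  expect_true(all(out$t_vaf[som] >= 0.10))
})

test_that("hotspot report is threshold-free and flags missing coverage", {
  hs <- data.frame(name = c("IDH1_R132", "BRAF_V600", "TERTp_C228T"),
                   chrom = c("chr2", "chr7", "chr5"),
                   pos = c(209113112, 140453136, 1295228))
  sites <- rbind(
    site_row(65, 35, 100, 0, chrom = "chr2", pos = 209113112),
    site_row(92, 8, 100, 0, chrom = "chr7", pos = 140453136),
    site_row(0, 0, 0, 0, chrom = "chr5", pos = 1295228))
  rep <- hotspot_report(sites, hs)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$t_vaf[rep$name == "IDH1_R132"], 0.35)
  # below the caller threshold but still reported with the exact count ratio
  expect_equal(rep$t_vaf[rep$name == "BRAF_V600"], 0.08)
  expect_equal(rep$flag[rep$name == "TERTp_C228T"], "no_data")
  expect_warning(hotspot_report(sites[1:2, ], hs), "without count data")
})

test_that("rare-germline MUTGER rule uses strict population thresholds", {
  calls <- call_somatic(rbind(site_row(25, 25, 26, 24),
                              site_row(25, 25, 26, 24),
                              site_row(25, 25, 26, 24)))
  out <- flag_germline(calls, maf_nfe = c(0.005, 0.02, 0.009),
                       n_hom = c(2, 0, 5))
  expect_equal(out$category, c("MUTGER", "none", "none"))
  expect_warning(flag_germline(calls, maf_nfe = c(NA, 0.5, 0.5), n_hom = c(1, 1, 1)),
                 "without population annotation")
})

test_that("effect classification separates truncating from missense-type variants", {
  # frameshift single-base deletion
  expect_equal(classify_effect("AT", "A"), "TRU")
  # missense SNV
  expect_equal(classify_effect("G", "A"), "MUT")
  # in-frame 3-base deletion
  expect_equal(classify_effect("AGTC", "A"), "MUT")
  # annotation wins where length arithmetic is blind
  expect_equal(classify_effect("C", "T", effect = "stopgain"), "TRU")
  expect_equal(classify_effect("C", "T", effect = "splicing"), "TRU")
  expect_equal(classify_effect("C", "T", effect = "promoter"), "MUT")
})

test_that("VCF output carries filter and INFO fields", {
  calls <- fp_filter(call_somatic(rbind(site_row(60, 40, 50, 0),
                                        site_row(8, 2, 500, 0))))
  f <- tempfile(fileext = ".vcf")
  write_calls_vcf(calls, f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2)
  expect_match(body[1], "PASS.*SS=somatic")
  expect_match(body[2], "min_alt")
})
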