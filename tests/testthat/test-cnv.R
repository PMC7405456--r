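test_that("log2 ratios are library-size invariant and clamped", {
  n <- 100
  counts <- data.frame(chrom = "chr1", pos = seq_len(n) * 1000, ref = "A",
                       alt = "G", t_ref = 200, t_alt = 0, n_ref = 200, n_alt = 0)
  r <- log2_ratios(counts)
  expect_equal(r$log2r, rep(0, n))

  # doubling tumor depth genome-wide changes nothing after normalization
  c2 <- counts; c2$t_ref <- 400
  expect_equal(log2_ratios(c2)$log2r, rep(0, n))

  # low-coverage normal loci are dropped; extreme ratios clamp at 4
  c3 <- counts
  c3$n_ref[1] <- 5
  c3$t_ref[2] <- 200 * 2^6
  r3 <- log2_ratios(c3)
  expect_equal(nrow(r3), n - 1)
  expect_lte(max(r3$log2r), 4)
  expect_error(log2_ratios(transform(counts, n_ref = 0, n_alt = 0)),
               "zero total depth")
})

test_that("segmentation recovers a noisy step and is deterministic", {
  set.seed(5)
  x <- c(rnorm(50, 0, 0.1), rnorm(50, -1, 0.1))
  ratios <- data.frame(chrom = "chr1", pos = seq_len(100) * 1000, log2r = x)
  seg <- segment_ratios(ratios, seed = 3)
  expect_equal(nrow(seg), 2)
  # boundary within +/- 2 loci of the true changepoint
  expect_lte(abs(seg$n_loci[1] - 50), 2)
  expect_equal(seg$mean_log2[1], mean(x[seq_len(seg$n_loci[1])]))
  expect_identical(seg, segment_ratios(ratios, seed = 3))

  # constant input stays one segment with the exact mean
  flat <- data.frame(chrom = "chr1", pos = seq_len(30) * 1000, log2r = 0.25)
  s1 <- segment_ratios(flat, seed = 1)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$mean_log2, 0.25)
  expect_equal(s1$n_loci, 30)

  # fewer loci than 2*min_loci: single segment
  tiny <- data.frame(chrom = "chr1", pos = 1:4 * 1000, log2r = c(0, 0, 5, 5))
  expect_equal(nrow(segment_ratios(tiny, seed = 1)), 1)
})

test_that("SEG files round-trip and can bypass internal segmentation", {
  seg <- data.frame(chrom = "chr1", start = c(0, 5e6), end = c(5e6, 9e6),
                    n_loci = c(10L, 8L), mean_log2 = c(0.1, -0.8))
  seg$length <- seg$end - seg$start
  f <- tempfile(fileext = ".seg")
  write_seg(seg, f)
  expect_equal(read_seg(f), seg)
})

test_that("size-sorted baseline follows the documented accumulation rule", {
  # single segment: baseline is its mean
  s1 <- data.frame(chrom = "chr1", start = 0, end = 1e6, n_loci = 10,
                   mean_log2 = 0.3, length = 1e6)
  expect_equal(estimate_baseline(s1)$value, 0.3)

  # 60% of length at -0.32 (pervasive loss), 40% at 0: the rule picks the
  # pervasive state as baseline
  s2 <- data.frame(chrom = c("chr1", "chr2"), start = 0, end = c(6e7, 4e7),
                   n_loci = 10, mean_log2 = c(-0.32, 0), length = c(6e7, 4e7))
  b <- estimate_baseline(s2)
  expect_equal(b$value, -0.32)
  # and chromosomes at 0 then sit +0.32 above it (documented behavior)
  expect_equal(cnv_state_region(0 - b$value), "BALANCED")

  # LOH exclusion removes the lost chromosome from the pool
  pan <- toy_panel(50)
  s3 <- data.frame(chrom = c("chr1", "chr2"), start = 0, end = c(6e7, 5e7),
                   n_loci = 10, mean_log2 = c(-0.7, 0.01), length = c(6e7, 5e7))
  loh <- data.frame(region = "chr1", n_eligible = 20, n_loh = 18, status = "LOH")
  b3 <- estimate_baseline(s3, loh, pan)
  expect_false(b3$used_loh_exclusion)  # chr2 alone is < 50% of covered length
  s4 <- data.frame(chrom = c("chr1", "chr2"), start = 0, end = c(4e7, 6e7),
                   n_loci = 10, mean_log2 = c(-0.7, 0.01), length = c(4e7, 6e7))
  b4 <- estimate_baseline(s4, loh, pan)
  expect_true(b4$used_loh_exclusion)
  expect_equal(b4$value, 0.01)
})

test_that("baseline on a simulated diploid genome is near zero", {
  pan <- toy_panel(150)
  s <- simulate_case(pan, sim_config(purity = 0.8, mean_depth = 500, seed = 31,
                                     ffpe_artifact_rate = 0))
  res <- call_cnv(s$counts, pan, seed = 2, regions = c("chr1", "chr2"))
  expect_lt(abs(res$baseline$value), 0.05)
  expect_true(all(res$region_calls$state == "BALANCED"))
})

test_that("region and gene state boundaries match the printed constants", {
  # region: 0.40 exactly balanced, 0.41 amplified (strict "more than")
  expect_equal(cnv_state_region(0.40), "BALANCED")
  expect_equal(cnv_state_region(0.41), "AMP")
  expect_equal(cnv_state_region(-0.40), "BALANCED")
  expect_equal(cnv_state_region(-0.41), "DEL")
  # gene: 0.5 inclusive relevance, 1.0 strict escalation
  expect_equal(cnv_state_gene(0.49), "BALANCED")
  expect_equal(cnv_state_gene(0.5), "AMP")
  expect_equal(cnv_state_gene(1.0), "AMP")
  expect_equal(cnv_state_gene(1.2), "HIGHCOPY")
  expect_equal(cnv_state_gene(-0.5), "DEL")
  expect_equal(cnv_state_gene(-1.0), "DEL")
  expect_equal(cnv_state_gene(-1.01), "HOMDEL")
})

test_that("state calls are monotone in delta", {
  ord <- c(HOMDEL = 1, DEL = 2, BALANCED = 3, AMP = 4, HIGHCOPY = 5)
  d <- seq(-2, 2, by = 0.01)
  expect_true(all(diff(ord[cnv_state_gene(d)]) >= 0))
  expect_true(all(diff(ord[cnv_state_region(d)]) >= 0))
})

test_that("region calls are length-weighted and flag partial events", {
  pan <- toy_panel(50)
  seg <- data.frame(chrom = "chr1", start = c(0, 100e6), end = c(100e6, 240e6),
                    n_loci = 10, mean_log2 = c(0.9, 0.0))
  seg$length <- seg$end - seg$start
  rc <- call_region(seg, pan, "chr1", baseline = 0)
  expect_true(rc$partial)
  expect_equal(rc$state, "BALANCED")  # majority length is balanced
  rc2 <- call_region(seg[1, ], pan, "chr1", baseline = 0)
  expect_false(rc2$partial)
  expect_equal(rc2$state, "AMP")
  # uncovered region
  rc3 <- call_region(seg[0, ], pan, "chr2", baseline = 0)
  expect_true(is.na(rc3$state))
})

test_that("combined 7 gain + 10 loss needs whole-chromosome non-partial calls", {
  mk <- function(s7, s10, p7 = FALSE, p10 = FALSE)
    data.frame(target = c("chr7", "chr10"), level = "chromosome",
               delta = c(0.5, -0.5), state = c(s7, s10), partial = c(p7, p10))
  expect_true(detect_7gain_10loss(mk("AMP", "DEL")))
  expect_false(detect_7gain_10loss(mk("AMP", "BALANCED")))
  expect_warning(got <- detect_7gain_10loss(mk("AMP", "DEL", p7 = TRUE)), "partial")
  expect_false(got)
  expect_warning(got <- detect_7gain_10loss(mk(NA, "DEL")), "uninformative")
  expect_false(got)
})

test_that("baseline estimation is shift-equivariant and calls are unchanged", {
  pan <- toy_panel(80)
  s <- simulate_case(pan, sim_config(purity = 0.8, mean_depth = 400, seed = 17,
                                     ffpe_artifact_rate = 0),
                     list(somatic_event("CNV_loss", "chr2", copies = 1)))
  r <- log2_ratios(s$counts)
  seg <- segment_ratios(r, seed = 4)
  b <- estimate_baseline(seg)
  for (const in c(-0.8, 0.6)) {
    seg2 <- seg; seg2$mean_log2 <- seg2$mean_log2 + const
    b2 <- estimate_baseline(seg2)
    expect_equal(b2$value, b$value + const, tolerance = 1e-12)
    for (rg in c("chr1", "chr2")) {
      c1 <- call_region(seg, pan, rg, b$value)
      c2 <- call_region(seg2, pan, rg, b2$value)
      expect_equal(c2$state, c1$state)
      expect_equal(c2$delta, c1$delta, tolerance = 1e-12)
    }
  }
})
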