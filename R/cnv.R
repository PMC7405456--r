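# Copy-number analysis: log2 ratios, segmentation, size-sorted baseline,
# five-state region/gene calls.

#' CNV calling thresholds (log2-ratio scale)
#'
#' @param region_window half-width of the balanced band around the baseline
#'   for chromosomal regions (0.4; strictly more than +/-0.4 calls AMP/DEL).
#' @param gene_cutoff minimum |delta| for a relevant gene-level call (0.5,
#'   inclusive).
#' @param extreme_offset gene-level delta beyond which AMP escalates to
#'   HIGHCOPY and DEL to HOMDEL (1.0, strict).
#' @return a `cnv_thresholds` list.
#' @export
cnv_thresholds <- function(region_window = 0.4, gene_cutoff = 0.5,
                           extreme_offset = 1.0) {
  stopifnot(region_window > 0, gene_cutoff > 0, extreme_offset > 0)
  structure(list(region_window = region_window, gene_cutoff = gene_cutoff,
                 extreme_offset = extreme_offset), class = "cnv_thresholds")
}

#' Library-size-normalized per-locus log2 tumor/normal depth ratios
#'
#' @param counts data.frame with chrom, pos, t_ref, t_alt, n_ref, n_alt.
#' @param min_normal_depth loci with fewer normal reads are dropped (10).
#' @param clamp absolute clamp on the log2 ratio (4).
#' @return data.frame chrom, pos, log2r, sorted by chrom/pos.
#' @export
log2_ratios <- function(counts, min_normal_depth = 10, clamp = 4) {
  t_d <- counts$t_ref + counts$t_alt
  n_d <- counts$n_ref + counts$n_alt
  T_tot <- sum(t_d); N_tot <- sum(n_d)
  if (N_tot == 0) stop_bad("normal sample has zero total depth")
  if (T_tot == 0) stop_bad("tumor sample has zero total depth")
  keep <- n_d >= min_normal_depth
  r <- log2((t_d[keep] / T_tot) / (n_d[keep] / N_tot))
  r <- pmax(pmin(r, clamp), -clamp)
  out <- data.frame(chrom = counts$chrom[keep], pos = counts$pos[keep],
                    log2r = r, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

# max two-sample t statistic over all split points with both sides >= min_loci;
# returns list(stat, k) or NULL
best_split <- function(x, min_loci) {
  n <- length(x)
  if (n < 2 * min_loci) return(NULL)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  k <- min_loci:(n - min_loci)
  n1 <- k; n2 <- n - k
  m1 <- cs[k] / n1
  m2 <- (cs[n] - cs[k]) / n2
  ss1 <- cs2[k] - n1 * m1^2
  ss2 <- (cs2[n] - cs2[k]) - n2 * m2^2
  s2 <- (ss1 + ss2) / pmax(n - 2, 1)
  s2 <- pmax(s2, 1e-12)
  tt <- abs(m1 - m2) / sqrt(s2 * (1 / n1 + 1 / n2))
  i <- which.max(tt)
  list(stat = tt[i], k = k[i])
}

#' Segment per-locus log2 ratios by recursive binary splitting
#'
#' Within each chromosome, the split maximizing the two-sample t statistic
#' is accepted when a seeded permutation test gives p < `alpha` and both
#' sides keep at least `min_loci` loci; accepted sides are split
#' recursively. This is an intentional simplification of circular binary
#' segmentation; supply an external SEG file to the pipeline to bypass it.
#'
#' @param ratios data.frame from [log2_ratios()] (chrom, pos, log2r), sorted.
#' @param min_loci minimum loci per segment (5).
#' @param alpha permutation p-value threshold for accepting a split (0.01).
#' @param n_perm permutations per candidate split (499).
#' @param seed seed for the permutation null (deterministic output).
#' @return data.frame of segments: chrom, start, end (0-based half-open
#'   locus span), n_loci, mean_log2, length.
#' @export
segment_ratios <- function(ratios, min_loci = 5, alpha = 0.01, n_perm = 499,
                           seed = 1L) {
  stopifnot(n_perm >= 1 / alpha - 1)
  seg_one <- function(x) { # returns list of index ranges into x
    counter <- 0L
    recurse <- function(lo, hi) {
      xs <- x[lo:hi]
      bs <- best_split(xs, min_loci)
      if (!is.null(bs)) {
        counter <<- counter + 1L
        exceed <- with_seed(seed + counter, {
          sum(vapply(seq_len(n_perm), function(b) {
            bp <- best_split(sample(xs), min_loci)
            bp$stat >= bs$stat
          }, TRUE))
        })
        p <- (1 + exceed) / (n_perm + 1)
        if (p < alpha) {
          k <- lo + bs$k - 1L
          return(c(recurse(lo, k), recurse(k + 1L, hi)))
        }
      }
      list(c(lo, hi))
    }
    recurse(1L, length(x))
  }
  out <- list()
  for (ch in unique(ratios$chrom)) {
    d <- ratios[ratios$chrom == ch, , drop = FALSE]
    for (rg in seg_one(d$log2r)) {
      i <- rg[1]:rg[2]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = d$pos[rg[1]] - 1, end = d$pos[rg[2]],
        n_loci = length(i), mean_log2 = mean(d$log2r[i]),
        stringsAsFactors = FALSE)
    }
  }
  seg <- do.call(rbind, out)
  seg$length <- seg$end - seg$start
  rownames(seg) <- NULL
  seg
}

#' Read / write SEG files (tab-separated, 0-based half-open)
#'
#' @param path file path.
#' @return for `read_seg`, a segments data.frame as produced by
#'   [segment_ratios()].
#' @export
read_seg <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "n_loci", "mean_log2")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_bad("SEG file lacks columns: %s", paste(miss, collapse = ", "))
  x$length <- x$end - x$start
  x
}

#' @rdname read_seg
#' @param segments a segments data.frame.
#' @export
write_seg <- function(segments, path) {
  write.table(segments[, c("chrom", "start", "end", "n_loci", "mean_log2")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Estimate the per-sample copy-number baseline by segment-size sorting
#'
#' Segments are sorted by genomic length (descending); segments overlapping
#' LOH-called regions are excluded first (an allele loss shifts depth and
#' would drag the baseline); the largest remaining segments are accumulated
#' until they cover at least `stop_fraction` of the total segmented length,
#' and the baseline is their length-weighted median log2 ratio. If the LOH
#' exclusion leaves less than `stop_fraction` of the length (e.g. genome-wide
#' LOH), the exclusion is dropped and `used_loh_exclusion` is FALSE.
#'
#' @param segments segments data.frame.
#' @param loh_calls optional region LOH call data.frame (from [call_loh()]).
#' @param panel required when `loh_calls` is given, to resolve region spans.
#' @param stop_fraction cumulative-length stopping fraction (0.5).
#' @return list(value, support_fraction, used_loh_exclusion).
#' @export
estimate_baseline <- function(segments, loh_calls = NULL, panel = NULL,
                              stop_fraction = 0.5) {
  stopifnot(nrow(segments) >= 1)
  total_len <- sum(segments$length)
  excl <- rep(FALSE, nrow(segments))
  if (!is.null(loh_calls) && any(loh_calls$status %in% "LOH")) {
    if (is.null(panel)) stop_bad("panel needed to resolve LOH region spans")
    for (rn in loh_calls$region[loh_calls$status %in% "LOH"]) {
      sp <- region_span(panel, rn)
      excl <- excl | (segments$chrom == sp$chrom &
                        segments$start < sp$end & segments$end > sp$start)
    }
  }
  used_loh <- any(excl) && sum(segments$length[!excl]) >= stop_fraction * total_len
  pool <- if (used_loh) segments[!excl, , drop = FALSE] else segments
  pool <- pool[order(-pool$length), , drop = FALSE]
  ncum <- cumsum(pool$length)
  take <- seq_len(which(ncum >= stop_fraction * total_len)[1])
  acc <- pool[take, , drop = FALSE]
  list(value = weighted_median(acc$mean_log2, acc$length),
       support_fraction = sum(acc$length) / total_len,
       used_loh_exclusion = used_loh)
}

#' Five-state classification of a gene-level delta
#'
#' BALANCED for |delta| < 0.5; AMP for 0.5 <= delta <= 1; HIGHCOPY for
#' delta > 1; DEL for -1 <= delta <= -0.5; HOMDEL for delta < -1. The
#' relevance cut-off is inclusive, the highcopy/homdel escalation strict.
#'
#' @param delta numeric vector of mean log2 ratio minus baseline.
#' @param thresholds a [cnv_thresholds()].
#' @return character vector of states.
#' @export
cnv_state_gene <- function(delta, thresholds = cnv_thresholds()) {
  th <- thresholds
  ifelse(delta > th$extreme_offset, "HIGHCOPY",
  ifelse(delta >= th$gene_cutoff, "AMP",
  ifelse(delta < -th$extreme_offset, "HOMDEL",
  ifelse(delta <= -th$gene_cutoff, "DEL", "BALANCED"))))
}

#' Three-state classification of a region-level delta
#'
#' BALANCED for |delta| <= 0.4; AMP strictly above +0.4; DEL strictly below
#' -0.4.
#'
#' @inheritParams cnv_state_gene
#' @return character vector of states.
#' @export
cnv_state_region <- function(delta, thresholds = cnv_thresholds()) {
  th <- thresholds
  ifelse(delta > th$region_window, "AMP",
         ifelse(delta < -th$region_window, "DEL", "BALANCED"))
}

#' Call copy-number state for a chromosomal region
#'
#' Delta is the length-weighted mean of the segments intersected with the
#' region span, minus the baseline. When segments within the region disagree
#' in state the call is flagged `partial` and the majority-length state is
#' reported (AMPp/DELp vocabulary).
#'
#' @param segments segments data.frame.
#' @param panel a `panel_def`.
#' @param region region name ("chr7", "1p", "17q", ...).
#' @param baseline baseline log2 value (from [estimate_baseline()]).
#' @param thresholds a [cnv_thresholds()].
#' @return one-row data.frame: target, level, delta, state, partial.
#' @export
call_region <- function(segments, panel, region, baseline,
                        thresholds = cnv_thresholds()) {
  sp <- region_span(panel, region)
  level <- if (grepl("[pq]$", region)) "arm" else "chromosome"
  s <- segments[segments$chrom == sp$chrom &
                  segments$start < sp$end & segments$end > sp$start, , drop = FALSE]
  if (!nrow(s))
    return(data.frame(target = region, level = level, delta = NA_real_,
                      state = NA_character_, partial = NA, stringsAsFactors = FALSE))
  w <- pmin(s$end, sp$end) - pmax(s$start, sp$start)
  delta_seg <- s$mean_log2 - baseline
  delta <- sum(w * delta_seg) / sum(w)
  st_seg <- cnv_state_region(delta_seg, thresholds)
  partial <- length(unique(st_seg)) > 1
  state <- if (partial) {
    byst <- tapply(w, st_seg, sum)
    names(byst)[which.max(byst)]
  } else cnv_state_region(delta, thresholds)
  data.frame(target = region, level = level, delta = delta, state = state,
             partial = partial, stringsAsFactors = FALSE)
}

#' Call gene-level copy-number states
#'
#' Delta per gene is the mean log2 ratio over the gene's loci (intronic SNP
#' backbone and/or coding sites) minus the baseline. Genes without any
#' ratio-bearing locus are reported with state NA (uncovered).
#'
#' @param ratios data.frame from [log2_ratios()].
#' @param panel a `panel_def`.
#' @param baseline baseline log2 value.
#' @param thresholds a [cnv_thresholds()].
#' @param genes gene names to call (default: genes with an intronic CNV
#'   backbone).
#' @return data.frame: target, level, delta, state, partial (always FALSE at
#'   gene scale), n_loci.
#' @export
call_genes <- function(ratios, panel, baseline, thresholds = cnv_thresholds(),
                       genes = NULL) {
  if (is.null(genes)) genes <- panel$genes$name[panel$genes$intronic_cnv_snps]
  loc <- locate(panel, ratios$chrom, ratios$pos)
  out <- lapply(genes, function(g) {
    sel <- loc$type == "gene" & loc$target == g
    if (!any(sel))
      return(data.frame(target = g, level = "gene", delta = NA_real_,
                        state = NA_character_, partial = FALSE, n_loci = 0L,
                        stringsAsFactors = FALSE))
    delta <- mean(ratios$log2r[sel]) - baseline
    data.frame(target = g, level = "gene", delta = delta,
               state = cnv_state_gene(delta, thresholds), partial = FALSE,
               n_loci = sum(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Combined chromosome-7 gain and chromosome-10 loss
#'
#' TRUE only for a whole-chromosome (non-partial) chr7 AMP together with a
#' whole-chromosome chr10 DEL; partial or uninformative calls give FALSE
#' with a warning.
#'
#' @param region_calls data.frame of region CNV calls (must contain targets
#'   "chr7" and "chr10").
#' @return logical.
#' @export
detect_7gain_10loss <- function(region_calls) {
  g7 <- region_calls[region_calls$target == "chr7", , drop = FALSE]
  l10 <- region_calls[region_calls$target == "chr10", , drop = FALSE]
  if (!nrow(g7) || !nrow(l10)) stop_bad("need region calls for chr7 and chr10")
  if (anyNA(c(g7$state, l10$state))) {
    warning("chr7/chr10 call uninformative; 7+/10- not assessable")
    return(FALSE)
  }
  if (isTRUE(g7$partial) || isTRUE(l10$partial)) {
    warning("partial chr7/chr10 event; 7+/10- requires whole-chromosome calls, flagged for review")
    return(FALSE)
  }
  g7$state == "AMP" && l10$state == "DEL"
}

#' Whole-case CNV calling
#'
#' Runs ratio computation, segmentation (or an external SEG), LOH-aware
#' baseline estimation, and region plus gene calls.
#'
#' @param counts paired counts data.frame.
#' @param panel a `panel_def`.
#' @param loh_calls optional region LOH calls for baseline exclusion.
#' @param seg optional pre-computed segments data.frame (bypasses the
#'   internal segmentation).
#' @param thresholds a [cnv_thresholds()].
#' @param seed segmentation permutation seed.
#' @param regions region names to call (default: panel regions plus derived
#'   17p/17q).
#' @return list(ratios, segments, baseline, region_calls, gene_calls,
#'   gain7_loss10).
#' @export
call_cnv <- function(counts, panel, loh_calls = NULL, seg = NULL,
                     thresholds = cnv_thresholds(), seed = 1L, regions = NULL) {
  ratios <- log2_ratios(counts)
  segments <- if (is.null(seg)) segment_ratios(ratios, seed = seed) else seg
  baseline <- estimate_baseline(segments, loh_calls, panel)
  if (is.null(regions)) {
    regions <- names(panel$regions)
    if ("chr17" %in% regions) regions <- c(regions, "17p", "17q")
  }
  region_calls <- do.call(rbind, lapply(regions, function(r)
    call_region(segments, panel, r, baseline$value, thresholds)))
  gene_calls <- call_genes(ratios, panel, baseline$value, thresholds)
  g7l10 <- if (all(c("chr7", "chr10") %in% region_calls$target))
    suppressWarnings(detect_7gain_10loss(region_calls)) else NA
  list(ratios = ratios, segments = segments, baseline = baseline,
       region_calls = region_calls, gene_calls = gene_calls,
       gain7_loss10 = g7l10)
}
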