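# Purity-aware paired tumor-normal count simulator with ground truth.

#' Simulation configuration
#'
#' Defaults emulate the assay's operating point: microdissected FFPE tumors
#' with matched blood normals, deep amplicon coverage, and low-VAF C>T
#' deamination artifacts in the tumor sample only.
#'
#' @param purity fraction of tumor cells in the specimen (rho in \[0,1\]).
#' @param mean_depth expected reads per locus (default 500).
#' @param depth_dispersion negative-binomial overdispersion; 0 gives Poisson
#'   depth. Variance = mu + dispersion * mu^2.
#' @param het_prob probability a backbone SNP is heterozygous in the normal.
#' @param ffpe_artifact_rate per-locus probability of a C>T artifact in the
#'   tumor sample at a site without true signal.
#' @param artifact_vaf mean VAF of injected artifacts (default 0.03, i.e.
#'   below the 10 percent somatic filter).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(purity = 0.8, mean_depth = 500, depth_dispersion = 0.05,
                       het_prob = 0.5, ffpe_artifact_rate = 0.02,
                       artifact_vaf = 0.03, seed = 1L) {
  stopifnot(purity >= 0, purity <= 1, mean_depth > 0, depth_dispersion >= 0,
            het_prob >= 0, het_prob <= 1, ffpe_artifact_rate >= 0,
            ffpe_artifact_rate <= 1, artifact_vaf >= 0, artifact_vaf <= 1)
  structure(list(purity = purity, mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion, het_prob = het_prob,
                 ffpe_artifact_rate = ffpe_artifact_rate,
                 artifact_vaf = artifact_vaf, seed = as.integer(seed)),
            class = "sim_config")
}

#' Specify a somatic event for simulation
#'
#' @param kind one of SNV, InDel, CNV_gain, CNV_loss, CN_LOH.
#' @param location a panel gene name, region name (e.g. "chr7", "1p") or
#'   hotspot name (e.g. "IDH1_R132", "TERTp_C228T") for point events.
#' @param copies total tumor copy number for CNV events (2 = neutral).
#' @param ccf cancer-cell fraction for SNV/InDel (0 < ccf <= 1).
#' @param alt_allele_copies copies of the mutant allele in a tumor cell.
#' @return a `somatic_event` list.
#' @export
somatic_event <- function(kind = c("SNV", "InDel", "CNV_gain", "CNV_loss", "CN_LOH"),
                          location, copies = NA_integer_, ccf = 1,
                          alt_allele_copies = 1L) {
  kind <- match.arg(kind)
  if (kind == "CN_LOH") copies <- 2L
  if (kind %in% c("CNV_gain", "CNV_loss")) {
    if (is.na(copies) || copies < 0) stop_bad("CNV event needs copies >= 0")
    if (kind == "CNV_gain" && copies <= 2) stop_bad("CNV_gain needs copies > 2")
    if (kind == "CNV_loss" && copies >= 2) stop_bad("CNV_loss needs copies < 2")
  }
  stopifnot(ccf > 0, ccf <= 1, alt_allele_copies >= 0)
  structure(list(kind = kind, location = location, copies = as.integer(copies),
                 ccf = ccf, alt_allele_copies = as.integer(alt_allele_copies)),
            class = "somatic_event")
}

#' Expected tumor VAF under the purity mixture model
#'
#' A fraction `purity` of cells are tumor (carrying `alt_copies` mutant
#' alleles among `total_copies`), the rest are diploid normal cells carrying
#' `germline_alt_copies` mutant alleles.
#'
#' @param purity tumor cell fraction rho.
#' @param alt_copies mutant allele copies per tumor cell.
#' @param total_copies total copies per tumor cell.
#' @param germline_alt_copies mutant allele copies per normal cell (0, 1, 2).
#' @return expected alt-allele fraction in the tumor specimen.
#' @export
expected_tumor_vaf <- function(purity, alt_copies, total_copies,
                               germline_alt_copies = 0) {
  if (any(alt_copies < 0) || any(total_copies < 0) || any(germline_alt_copies < 0))
    stop_bad("copy numbers must be non-negative")
  num <- (1 - purity) * germline_alt_copies + purity * alt_copies
  den <- (1 - purity) * 2 + purity * total_copies
  out <- ifelse(den == 0, ifelse(num > 0 | alt_copies > 0, 1, 0), num / den)
  if (any(den == 0)) attr(out, "degenerate") <- TRUE
  out
}

#' Expected log2 tumor/normal depth ratio for a total copy number
#'
#' @param purity tumor cell fraction rho.
#' @param total_copies total copies per tumor cell.
#' @param clamp absolute clamp for the ratio (default 4).
#' @return log2(((1-rho)*2 + rho*copies) / 2), clamped to `[-clamp, clamp]`.
#' @export
expected_log2_ratio <- function(purity, total_copies, clamp = 4) {
  r <- log2(((1 - purity) * 2 + purity * total_copies) / 2)
  pmax(pmin(r, clamp), -clamp)
}

# Resolve an event location to (chrom, span or positions).
resolve_location <- function(panel, ev) {
  loc <- ev$location
  if (ev$kind %in% c("SNV", "InDel")) {
    hs <- panel$hotspots
    if (loc %in% hs$name) {
      i <- match(loc, hs$name)
      return(list(chrom = hs$chrom[i], pos = hs$pos[i], gene = hs$gene[i]))
    }
    if (loc %in% panel$genes$name) {
      iv <- panel$intervals[panel$intervals$gene == loc, , drop = FALSE]
      # deterministic representative coding site: centre of the first interval
      return(list(chrom = iv$chrom[1],
                  pos = floor((iv$start[1] + iv$end[1]) / 2) + 1, gene = loc))
    }
    stop_bad("event location not on panel: %s", loc)
  }
  if (loc %in% names(panel$regions) || grepl("^(chr)?\\d+[pq]$", loc)) {
    sp <- region_span(panel, loc)
    return(list(chrom = sp$chrom, start = sp$start, end = sp$end, region = loc))
  }
  if (loc %in% panel$genes$name) {
    iv <- panel$intervals[panel$intervals$gene == loc, , drop = FALSE]
    return(list(chrom = iv$chrom[1], start = min(iv$start) + 1,
                end = max(iv$end), gene = loc))
  }
  stop_bad("event location not on panel: %s", loc)
}

#' Simulate a paired tumor-normal panel case
#'
#' Generates per-locus read counts over the panel's SNP backbones, gene
#' coding sites and hotspot positions. Locus depth is negative-binomial
#' around `mean_depth` (tumor depth additionally scaled by the local copy
#' ratio); alt counts are binomial around the purity-mixture expected VAF.
#' FFPE-like C>T artifacts are injected into the tumor sample only.
#'
#' @param panel a `panel_def`.
#' @param config a `sim_config`.
#' @param events list of `somatic_event`s.
#' @return list with `counts` (data.frame chrom, pos, ref, alt, t_ref, t_alt,
#'   n_ref, n_alt, mean_baseq), and `truth` (list: `events`, `loci` with
#'   per-locus expected VAF and log2 ratio, `config`).
#' @export
simulate_case <- function(panel, config = sim_config(), events = list()) {
  rho <- config$purity
  with_seed(config$seed, {
    snp <- panel_snp_loci(panel)
    # coding representative sites per gene + hotspot positions
    cds <- do.call(rbind, lapply(seq_len(nrow(panel$genes)), function(i) {
      g <- panel$genes$name[i]
      iv <- panel$intervals[panel$intervals$gene == g, , drop = FALSE]
      data.frame(chrom = iv$chrom[1],
                 pos = floor((iv$start[1] + iv$end[1]) / 2) + 1,
                 target = g, target_type = "gene_cds", stringsAsFactors = FALSE)
    }))
    hs <- panel$hotspots
    hsdf <- data.frame(chrom = hs$chrom, pos = hs$pos, target = hs$gene,
                       target_type = "hotspot", stringsAsFactors = FALSE)
    loci <- rbind(snp, cds, hsdf)
    loci <- loci[!duplicated(paste(loci$chrom, loci$pos)), ]
    loci <- loci[order(loci$chrom, loci$pos), ]
    n <- nrow(loci)

    ref <- rep("A", n); alt <- rep("G", n)
    is_backbone <- loci$target_type %in% c("region", "gene")
    germ_alt <- integer(n)  # germline alt copies per normal cell
    germ_alt[is_backbone] <- ifelse(rbinom(sum(is_backbone), 1, config$het_prob) == 1, 1L, 0L)

    copies <- rep(2L, n)          # tumor total copies
    tum_alt <- as.numeric(germ_alt)  # tumor alt copies (per tumor cell)
    evrec <- list()

    for (ev in events) {
      locr <- resolve_location(panel, ev)
      if (ev$kind %in% c("SNV", "InDel")) {
        i <- which(loci$chrom == locr$chrom & loci$pos == locr$pos)
        if (!length(i)) stop_bad("event site %s:%d not simulated", locr$chrom, locr$pos)
        if (ev$kind == "InDel") { ref[i] <- "AT"; alt[i] <- "A" }
        tum_alt[i] <- ev$ccf * ev$alt_allele_copies
        evrec[[length(evrec) + 1]] <- c(ev, list(chrom = locr$chrom, pos = locr$pos,
          expected_vaf = expected_tumor_vaf(rho, ev$ccf * ev$alt_allele_copies,
                                            copies[i], germ_alt[i])))
      } else {
        i <- which(loci$chrom == locr$chrom & loci$pos >= locr$start & loci$pos <= locr$end)
        if (!length(i)) stop_bad("CNV event region has no simulated loci: %s", ev$location)
        copies[i] <- ev$copies
        het <- i[germ_alt[i] == 1]
        if (length(het)) {
          # the alt allele sits on the affected haplotype with probability 1/2
          alt_hap <- rbinom(length(het), 1, 0.5) == 1
          tum_alt[het] <- switch(ev$kind,
            CNV_loss = ifelse(alt_hap, pmax(ev$copies - 1, 0), pmin(1, ev$copies)),
            CNV_gain = ifelse(alt_hap, ev$copies - 1, 1),
            CN_LOH   = ifelse(alt_hap, 2, 0))
        }
        hom <- i[germ_alt[i] == 2]
        if (length(hom)) tum_alt[hom] <- copies[hom]
        evrec[[length(evrec) + 1]] <- c(ev, list(chrom = locr$chrom,
          n_loci = length(i), expected_log2 = expected_log2_ratio(rho, ev$copies)))
      }
    }

    exp_vaf <- expected_tumor_vaf(rho, tum_alt, copies, germ_alt)
    exp_vaf <- pmin(pmax(as.numeric(exp_vaf), 0), 1)
    exp_l2r <- expected_log2_ratio(rho, copies)
    n_vaf <- germ_alt / 2

    size <- if (config$depth_dispersion > 0) 1 / config$depth_dispersion else Inf
    draw_depth <- function(mu) {
      if (is.finite(size)) rnbinom(n, size = size, mu = mu) else rpois(n, mu)
    }
    n_depth <- draw_depth(rep(config$mean_depth, n))
    t_depth <- draw_depth(config$mean_depth * 2^exp_l2r)

    n_alt_reads <- rbinom(n, n_depth, n_vaf)
    t_alt_reads <- rbinom(n, t_depth, exp_vaf)

    # FFPE artifacts: tumor-only, at sites without germline or somatic signal
    quiet <- germ_alt == 0 & tum_alt == 0
    art <- quiet & rbinom(n, 1, config$ffpe_artifact_rate) == 1
    if (any(art)) {
      ref[art] <- "C"; alt[art] <- "T"
      t_alt_reads[art] <- rbinom(sum(art), t_depth[art], config$artifact_vaf)
    }

    counts <- data.frame(
      chrom = loci$chrom, pos = loci$pos, ref = ref, alt = alt,
      t_ref = t_depth - t_alt_reads, t_alt = t_alt_reads,
      n_ref = n_depth - n_alt_reads, n_alt = n_alt_reads,
      mean_baseq = ifelse(art, 30, 36), stringsAsFactors = FALSE)

    truth <- list(
      events = evrec,
      loci = data.frame(chrom = loci$chrom, pos = loci$pos,
                        target = loci$target, target_type = loci$target_type,
                        germline_alt_copies = germ_alt, tumor_total_copies = copies,
                        expected_vaf = exp_vaf, expected_log2 = exp_l2r,
                        is_artifact = art, stringsAsFactors = FALSE),
      config = unclass(config))
    list(counts = counts, truth = truth)
  })
}

#' Write simulated counts and truth to a directory
#'
#' @param sim result of [simulate_case()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(sim$counts, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$events <- lapply(truth$events, function(e) lapply(e, unclass))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a per-locus counts table
#'
#' @param path a TSV with columns chrom, pos, ref, alt, t_ref, t_alt, n_ref,
#'   n_alt, mean_baseq (the simulator's output format).
#' @return data.frame of counts.
#' @export
read_counts <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "t_ref", "t_alt", "n_ref", "n_alt")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_bad("counts file %s lacks columns: %s", path,
                             paste(miss, collapse = ", "))
  if (is.null(x$mean_baseq)) x$mean_baseq <- 36
  x
}
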