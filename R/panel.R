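# Panel definition: genes, chromosomal-region SNP backbones, interval lookup.

#' Load a panel definition from a YAML/JSON config
#'
#' A panel couples gene targets (CDS or hotspot intervals, optional intronic
#' SNP backbones used for gene-level CNV/LOH) with chromosomal-region SNP
#' backbones (arms and whole chromosomes) and centromere positions. All
#' interval coordinates are 0-based half-open; SNP backbone positions are
#' 1-based single bases, matching the counts/VCF convention.
#'
#' The packaged default (`default_panel()`) covers 57 genes, 19 of which carry
#' an intronic SNP backbone for copy-number analysis, 3 chromosomal arms
#' (1p, 19q, 10q) and 4 whole chromosomes (6, 7, 10, 17). The gene list is a
#' reconstruction around the publicly documented core markers and is flagged
#' `reconstructed: true` in the config.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` panel config.
#' @return an object of class `panel_def` with elements `genes` (data.frame),
#'   `intervals` (data.frame gene/chrom/start/end), `regions` (list of
#'   region targets), `hotspots` (data.frame), `centromeres` (named integer),
#'   `genome_build`.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop_bad("panel config not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  panel_from_config(cfg)
}

#' @rdname load_panel
#' @param cfg a list with the structure of the panel YAML (see
#'   `system.file("extdata", "panel_cns_default.yaml", package = "gliopanel")`).
#' @export
panel_from_config <- function(cfg) {
  if (length(cfg$genes) == 0) stop_bad("panel validation: empty gene list")
  gene_names <- vapply(cfg$genes, function(g) g$name %||% NA_character_, "")
  if (anyNA(gene_names)) stop_bad("panel validation: gene without a name")
  dup <- gene_names[duplicated(gene_names)]
  if (length(dup)) stop_bad("panel validation: duplicate gene name(s): %s",
                            paste(unique(dup), collapse = ", "))

  iv <- list(); backbone <- list()
  for (g in cfg$genes) {
    ivs <- g$intervals
    if (length(ivs) == 0) stop_bad("panel validation: gene %s has no intervals", g$name)
    s <- vapply(ivs, function(i) as.numeric(i$start), 0)
    e <- vapply(ivs, function(i) as.numeric(i$end), 0)
    if (any(s < 0)) stop_bad("panel validation: gene %s has negative coordinates", g$name)
    if (any(e <= s)) stop_bad("panel validation: gene %s interval with end <= start", g$name)
    o <- order(s)
    s <- s[o]; e <- e[o]
    if (length(s) > 1 && any(s[-1] < e[-length(e)]))
      stop_bad("panel validation: gene %s has overlapping intervals", g$name)
    iv[[g$name]] <- data.frame(gene = g$name, chrom = g$chrom, start = s, end = e,
                               stringsAsFactors = FALSE)
    if (isTRUE(g$intronic_cnv_snps) && length(g$backbone_snps))
      backbone[[g$name]] <- data.frame(gene = g$name, chrom = g$chrom,
                                       pos = sort(unlist(g$backbone_snps)),
                                       stringsAsFactors = FALSE)
  }
  intervals <- do.call(rbind, iv)
  rownames(intervals) <- NULL

  genes <- data.frame(
    name = gene_names,
    chrom = vapply(cfg$genes, function(g) g$chrom, ""),
    coverage_mode = vapply(cfg$genes, function(g) g$coverage_mode %||% "CDS", ""),
    intronic_cnv_snps = vapply(cfg$genes, function(g) isTRUE(g$intronic_cnv_snps), TRUE),
    roles = vapply(cfg$genes, function(g) paste(unlist(g$roles), collapse = ","), ""),
    stringsAsFactors = FALSE
  )

  centromeres <- unlist(cfg$centromeres)
  regions <- lapply(cfg$regions, function(r) {
    loci <- sort(unique(unlist(r$snp_loci)))
    if (length(loci) != length(unlist(r$snp_loci)))
      stop_bad("panel validation: region %s has duplicate SNP loci", r$name)
    if (r$kind == "arm") {
      cen <- centromeres[[r$chrom]]
      if (is.null(cen)) stop_bad("panel validation: arm %s without centromere for %s",
                                 r$name, r$chrom)
      p_arm <- grepl("p$", r$name)
      bad <- if (p_arm) loci > cen else loci < cen
      if (any(bad))
        stop_bad("panel validation: region %s has %d SNP loci on the wrong side of the centromere",
                 r$name, sum(bad))
    }
    list(name = r$name, kind = r$kind, chrom = r$chrom, snp_loci = loci)
  })
  names(regions) <- vapply(regions, `[[`, "", "name")

  hotspots <- if (length(cfg$hotspots)) {
    data.frame(name = vapply(cfg$hotspots, `[[`, "", "name"),
               gene = vapply(cfg$hotspots, `[[`, "", "gene"),
               chrom = vapply(cfg$hotspots, `[[`, "", "chrom"),
               pos = vapply(cfg$hotspots, function(h) as.numeric(h$pos), 0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(name = character(), gene = character(), chrom = character(),
               pos = numeric(), stringsAsFactors = FALSE)
  }

  gene_backbone <- if (length(backbone)) do.call(rbind, backbone) else
    data.frame(gene = character(), chrom = character(), pos = numeric())
  rownames(gene_backbone) <- NULL

  # every SNP locus maps to exactly one backbone (region or gene)
  keys <- c(unlist(lapply(regions, function(r) paste(r$chrom, r$snp_loci))),
            paste(gene_backbone$chrom, gene_backbone$pos))
  if (anyDuplicated(keys))
    stop_bad("panel validation: SNP locus assigned to more than one backbone")

  structure(list(
    panel_name = cfg$panel_name %||% "panel",
    genome_build = cfg$genome_build %||% "unknown",
    reconstructed = isTRUE(cfg$reconstructed),
    genes = genes, intervals = intervals, gene_backbone = gene_backbone,
    regions = regions, hotspots = hotspots, centromeres = centromeres
  ), class = "panel_def")
}

#' @export
print.panel_def <- function(x, ...) {
  cat(sprintf("<panel_def> %s (%s)\n", x$panel_name, x$genome_build))
  cat(sprintf("  %d genes (%d with intronic CNV SNP backbone), %d regions (%s)\n",
              nrow(x$genes), sum(x$genes$intronic_cnv_snps), length(x$regions),
              paste(names(x$regions), collapse = ", ")))
  invisible(x)
}

#' Packaged default CNS panel
#' @return a `panel_def`.
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "panel_cns_default.yaml",
                         package = "gliopanel", mustWork = TRUE))
}

panel_gene_gr <- function(panel) {
  GenomicRanges::GRanges(panel$intervals$chrom,
                         IRanges::IRanges(panel$intervals$start + 1L, panel$intervals$end),
                         gene = panel$intervals$gene)
}

#' Assign genomic positions to panel targets
#'
#' Gene intervals take precedence over region SNP backbones at the same
#' coordinate; positions matching neither are `none`. Positions are 1-based.
#'
#' @param panel a `panel_def`.
#' @param chrom character vector of chromosome names.
#' @param pos numeric vector of 1-based positions.
#' @return data.frame with columns `chrom`, `pos`, `type`
#'   (gene/region/none) and `target` (name or NA).
#' @export
locate <- function(panel, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  out <- data.frame(chrom = chrom, pos = pos, type = "none",
                    target = NA_character_, stringsAsFactors = FALSE)
  if (!nrow(out)) return(out)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  # query chromosomes outside the panel are a legitimate "none", not a warning
  hit <- suppressWarnings(
    GenomicRanges::findOverlaps(q, panel_gene_gr(panel), select = "first"))
  in_gene <- !is.na(hit)
  out$type[in_gene] <- "gene"
  out$target[in_gene] <- panel$intervals$gene[hit[in_gene]]
  # gene intronic backbones also map to their gene
  for (r in panel$regions) {
    m <- !in_gene & chrom == r$chrom & pos %in% r$snp_loci
    out$type[m] <- "region"
    out$target[m] <- r$name
  }
  gb <- panel$gene_backbone
  if (nrow(gb)) {
    m <- out$type == "none" & paste(chrom, pos) %in% paste(gb$chrom, gb$pos)
    if (any(m)) {
      idx <- match(paste(chrom, pos)[m], paste(gb$chrom, gb$pos))
      out$type[m] <- "gene"
      out$target[m] <- gb$gene[idx]
    }
  }
  out
}

#' Export panel intervals as BED
#'
#' Writes the gene intervals (0-based half-open, name column = gene symbol).
#' SNP backbone positions are written as single-base features named
#' `<region>_snp`.
#'
#' @param panel a `panel_def`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_bed <- function(panel, path) {
  iv <- panel$intervals
  gr1 <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end),
                                name = iv$gene)
  snp <- do.call(rbind, lapply(panel$regions, function(r)
    data.frame(chrom = r$chrom, pos = r$snp_loci, name = paste0(r$name, "_snp"))))
  gr2 <- GenomicRanges::GRanges(snp$chrom, IRanges::IRanges(snp$pos, snp$pos),
                                name = snp$name)
  gr <- suppressWarnings(c(gr1, gr2))  # gene and backbone chrom sets differ
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export a panel back to YAML config
#'
#' `load_panel(export_panel(p, f))` reproduces `p` exactly; used for
#' round-trip validation and for persisting programmatically built panels.
#'
#' @param panel a `panel_def`.
#' @param path output `.yaml` file.
#' @return `path`, invisibly.
#' @export
export_panel <- function(panel, path) {
  genes <- lapply(seq_len(nrow(panel$genes)), function(i) {
    g <- panel$genes[i, ]
    iv <- panel$intervals[panel$intervals$gene == g$name, , drop = FALSE]
    out <- list(name = g$name, chrom = g$chrom,
                intervals = lapply(seq_len(nrow(iv)), function(j)
                  list(start = as.integer(iv$start[j]), end = as.integer(iv$end[j]))),
                coverage_mode = g$coverage_mode,
                intronic_cnv_snps = g$intronic_cnv_snps,
                roles = as.list(strsplit(g$roles, ",", fixed = TRUE)[[1]]))
    bb <- panel$gene_backbone[panel$gene_backbone$gene == g$name, , drop = FALSE]
    if (nrow(bb)) out$backbone_snps <- as.integer(bb$pos)
    out
  })
  regions <- lapply(panel$regions, function(r)
    list(name = r$name, kind = r$kind, chrom = r$chrom,
         snp_loci = as.integer(r$snp_loci)))
  names(regions) <- NULL
  hs <- panel$hotspots
  hotspots <- lapply(seq_len(nrow(hs)), function(i)
    list(name = hs$name[i], gene = hs$gene[i], chrom = hs$chrom[i],
         pos = as.integer(hs$pos[i])))
  cfg <- list(panel_name = panel$panel_name, genome_build = panel$genome_build,
              reconstructed = panel$reconstructed,
              centromeres = as.list(panel$centromeres),
              genes = genes, regions = regions, hotspots = hotspots)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' All SNP backbone loci of a panel
#'
#' @param panel a `panel_def`.
#' @return data.frame `chrom`, `pos` (1-based), `target`, `target_type`
#'   (region or gene).
#' @export
panel_snp_loci <- function(panel) {
  reg <- do.call(rbind, lapply(panel$regions, function(r)
    data.frame(chrom = r$chrom, pos = r$snp_loci, target = r$name,
               target_type = "region", stringsAsFactors = FALSE)))
  gb <- panel$gene_backbone
  if (nrow(gb)) {
    reg <- rbind(reg, data.frame(chrom = gb$chrom, pos = gb$pos, target = gb$gene,
                                 target_type = "gene", stringsAsFactors = FALSE))
  }
  rownames(reg) <- NULL
  reg[order(reg$chrom, reg$pos), ]
}

# Span of a region target in 1-based coordinates, for segment intersection.
# Arms are bounded by the centromere; "17p"/"17q" are accepted as derived
# arms of a chromosome target.
region_span <- function(panel, name) {
  r <- panel$regions[[name]]
  if (is.null(r) && grepl("^(\\d+|chr\\d+)[pq]$", name)) {
    chrom <- paste0("chr", sub("^chr", "", sub("[pq]$", "", name)))
    cen <- panel$centromeres[[chrom]]
    if (is.null(cen)) stop_bad("no centromere recorded for %s", chrom)
    if (grepl("p$", name)) return(list(chrom = chrom, start = 1, end = cen))
    return(list(chrom = chrom, start = cen + 1, end = .Machine$double.xmax))
  }
  if (is.null(r)) stop_bad("unknown region: %s", name)
  if (r$kind == "arm") {
    cen <- panel$centromeres[[r$chrom]]
    if (grepl("p$", r$name)) list(chrom = r$chrom, start = 1, end = cen)
    else list(chrom = r$chrom, start = cen + 1, end = .Machine$double.xmax)
  } else {
    list(chrom = r$chrom, start = 1, end = .Machine$double.xmax)
  }
}
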