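# Element annotation: gene models (BED12 / GFF3), strand-aware TSS,
# promoter/UTR/intron/intergenic classification of tested windows, and the
# ranked report.

#' Construct a gene-annotation container
#'
#' @param genes data frame: `gene`, `chrom`, `strand` (`+`/`-`), `tss`
#'   (1-based), `start`, `end` (0-based half-open transcript extent).
#' @param elements data frame: `gene`, `chrom`, `type`
#'   (`exon`/`intron`/`utr5`/`utr3`/`cds`), `start`, `end` (0-based
#'   half-open).
#' @return object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, elements) {
  genes <- as.data.frame(genes)
  elements <- as.data.frame(elements)
  stopifnot(all(c("gene", "chrom", "strand", "tss", "start", "end") %in%
                  names(genes)),
            all(c("gene", "chrom", "type", "start", "end") %in%
                  names(elements)),
            all(genes$strand %in% c("+", "-")))
  genes$chrom <- harmonize_chrom(genes$chrom)
  elements$chrom <- harmonize_chrom(elements$chrom)
  rownames(genes) <- rownames(elements) <- NULL
  structure(list(genes = genes, elements = elements),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d gene(s), %d element interval(s)\n",
              nrow(x$genes), nrow(x$elements)))
  invisible(x)
}

# exons (0-based half-open, sorted) + CDS extent -> element intervals + TSS
derive_gene_model <- function(gene, chrom, strand, exons, cds_start, cds_end) {
  exons <- exons[order(exons$start), , drop = FALSE]
  tss <- if (strand == "+") exons$start[1] + 1L else exons$end[nrow(exons)]
  el <- data.frame(gene = gene, chrom = chrom, type = "exon",
                   start = exons$start, end = exons$end)
  if (nrow(exons) > 1) {
    el <- rbind(el, data.frame(gene = gene, chrom = chrom, type = "intron",
                               start = exons$end[-nrow(exons)],
                               end = exons$start[-1]))
  }
  clip <- function(lo, hi) {
    s <- pmax(exons$start, lo); e <- pmin(exons$end, hi)
    keep <- e > s
    data.frame(start = s[keep], end = e[keep])
  }
  if (!is.na(cds_start) && cds_end > cds_start) {
    cds <- clip(cds_start, cds_end)
    left <- clip(-Inf, cds_start)
    right <- clip(cds_end, Inf)
    u5 <- if (strand == "+") left else right
    u3 <- if (strand == "+") right else left
    add <- function(type, d) if (nrow(d))
      data.frame(gene = gene, chrom = chrom, type = type,
                 start = d$start, end = d$end) else NULL
    el <- rbind(el, add("cds", cds), add("utr5", u5), add("utr3", u3))
  }
  list(gene = data.frame(gene = gene, chrom = chrom, strand = strand,
                         tss = tss, start = exons$start[1],
                         end = exons$end[nrow(exons)]),
       elements = el)
}

#' Load gene models
#'
#' Reads gene annotation from BED12 (blocks = exons, thick = CDS) or GFF3
#' (gene/mRNA/exon/CDS features). The TSS is the strand-aware transcript
#' start; introns are derived as gaps between exons and UTRs as the exon
#' bases outside the CDS, so both encodings of a gene yield the same model.
#' Transcripts without exons are skipped with a warning.
#'
#' @param path file path.
#' @param format `"bed"` (BED12) or `"gff3"`.
#' @return a [gene_annotation()].
#' @export
load_annotation <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = if (format == "bed") "bed" else "gff3")
  models <- list()
  if (format == "bed") {
    for (i in seq_along(gr)) {
      x <- gr[i]
      blocks <- x$blocks[[1]]
      if (is.null(blocks) || length(blocks) == 0L) {
        warning("transcript '", x$name, "' has no exon blocks; skipped")
        next
      }
      exons <- data.frame(start = GenomicRanges::start(x) - 1L +
                            IRanges::start(blocks) - 1L,
                          end = GenomicRanges::start(x) - 1L +
                            IRanges::end(blocks))
      thick <- x$thick
      cds_start <- IRanges::start(thick)[1] - 1L
      cds_end <- IRanges::end(thick)[1]
      if (cds_end <= cds_start) { cds_start <- NA; cds_end <- NA }
      models[[length(models) + 1L]] <- derive_gene_model(
        as.character(x$name),
        harmonize_chrom(as.character(GenomicRanges::seqnames(x))),
        as.character(GenomicRanges::strand(x)), exons, cds_start, cds_end)
    }
  } else {
    type <- as.character(gr$type)
    tx <- gr[type %in% c("mRNA", "transcript")]
    if (length(tx) == 0L) tx <- gr[type == "gene"]
    for (i in seq_along(tx)) {
      x <- tx[i]
      id <- as.character(x$ID)
      kids <- gr[vapply(gr$Parent, function(p) id %in% p, logical(1))]
      ex <- kids[as.character(kids$type) == "exon"]
      if (length(ex) == 0L) {
        warning("transcript '", id, "' has no exons; skipped")
        next
      }
      cds <- kids[as.character(kids$type) == "CDS"]
      cds_start <- if (length(cds)) min(GenomicRanges::start(cds)) - 1L else NA
      cds_end <- if (length(cds)) max(GenomicRanges::end(cds)) else NA
      name <- as.character(x$Name %||% x$ID)
      if (is.na(name) || !nzchar(name)) name <- id
      models[[length(models) + 1L]] <- derive_gene_model(
        name, harmonize_chrom(as.character(GenomicRanges::seqnames(x))),
        as.character(GenomicRanges::strand(x)),
        data.frame(start = GenomicRanges::start(ex) - 1L,
                   end = GenomicRanges::end(ex)),
        cds_start, cds_end)
    }
  }
  if (!length(models)) stop("no usable transcripts in ", path)
  gene_annotation(genes = do.call(rbind, lapply(models, `[[`, "gene")),
                  elements = do.call(rbind, lapply(models, `[[`, "elements")))
}

# write a gene_annotation as BED12 (exon blocks, CDS as thick)
write_annotation_bed12 <- function(ann, path) {
  stopifnot(inherits(ann, "gene_annotation"))
  lines <- vapply(seq_len(nrow(ann$genes)), function(i) {
    g <- ann$genes[i, ]
    el <- ann$elements[ann$elements$gene == g$gene, ]
    ex <- el[el$type == "exon", ]
    ex <- ex[order(ex$start), ]
    cds <- el[el$type == "cds", ]
    thick <- if (nrow(cds)) c(min(cds$start), max(cds$end)) else
      c(g$start, g$start)
    paste(g$chrom, g$start, g$end, g$gene, 0, g$strand, thick[1], thick[2],
          "0", nrow(ex), paste0(paste(ex$end - ex$start, collapse = ","), ","),
          paste0(paste(ex$start - g$start, collapse = ","), ","), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Classify a window by genomic element
#'
#' A window is a `promoter` hit when any of its bases lies within
#' `promoter_halfwidth` of a transcription start site (symmetric around the
#' TSS; strand affects only the sign of the reported distance). Otherwise it
#' is classified by overlap with precedence `utr5 > utr3 > intron`, else
#' `intergenic`. Ties across genes go to the smallest absolute
#' center-to-TSS distance, then to the lexicographically first gene name.
#'
#' @param candidate one-row window data frame (`chrom`, `start`, `end`,
#'   `center`).
#' @param annotations a [gene_annotation()].
#' @param promoter_halfwidth promoter half-width in bp around the TSS
#'   (default 5000).
#' @return list: `element_class`, `gene`, `distance_to_tss` (signed,
#'   negative upstream, strand-aware), `coding_overlap`.
#' @export
classify_window <- function(candidate, annotations, promoter_halfwidth = 5000) {
  stopifnot(inherits(annotations, "gene_annotation"))
  genes <- annotations$genes[annotations$genes$chrom == candidate$chrom, ]
  el <- annotations$elements[annotations$elements$chrom == candidate$chrom, ]
  w_lo <- candidate$start + 1L          # 1-based inclusive window
  w_hi <- candidate$end
  center <- candidate$center
  signed_dist <- function(g) ifelse(g$strand == "+", center - g$tss,
                                    g$tss - center)
  if (nrow(genes)) {
    gap <- pmax(w_lo - genes$tss, genes$tss - w_hi, 0)  # bp from window to TSS
    promo <- gap <= promoter_halfwidth
  } else promo <- logical(0)
  coding <- FALSE
  if (nrow(el)) {
    ov <- el$start < w_hi & el$end > w_lo - 1L          # any base overlap
    coding <- any(ov & el$type == "cds")
  } else ov <- logical(0)
  pick_gene <- function(cand_genes) {
    d <- signed_dist(cand_genes)
    o <- order(abs(d), cand_genes$gene)
    list(gene = cand_genes$gene[o[1]], distance = d[o[1]])
  }
  if (any(promo)) {
    sel <- pick_gene(genes[promo, , drop = FALSE])
    return(list(element_class = "promoter", gene = sel$gene,
                distance_to_tss = sel$distance, coding_overlap = coding))
  }
  for (cls in c("utr5", "utr3", "intron")) {
    hit_genes <- unique(el$gene[ov & el$type == cls])
    if (length(hit_genes)) {
      sel <- pick_gene(genes[genes$gene %in% hit_genes, , drop = FALSE])
      return(list(element_class = cls, gene = sel$gene,
                  distance_to_tss = sel$distance, coding_overlap = coding))
    }
  }
  out_gene <- NA_character_; out_d <- NA_real_
  if (nrow(genes)) {
    sel <- pick_gene(genes)
    out_gene <- sel$gene; out_d <- sel$distance
  }
  list(element_class = "intergenic", gene = out_gene,
       distance_to_tss = out_d, coding_overlap = coding)
}

#' Annotate scan results with genomic elements
#'
#' Applies [classify_window()] to every window of a scan result table.
#'
#' @param results a scan result data frame (one width's table from
#'   [scan_hotspots()]).
#' @param annotations a [gene_annotation()].
#' @param promoter_halfwidth promoter half-width in bp (default 5000).
#' @return `results` with `element_class`, `gene`, `distance_to_tss`,
#'   `coding_overlap` columns.
#' @export
annotate_results <- function(results, annotations, promoter_halfwidth = 5000) {
  if (nrow(results) == 0L) {
    results$element_class <- character(0)
    results$gene <- character(0)
    results$distance_to_tss <- numeric(0)
    results$coding_overlap <- logical(0)
    return(results)
  }
  cls <- lapply(seq_len(nrow(results)), function(i)
    classify_window(results[i, ], annotations, promoter_halfwidth))
  results$element_class <- vapply(cls, `[[`, character(1), "element_class")
  results$gene <- vapply(cls, `[[`, character(1), "gene")
  results$distance_to_tss <- vapply(cls, `[[`, numeric(1), "distance_to_tss")
  results$coding_overlap <- vapply(cls, `[[`, logical(1), "coding_overlap")
  results
}

#' Ranked hotspot report
#'
#' Orders annotated windows by (p ascending, recurrence `k` descending,
#' coordinates), optionally restricted to promoter hits. Windows overlapping
#' coding exons are excluded by default (the scan targets noncoding
#' elements). The returned table doubles as the recurrence-vs-probability
#' scatter (`k`, `neg_log10_p`, `gene` label).
#'
#' @param annotated_results output of [annotate_results()].
#' @param restrict `"all"` or `"promoter"`.
#' @param drop_coding drop coding-exon-overlapping windows (default TRUE).
#' @return the ranked data frame.
#' @export
rank_report <- function(annotated_results, restrict = c("all", "promoter"),
                        drop_coding = TRUE) {
  restrict <- match.arg(restrict)
  d <- annotated_results
  if (drop_coding && "coding_overlap" %in% names(d)) d <- d[!d$coding_overlap, ]
  if (restrict == "promoter") d <- d[d$element_class == "promoter", ]
  o <- order(d$p_value, -d$k, d$chrom, d$start)
  d <- d[o, , drop = FALSE]
  rownames(d) <- NULL
  d
}
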