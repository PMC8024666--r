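# Synthetic cohorts: a single synthetic chromosome with spatially
# autocorrelated covariate tracks, a multi-donor mutation set drawn from the
# same logistic model the analysis fits, and injectable clustered hotspots.

#' Specify a clustered-hotspot injection
#'
#' Describes a short window into which a fixed number of donors are forced to
#' carry at least one SNV, emulating a recurrently mutated noncoding element
#' for power analyses.
#'
#' @param center 1-based window center.
#' @param width odd window width in bp, between 7 and 21 (default 11).
#' @param n_recurrent_donors number of distinct donors that must carry a
#'   mutation inside the window after injection.
#' @param allele_rule named character vector mapping each reference base to
#'   the alternate allele used for injected mutations.
#' @return an object of class `hotspot_spec`.
#' @export
hotspot_spec <- function(center, width = 11L, n_recurrent_donors,
                         allele_rule = c(A = "C", C = "A", G = "T", T = "G")) {
  if (width %% 2L != 1L || width < 7L || width > 21L) {
    stop_field("width", "must be odd and in [7, 21]")
  }
  if (center < 1L) stop_field("center", "must be >= 1")
  if (n_recurrent_donors < 0L) stop_field("n_recurrent_donors", "must be >= 0")
  stopifnot(all(c("A", "C", "G", "T") %in% names(allele_rule)))
  structure(list(center = as.integer(center), width = as.integer(width),
                 n_recurrent_donors = as.integer(n_recurrent_donors),
                 allele_rule = allele_rule),
            class = "hotspot_spec")
}

default_covariate_specs <- function() {
  data.frame(
    name = c("replication_timing", "gc_content", "H3K9me3", "TFBS"),
    kind = c("continuous", "continuous", "binary", "binary"),
    corlen = c(50000, 10000, 20000, 1000),
    coverage = c(NA, NA, 0.30, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Specify a synthetic cohort
#'
#' Full parameterization of a simulated genome plus mutation cohort. Sites
#' mutate independently per donor with probability
#' \eqn{\sigma(\alpha_j + \beta \cdot x_i)}: shared covariate effects
#' \eqn{\beta} on spatially autocorrelated tracks, and donor-specific
#' intercepts \eqn{\alpha_j} encoding burden heterogeneity. Defaults describe
#' a 1 Mb chromosome with 50 donors whose intercepts are normal on the logit
#' scale around logit(1e-3) (sd 0.5), elevated rates in a
#' heterochromatin-like mark and in TFBS clusters, and a negative
#' replication-timing effect.
#'
#' @param genome_length chromosome length in bp (>= 1000).
#' @param n_donors number of donors (>= 2).
#' @param true_coefficients named numeric, logit-scale effect per track name.
#' @param donor_log_offsets per-donor logit-scale intercepts; drawn from
#'   `rnorm(n_donors, mean_logit, offset_sd)` under `seed` when `NULL`.
#'   May contain `-Inf` (a donor that never mutates).
#' @param covariate_specs data frame with columns `name`, `kind`
#'   (`continuous`/`binary`), `corlen` (spatial correlation length, bp) and
#'   `coverage` (target fraction covered, binary tracks only).
#' @param hotspots list of [hotspot_spec()] to inject.
#' @param seed integer RNG seed; a fixed seed gives byte-identical fixtures.
#' @param resolution track bin width in bp.
#' @param mean_logit,offset_sd parameters of the donor-intercept distribution.
#' @param n_genes number of synthetic gene models to place.
#' @param cancer_type label assigned to every donor.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(genome_length = 1000000L, n_donors = 50L,
                        true_coefficients = c(replication_timing = -0.5,
                                              H3K9me3 = 0.5, TFBS = 0.3),
                        donor_log_offsets = NULL,
                        covariate_specs = default_covariate_specs(),
                        hotspots = list(), seed = 1L,
                        resolution = 100L,
                        mean_logit = qlogis(1e-3), offset_sd = 0.5,
                        n_genes = 20L, cancer_type = "SYN") {
  if (genome_length < 1000L) stop_field("genome_length", "must be >= 1000")
  if (n_donors < 2L) stop_field("n_donors", "must be >= 2")
  if (resolution < 1L) stop_field("resolution", "must be >= 1")
  covariate_specs <- as.data.frame(covariate_specs)
  stopifnot(all(c("name", "kind", "corlen") %in% names(covariate_specs)))
  if (!"coverage" %in% names(covariate_specs)) {
    covariate_specs$coverage <- rep(NA_real_, nrow(covariate_specs))
  }
  if (!all(names(true_coefficients) %in% covariate_specs$name)) {
    stop_field("true_coefficients",
               "every coefficient name must match a covariate_specs name")
  }
  if (is.null(donor_log_offsets)) {
    donor_log_offsets <- withr_seed(seed, rnorm(n_donors, mean_logit, offset_sd))
  }
  if (length(donor_log_offsets) != n_donors) {
    stop_field("donor_log_offsets", "length must equal n_donors")
  }
  hotspots <- lapply(hotspots, function(h) {
    stopifnot(inherits(h, "hotspot_spec"))
    half <- (h$width - 1L) %/% 2L
    if (h$center - half < 1L || h$center + half > genome_length) {
      stop_field("hotspots", "window extends outside the genome")
    }
    if (h$n_recurrent_donors > n_donors) {
      stop_field("hotspots", "n_recurrent_donors exceeds n_donors")
    }
    h
  })
  structure(list(genome_length = as.integer(genome_length),
                 n_donors = as.integer(n_donors),
                 true_coefficients = true_coefficients,
                 donor_log_offsets = donor_log_offsets,
                 covariate_specs = covariate_specs,
                 hotspots = hotspots, seed = as.integer(seed),
                 resolution = as.integer(resolution),
                 n_genes = as.integer(n_genes),
                 cancer_type = cancer_type),
            class = "cohort_spec")
}

donor_ids_of <- function(spec) sprintf("D%03d", seq_len(spec$n_donors))

# evaluate expr under a local seed without disturbing the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# smoothed standard-normal field at bin resolution
smooth_field <- function(n_bins, corlen_bins) {
  z <- rnorm(n_bins)
  if (corlen_bins > 0.5) {
    half <- min(max(1L, ceiling(3 * corlen_bins)), (n_bins - 1L) %/% 2L)
    k <- dnorm(seq(-half, half), sd = corlen_bins)
    k <- k / sum(k)
    z <- as.numeric(stats::filter(z, k, circular = TRUE))
    s <- sd(z)
    if (s > 0) z <- z / s
  }
  z
}

bins_to_intervals <- function(member, resolution, genome_length) {
  r <- rle(member)
  ends_bin <- cumsum(r$lengths)
  starts_bin <- ends_bin - r$lengths
  keep <- r$values
  data.frame(start = starts_bin[keep] * resolution,
             end = pmin(ends_bin[keep] * resolution, genome_length))
}

#' Simulate a synthetic genome
#'
#' Draws a random nucleotide sequence, one covariate track per row of
#' `covariate_specs` (continuous tracks are sigmoid-mapped smoothed Gaussian
#' fields in \[0, 1\]; binary tracks threshold a smoothed field at the target
#' coverage), and a set of non-overlapping synthetic gene models used for
#' element annotation. Deterministic under `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return a list with elements `sequence` (named character vector, one
#'   chromosome `"1"`), `tracks` (list of [covariate_track()]), `genes`
#'   (a `gene_annotation`) and `spec`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  L <- spec$genome_length
  res <- spec$resolution
  withr_seed(spec$seed, {
    seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    sequence <- setNames(paste(seq_chars, collapse = ""), "1")
    n_bins <- ceiling(L / res)
    tracks <- lapply(seq_len(nrow(spec$covariate_specs)), function(i) {
      cs <- spec$covariate_specs[i, ]
      z <- smooth_field(n_bins, cs$corlen / res)
      starts <- (seq_len(n_bins) - 1L) * res
      ends <- pmin(starts + res, L)
      if (cs$kind == "continuous") {
        covariate_track(cs$name, "continuous",
                        list(`1` = data.frame(start = starts, end = ends,
                                              value = plogis(z))))
      } else {
        coverage <- if (is.na(cs$coverage)) 0.2 else cs$coverage
        member <- z >= quantile(z, 1 - coverage)
        covariate_track(cs$name, "binary",
                        list(`1` = bins_to_intervals(member, res, L)))
      }
    })
    names(tracks) <- spec$covariate_specs$name
    genes <- simulate_genes(spec)
    list(sequence = sequence, tracks = tracks, genes = genes, spec = spec)
  })
}

# non-overlapping three-exon gene models; 5'UTR 200 bp, 3'UTR 300 bp
simulate_genes <- function(spec) {
  L <- spec$genome_length
  exon_len <- c(400L, 600L, 800L)
  intron_len <- c(1000L, 1500L)
  span <- sum(exon_len) + sum(intron_len)
  n <- spec$n_genes
  if (L < span + 2L || n == 0L) {
    return(gene_annotation(genes = data.frame(gene = character(0),
                                              chrom = character(0),
                                              strand = character(0),
                                              tss = integer(0),
                                              start = integer(0),
                                              end = integer(0)),
                           elements = data.frame(gene = character(0),
                                                 chrom = character(0),
                                                 type = character(0),
                                                 start = integer(0),
                                                 end = integer(0))))
  }
  starts <- integer(0)
  tries <- 0L
  while (length(starts) < n && tries < 50L * n) {
    cand <- sample.int(L - span, 1L) - 1L  # 0-based transcript start
    if (!any(abs(cand - starts) < span + 1000L)) starts <- c(starts, cand)
    tries <- tries + 1L
  }
  starts <- sort(starts)
  strand <- sample(c("+", "-"), length(starts), replace = TRUE)
  genes <- data.frame(gene = sprintf("G%03d", seq_along(starts)),
                      chrom = "1", strand = strand,
                      tss = ifelse(strand == "+", starts + 1L, starts + span),
                      start = starts, end = starts + span)
  el <- do.call(rbind, lapply(seq_along(starts), function(i) {
    s <- starts[i]
    e1 <- c(s, s + exon_len[1])
    e2 <- c(e1[2] + intron_len[1], e1[2] + intron_len[1] + exon_len[2])
    e3 <- c(e2[2] + intron_len[2], e2[2] + intron_len[2] + exon_len[3])
    ex <- rbind(e1, e2, e3)
    introns <- rbind(c(e1[2], e2[1]), c(e2[2], e3[1]))
    if (strand[i] == "+") {
      utr5 <- c(e1[1], e1[1] + 200L); utr3 <- c(e3[2] - 300L, e3[2])
      cds <- rbind(c(utr5[2], e1[2]), e2, c(e3[1], utr3[1]))
    } else {
      utr5 <- c(e3[2] - 200L, e3[2]); utr3 <- c(e1[1], e1[1] + 300L)
      cds <- rbind(c(e1[1] + 300L, e1[2]), e2, c(e3[1], utr5[1]))
    }
    data.frame(gene = sprintf("G%03d", i), chrom = "1",
               type = c(rep("exon", 3), rep("intron", 2), "utr5", "utr3",
                        rep("cds", 3)),
               start = c(ex[, 1], introns[, 1], utr5[1], utr3[1], cds[, 1]),
               end = c(ex[, 2], introns[, 2], utr5[2], utr3[2], cds[, 2]))
  }))
  gene_annotation(genes = genes, elements = el)
}

# per-site logit-scale covariate contribution beta . x_i over the whole genome
covariate_logit <- function(spec, tracks) {
  L <- spec$genome_length
  g <- numeric(L)
  for (nm in names(spec$true_coefficients)) {
    tr <- tracks[[nm]]
    if (is.null(tr)) stop("coefficient '", nm, "' has no matching track")
    g <- g + spec$true_coefficients[[nm]] * track_values(tr, "1", seq_len(L))
  }
  g
}

#' True per-site mutation probabilities of a synthetic cohort
#'
#' Exposes the generative truth for recovery tests: the covariate linear
#' predictor at every site and the per-donor intercepts, so that the mutation
#' probability of donor `j` at site `i` is `plogis(alpha[j] + g[i])`.
#'
#' @param spec a [cohort_spec()].
#' @param genome output of [simulate_genome()] for the same spec.
#' @return list with `g` (length-genome numeric) and `alpha` (named per-donor).
#' @export
true_site_probabilities <- function(spec, genome) {
  g <- covariate_logit(spec, genome$tracks)
  list(g = g, alpha = setNames(spec$donor_log_offsets, donor_ids_of(spec)))
}

#' Simulate donor mutation sets
#'
#' For each donor `j` and site `i`, a mutation occurs independently with
#' probability `plogis(alpha_j + beta . x_i)`; the alternate allele is drawn
#' uniformly from the three non-reference bases. Records are sorted by
#' (donor, position). Hotspots in the spec are *not* injected here; see
#' [inject_hotspot()] and [simulate_cohort()].
#'
#' @param spec a [cohort_spec()].
#' @param tracks covariate tracks covering the genome (named as in
#'   `spec$true_coefficients`).
#' @param sequence named character vector of chromosome sequences.
#' @return data frame of mutation records: `donor_id`, `cancer_type`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`.
#' @export
simulate_mutations <- function(spec, tracks, sequence) {
  stopifnot(inherits(spec, "cohort_spec"))
  L <- spec$genome_length
  g <- covariate_logit(spec, tracks)
  donors <- donor_ids_of(spec)
  seq_chars <- strsplit(sequence[["1"]], "", fixed = TRUE)[[1]]
  withr_seed(spec$seed + 1000003L, {
    per_donor <- lapply(seq_len(spec$n_donors), function(j) {
      a <- spec$donor_log_offsets[j]
      if (!is.finite(a) && a < 0) return(NULL)     # probability-zero donor
      p <- plogis(a + g)
      hit <- which(runif(L) < p)
      if (length(hit) == 0L) return(NULL)
      ref <- seq_chars[hit]
      alt <- draw_alt(ref)
      data.frame(donor_id = donors[j], cancer_type = spec$cancer_type,
                 chrom = "1", pos = hit, ref = ref, alt = alt,
                 stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, per_donor)
    if (is.null(recs)) {
      recs <- data.frame(donor_id = character(0), cancer_type = character(0),
                         chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0))
    }
    recs[order(recs$donor_id, recs$pos), , drop = FALSE] -> recs
    rownames(recs) <- NULL
    recs
  })
}

# uniform draw from the three non-reference bases, vectorized
draw_alt <- function(ref) {
  bases <- c("A", "C", "G", "T")
  others <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
  pick <- sample.int(3L, length(ref), replace = TRUE)
  others[cbind(match(ref, bases), pick)]
}

#' Inject a clustered hotspot into a mutation set
#'
#' Forces exactly `n_recurrent_donors` distinct donors to carry at least one
#' SNV inside the hotspot window. Donors already mutated there are counted
#' first; the remainder are drawn (deterministically under the spec seed)
#' from the unaffected donors and given one SNV at a position sampled inside
#' the window, with the alternate allele taken from the hotspot's
#' `allele_rule`. Calling twice with the same spec is idempotent.
#'
#' @param records mutation data frame (as from [simulate_mutations()]).
#' @param hotspot a [hotspot_spec()].
#' @param spec the [cohort_spec()] that produced `records`.
#' @param sequence named character vector of chromosome sequences (reference
#'   alleles of injected mutations are read from it).
#' @return the augmented, (donor, position)-sorted mutation data frame.
#' @export
inject_hotspot <- function(records, hotspot, spec, sequence) {
  stopifnot(inherits(hotspot, "hotspot_spec"), inherits(spec, "cohort_spec"))
  if (hotspot$n_recurrent_donors > spec$n_donors) {
    stop_field("n_recurrent_donors", "exceeds n_donors")
  }
  half <- (hotspot$width - 1L) %/% 2L
  lo <- hotspot$center - half
  hi <- hotspot$center + half
  inside <- records$chrom == "1" & records$pos >= lo & records$pos <= hi
  have <- unique(records$donor_id[inside])
  need <- hotspot$n_recurrent_donors - length(have)
  if (need <= 0L) {
    if (need < 0L) warning("window already recurrent in more donors than requested")
    return(records)
  }
  candidates <- setdiff(donor_ids_of(spec), have)
  seq_chars <- strsplit(sequence[["1"]], "", fixed = TRUE)[[1]]
  withr_seed(spec$seed + 7L * hotspot$center, {
    chosen <- sample(candidates, need)
    pos <- sample(lo:hi, need, replace = TRUE)
    ref <- seq_chars[pos]
    add <- data.frame(donor_id = chosen, cancer_type = spec$cancer_type,
                      chrom = "1", pos = pos, ref = ref,
                      alt = unname(hotspot$allele_rule[ref]),
                      stringsAsFactors = FALSE)
    out <- rbind(records, add)
    out <- out[order(out$donor_id, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a full cohort (genome + mutations + injected hotspots)
#'
#' Convenience wrapper: [simulate_genome()], [simulate_mutations()], then
#' [inject_hotspot()] for every hotspot in the spec.
#'
#' @param spec a [cohort_spec()].
#' @return list with `sequence`, `tracks`, `genes`, `records`, `spec`.
#' @export
simulate_cohort <- function(spec) {
  genome <- simulate_genome(spec)
  records <- simulate_mutations(spec, genome$tracks, genome$sequence)
  for (h in spec$hotspots) {
    records <- inject_hotspot(records, h, spec, genome$sequence)
  }
  c(genome[c("sequence", "tracks", "genes")], list(records = records, spec = spec))
}

#' Write a synthetic cohort as a fixture file set
#'
#' Emits the reference FASTA, mutations as ICGC-style TSV and as VCF 4.2
#' (donor in INFO), continuous tracks as bedGraph, binary tracks as BED,
#' gene models as BED12, and a JSON truth file holding the spec, the
#' per-donor intercepts and the per-site covariate linear predictor for
#' recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @param outdir output directory (created if missing).
#' @param cohort optional precomputed [simulate_cohort()] result for the same
#'   spec (avoids re-simulation).
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture <- function(spec, outdir, cohort = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  if (is.null(cohort)) cohort <- simulate_cohort(spec)
  paths <- c()

  fa <- file.path(outdir, "reference.fa")
  dna <- Biostrings::DNAStringSet(cohort$sequence)
  Biostrings::writeXStringSet(dna, fa)
  paths["fasta"] <- fa

  tsv <- file.path(outdir, "mutations.tsv")
  write.table(cohort$records, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["tsv"] <- tsv

  vcf <- file.path(outdir, "mutations.vcf")
  write_mutations_vcf(cohort$records, vcf, spec$genome_length)
  paths["vcf"] <- vcf

  for (tr in cohort$tracks) {
    ext <- if (tr$kind == "continuous") "bedGraph" else "bed"
    p <- file.path(outdir, paste0(tr$name, ".", ext))
    write_track(tr, p)
    paths[tr$name] <- p
  }

  genes_bed <- file.path(outdir, "genes.bed")
  write_annotation_bed12(cohort$genes, genes_bed)
  paths["genes"] <- genes_bed

  truth <- file.path(outdir, "truth.json")
  g <- covariate_logit(spec, cohort$tracks)
  jsonlite::write_json(
    list(genome_length = spec$genome_length, n_donors = spec$n_donors,
         seed = spec$seed, cancer_type = spec$cancer_type,
         true_coefficients = as.list(spec$true_coefficients),
         donor_log_offsets = setNames(as.list(spec$donor_log_offsets),
                                      donor_ids_of(spec)),
         hotspots = lapply(spec$hotspots, function(h)
           h[c("center", "width", "n_recurrent_donors")]),
         n_records = nrow(cohort$records),
         site_linear_predictor = round(g, 6)),
    truth, auto_unbox = TRUE, digits = NA)
  paths["truth"] <- truth
  invisible(paths)
}

write_mutations_vcf <- function(records, path, contig_length = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    if (!is.null(contig_length))
      sprintf("##contig=<ID=1,length=%d>", as.integer(contig_length)),
    "##INFO=<ID=DONOR,Number=1,Type=String,Description=\"Donor identifier\">",
    "##INFO=<ID=CTYPE,Number=1,Type=String,Description=\"Cancer type\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(records)) {
    o <- order(records$chrom, records$pos, records$donor_id)
    r <- records[o, , drop = FALSE]
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDONOR=%s;CTYPE=%s",
                       r$chrom, r$pos, r$ref, r$alt, r$donor_id,
                       r$cancer_type), con)
  }
  invisible(path)
}
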