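# Ingest somatic SNV calls (ICGC-style TSV, MAF, VCF) and apply the cohort
# and site filters: SNV-only, hypermutator removal, common-SNP removal,
# mappability-based removal.

mutation_columns <- c("donor_id", "cancer_type", "chrom", "pos", "ref", "alt")

empty_records <- function() {
  data.frame(donor_id = character(0), cancer_type = character(0),
             chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), is_snv = logical(0))
}

normalize_records <- function(df) {
  df$chrom <- harmonize_chrom(df$chrom)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  bad <- which(!is.finite(df$pos) | df$pos < 1)
  if (length(bad)) {
    stop("malformed row ", bad[1], ": invalid position '", df$pos[bad[1]], "'")
  }
  df$pos <- as.integer(df$pos)
  df$is_snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T") &
    df$ref != df$alt
  rownames(df) <- NULL
  df[c(mutation_columns, "is_snv")]
}

#' Read somatic mutation calls
#'
#' Parses somatic SNV calls from an ICGC-style simple-somatic TSV, a MAF, or
#' a VCF. Records are normalized to 1-based positions, uppercase alleles and
#' canonical chromosome names (leading `"chr"` stripped). Non-SNV rows are
#' retained but flagged (`is_snv = FALSE`) for [filter_snvs()].
#'
#' @param path input file.
#' @param format one of `"icgc_tsv"`, `"maf"`, `"vcf"`. The TSV dialect
#'   accepts either this package's fixture schema (`donor_id`, `cancer_type`,
#'   `chrom`, `pos`, `ref`, `alt`) or ICGC portal column names
#'   (`icgc_donor_id`, `project_code`, `chromosome`, `chromosome_start`,
#'   `mutated_from_allele`, `mutated_to_allele`).
#' @return mutation data frame with an `is_snv` flag column.
#' @export
read_mutations <- function(path, format = c("icgc_tsv", "maf", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- switch(format,
    icgc_tsv = {
      d <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
      if (all(mutation_columns %in% names(d))) {
        d[mutation_columns]
      } else if (all(c("icgc_donor_id", "chromosome", "chromosome_start",
                       "mutated_from_allele", "mutated_to_allele") %in% names(d))) {
        data.frame(donor_id = d$icgc_donor_id,
                   cancer_type = if ("project_code" %in% names(d))
                     d$project_code else NA_character_,
                   chrom = d$chromosome, pos = d$chromosome_start,
                   ref = d$mutated_from_allele, alt = d$mutated_to_allele,
                   stringsAsFactors = FALSE)
      } else {
        stop("unrecognized TSV columns in ", path)
      }
    },
    maf = {
      d <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
      need <- c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
                "Reference_Allele", "Tumor_Seq_Allele2")
      if (!all(need %in% names(d))) {
        stop("MAF is missing columns: ",
             paste(setdiff(need, names(d)), collapse = ", "))
      }
      data.frame(donor_id = d$Tumor_Sample_Barcode,
                 cancer_type = if ("Cancer_Type" %in% names(d))
                   d$Cancer_Type else NA_character_,
                 chrom = d$Chromosome, pos = d$Start_Position,
                 ref = d$Reference_Allele, alt = d$Tumor_Seq_Allele2,
                 stringsAsFactors = FALSE)
    },
    vcf = read_vcf_records(path)
  )
  if (nrow(df) == 0L) return(empty_records())
  normalize_records(df)
}

# minimal somatic VCF reader: donor and cancer type carried in INFO
read_vcf_records <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) return(empty_records()[mutation_columns])
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 8L)) {
    bad <- which(nf < 8L)[1]
    stop("malformed row ", bad, ": VCF data line has ", nf[bad], " fields")
  }
  m <- do.call(rbind, fields)
  info_get <- function(info, key) {
    v <- sub(paste0(".*(?:^|;)", key, "=([^;]*).*"), "\\1", info)
    ifelse(grepl(paste0("(^|;)", key, "="), info), v, NA_character_)
  }
  alt <- vapply(strsplit(m[, 5], ",", fixed = TRUE), `[`, character(1), 1)
  data.frame(donor_id = info_get(m[, 8], "DONOR"),
             cancer_type = info_get(m[, 8], "CTYPE"),
             chrom = m[, 1], pos = suppressWarnings(as.numeric(m[, 2])),
             ref = m[, 4], alt = alt, stringsAsFactors = FALSE)
}

#' Keep single-nucleotide variants only
#'
#' Drops records whose ref or alt allele is not a single A/C/G/T base or
#' whose alleles are equal; the number removed is reported via `message()`.
#'
#' @param records mutation data frame.
#' @return the SNV subset (the `is_snv` helper column is dropped).
#' @export
filter_snvs <- function(records) {
  if (nrow(records) == 0L) return(records[setdiff(names(records), "is_snv")])
  if (!"is_snv" %in% names(records)) records <- normalize_records(records)
  n0 <- nrow(records)
  out <- records[records$is_snv, setdiff(names(records), "is_snv"), drop = FALSE]
  if (n0 - nrow(out) > 0) {
    message("filter_snvs: removed ", n0 - nrow(out), " non-SNV record(s)")
  }
  rownames(out) <- NULL
  out
}

#' Remove hypermutated donors
#'
#' A donor is excluded when its SNV count exceeds
#' `min(absolute_cap, fold_over_median * cohort median)` — an absolute cap
#' guarding small cohorts plus a fold-over-median rule that adapts to
#' per-cancer-type burden. All records of excluded donors are dropped.
#'
#' @param records mutation data frame.
#' @param absolute_cap absolute SNV-count cap (default 100000).
#' @param fold_over_median multiple of the cohort median (default 10).
#' @return list with `records` (retained) and `summaries` (one row per donor:
#'   `donor_id`, `cancer_type`, `snv_count`, `excluded`, `exclusion_reason`).
#' @export
remove_hypermutators <- function(records, absolute_cap = 100000,
                                 fold_over_median = 10) {
  if (nrow(records) == 0L) {
    return(list(records = records,
                summaries = data.frame(donor_id = character(0),
                                       cancer_type = character(0),
                                       snv_count = integer(0),
                                       excluded = logical(0),
                                       exclusion_reason = character(0))))
  }
  counts <- table(records$donor_id)
  med <- median(as.numeric(counts))
  threshold <- min(absolute_cap, fold_over_median * med)
  donors <- names(counts)
  excluded <- as.numeric(counts) > threshold
  ctype <- records$cancer_type[match(donors, records$donor_id)]
  summaries <- data.frame(donor_id = donors, cancer_type = ctype,
                          snv_count = as.integer(counts),
                          excluded = excluded,
                          exclusion_reason = ifelse(excluded, "hypermutator",
                                                    "none"),
                          stringsAsFactors = FALSE)
  keep <- !records$donor_id %in% donors[excluded]
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, summaries = summaries)
}

#' Load common-SNP sites
#'
#' Reads polymorphic sites (e.g. 1000 Genomes common SNPs) from a VCF or a
#' 3-column TSV (`chrom`, `pos`, `alt`).
#'
#' @param path file path.
#' @param format `"vcf"` or `"tsv"`.
#' @return data frame with `chrom`, `pos`, `alt`.
#' @export
load_snp_sites <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "vcf") {
    d <- read_vcf_records(path)
    data.frame(chrom = harmonize_chrom(d$chrom), pos = as.integer(d$pos),
               alt = toupper(d$alt), stringsAsFactors = FALSE)
  } else {
    d <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    names(d)[1:2] <- c("chrom", "pos")
    if (ncol(d) >= 3) names(d)[3] <- "alt" else d$alt <- NA_character_
    data.frame(chrom = harmonize_chrom(d$chrom), pos = as.integer(d$pos),
               alt = toupper(d$alt), stringsAsFactors = FALSE)
  }
}

#' Remove records at common-SNP sites
#'
#' Drops somatic calls matching a known polymorphic site. Allele-aware by
#' default (match on chromosome, position and alternate allele); a
#' position-only mode is available for parity with coarser pipelines.
#'
#' @param records mutation data frame.
#' @param snp_sites data frame with `chrom`, `pos` and (for allele-aware
#'   matching) `alt`; see [load_snp_sites()].
#' @param mode `"allele"` (default) or `"position"`.
#' @return the filtered data frame.
#' @export
remove_snp_overlap <- function(records, snp_sites, mode = c("allele", "position")) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L || is.null(snp_sites) || nrow(snp_sites) == 0L) {
    return(records)
  }
  snp_chrom <- harmonize_chrom(snp_sites$chrom)
  key <- if (mode == "allele") {
    paste(snp_chrom, snp_sites$pos, toupper(snp_sites$alt))
  } else {
    paste(snp_chrom, snp_sites$pos)
  }
  rec_key <- if (mode == "allele") {
    paste(records$chrom, records$pos, records$alt)
  } else {
    paste(records$chrom, records$pos)
  }
  out <- records[!rec_key %in% key, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove records in poorly mappable regions
#'
#' Drops records whose position has mappability below `min_score` on a
#' continuous \[0, 1\] uniqueness track (e.g. a 24-mer alignability track).
#' Positions outside the track domain are treated as score 0 and removed,
#' with a warning.
#'
#' @param records mutation data frame.
#' @param mappability a continuous [covariate_track()] with values in \[0, 1\].
#' @param min_score minimum score to retain a record (default 1.0).
#' @return the filtered data frame.
#' @export
apply_mappability_filter <- function(records, mappability, min_score = 1.0) {
  stopifnot(inherits(mappability, "covariate_track"),
            mappability$kind == "continuous")
  if (nrow(records) == 0L) return(records)
  scores <- track_values(mappability, records$chrom, records$pos)
  outside <- vapply(seq_len(nrow(records)), function(i) {
    records$pos[i] - 1L >= track_extent(mappability, records$chrom[i])
  }, logical(1))
  if (any(outside)) {
    warning(sum(outside), " record(s) outside the mappability track domain; ",
            "treated as score 0")
    scores[outside] <- 0
  }
  out <- records[scores >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}
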