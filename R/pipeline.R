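# End-to-end pipeline: ingest -> filter cascade -> background fit -> window
# scan -> element annotation -> ranked report, driven by one reproducible
# configuration.

#' Build a run configuration
#'
#' Collects every path and parameter of a pipeline run. Any field can also
#' be supplied through a YAML file (see [read_run_config()]).
#'
#' @param mutations path to the mutation file.
#' @param format mutation file format (`"icgc_tsv"`, `"maf"`, `"vcf"`).
#' @param tracks named list: `name = list(path, kind)` for each covariate
#'   track.
#' @param fasta reference FASTA path.
#' @param genes gene-model path (BED12 or GFF3).
#' @param genes_format `"bed"` or `"gff3"`.
#' @param snp_sites optional common-SNP file (VCF or TSV); `NULL` skips.
#' @param snp_mode `"allele"` or `"position"`.
#' @param mappability optional mappability bedGraph; `NULL` skips.
#' @param min_mappability minimum mappability score.
#' @param hypermutator_cap,hypermutator_fold hypermutator thresholds.
#' @param background_sites background (donor, site) pairs for the model fit.
#' @param use_context include trinucleotide-context terms.
#' @param l2 ridge penalty for the fit (0 = plain ML).
#' @param widths odd scan widths in bp.
#' @param min_donors recurrence seed threshold.
#' @param adjust `"bonferroni"` or `"BH"`.
#' @param promoter_halfwidth promoter half-width around the TSS (bp).
#' @param restrict `"all"` or `"promoter"` for the final report.
#' @param seed RNG seed, recorded in every output header.
#' @return object of class `run_config`.
#' @export
run_config <- function(mutations, format = "icgc_tsv", tracks = list(),
                       fasta, genes = NULL, genes_format = "bed",
                       snp_sites = NULL, snp_mode = "allele",
                       mappability = NULL, min_mappability = 1.0,
                       hypermutator_cap = 100000, hypermutator_fold = 10,
                       background_sites = 200000L, use_context = TRUE,
                       l2 = 0, widths = 11L, min_donors = 2L,
                       adjust = "bonferroni", promoter_halfwidth = 5000,
                       restrict = "promoter", seed = 1L) {
  widths <- as.integer(widths)
  if (any(widths %% 2L != 1L | widths < 7L | widths > 21L)) {
    stop_field("widths", "must all be odd and in [7, 21]")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys are [run_config()] arguments; relative
#'   paths are resolved against the YAML file's directory.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix_path <- function(p) {
    if (is.null(p) || is.na(p)) return(p)
    if (startsWith(p, "/")) p else file.path(base, p)
  }
  for (f in c("mutations", "fasta", "genes", "snp_sites", "mappability")) {
    if (!is.null(y[[f]])) y[[f]] <- fix_path(y[[f]])
  }
  if (!is.null(y$tracks)) {
    y$tracks <- lapply(y$tracks, function(t) {
      t$path <- fix_path(t$path); t
    })
  }
  do.call(run_config, y)
}

config_hash <- function(config) {
  string_hash(paste(deparse(unclass(config)), collapse = ""))
}

#' Run the full hotspot-discovery pipeline
#'
#' Executes ingest (format parsing + SNV / hypermutator / common-SNP /
#' mappability filters), background-model fit, the Poisson-binomial window
#' scan at every configured width, and element annotation, writing each
#' stage's table into `outdir` with a provenance header (tool version,
#' configuration hash, seed) and logging record counts per stage. A rerun
#' with the same configuration and seed reproduces the outputs byte for
#' byte.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created).
#' @return invisibly, a list with `records`, `summaries`, `model`, `scan`,
#'   `report` and the output paths.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("mutations", "fasta")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      stop("startup validation: missing input '", f, "' (",
           config[[f]] %||% "NULL", ")")
    }
  }
  for (t in config$tracks) {
    if (!file.exists(t$path)) {
      stop("startup validation: missing track file ", t$path)
    }
  }
  if (!is.null(config$genes) && !file.exists(config$genes)) {
    stop("startup validation: missing genes file ", config$genes)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$seed
  log_stage <- function(stage, n_in, n_out) {
    message(sprintf("[%s] records in: %d, out: %d", stage, n_in, n_out))
  }

  # -- ingest + filter cascade
  recs <- read_mutations(config$mutations, config$format)
  n0 <- nrow(recs)
  recs <- filter_snvs(recs)
  log_stage("filter_snvs", n0, nrow(recs))
  hm <- remove_hypermutators(recs, config$hypermutator_cap,
                             config$hypermutator_fold)
  log_stage("remove_hypermutators", nrow(recs), nrow(hm$records))
  recs <- hm$records
  if (!is.null(config$snp_sites)) {
    fmt <- if (grepl("\\.vcf$", config$snp_sites)) "vcf" else "tsv"
    snps <- load_snp_sites(config$snp_sites, fmt)
    n_in <- nrow(recs)
    recs <- remove_snp_overlap(recs, snps, config$snp_mode)
    log_stage("remove_snp_overlap", n_in, nrow(recs))
  }
  sequence <- load_fasta(config$fasta)
  tracks <- lapply(names(config$tracks), function(nm) {
    t <- config$tracks[[nm]]
    load_track(t$path, t$kind, name = nm)
  })
  names(tracks) <- names(config$tracks)
  if (!is.null(config$mappability)) {
    mtrack <- load_track(config$mappability, "continuous", "mappability")
    n_in <- nrow(recs)
    recs <- apply_mappability_filter(recs, mtrack, config$min_mappability)
    log_stage("apply_mappability_filter", n_in, nrow(recs))
  }
  if (nrow(recs) == 0L) stop("stage ingest: no records survive filtering")
  write_tsv_header(recs, file.path(outdir, "filtered_mutations.tsv"),
                   seed, hash)
  write_tsv_header(hm$summaries, file.path(outdir, "donor_summary.tsv"),
                   seed, hash)

  # -- background model
  model <- tryCatch(
    fit_background(recs, tracks, sequence,
                   n_background_sites = config$background_sites,
                   seed = seed, use_context = config$use_context,
                   l2 = config$l2),
    error = function(e) stop("stage fit: ", conditionMessage(e)))
  save_model(model, file.path(outdir, "model.json"))
  message(sprintf("[fit] %d training sites, converged: %s",
                  model$fit_metadata$n_sites_sampled,
                  model$fit_metadata$converged))

  # -- scan
  scan <- tryCatch(
    scan_hotspots(recs, model, tracks, sequence, widths = config$widths,
                  min_donors = config$min_donors, adjust = config$adjust),
    error = function(e) stop("stage scan: ", conditionMessage(e)))
  for (w in names(scan$results)) {
    write_tsv_header(scan$results[[w]],
                     file.path(outdir, sprintf("scan_width%s.tsv", w)),
                     seed, hash)
    message(sprintf("[scan] width %s: %d window(s) tested", w,
                    nrow(scan$results[[w]])))
  }

  # -- annotation + report
  report <- NULL
  if (!is.null(config$genes)) {
    ann <- tryCatch(load_annotation(config$genes, config$genes_format),
                    error = function(e) stop("stage annotate: ",
                                             conditionMessage(e)))
    report <- lapply(scan$results, function(res)
      rank_report(annotate_results(res, ann, config$promoter_halfwidth),
                  restrict = config$restrict))
    for (w in names(report)) {
      write_tsv_header(report[[w]],
                       file.path(outdir, sprintf("report_width%s.tsv", w)),
                       seed, hash)
      message(sprintf("[annotate] width %s: %d window(s) in report", w,
                      nrow(report[[w]])))
    }
  }
  writeLines(yaml::as.yaml(lapply(unclass(config), function(x) x)),
             file.path(outdir, "config.yaml"))
  invisible(list(records = recs, summaries = hm$summaries, model = model,
                 scan = scan, report = report, outdir = outdir))
}

#' Load a reference FASTA as plain character sequences
#'
#' @param path FASTA file.
#' @return named character vector (canonical chromosome names).
#' @export
load_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  out <- as.character(dna)
  names(out) <- harmonize_chrom(sub("\\s.*$", "", names(dna)))
  out
}
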