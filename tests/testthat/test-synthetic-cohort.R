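# Generator contracts: determinism, track geometry, generative calibration,
# hotspot injection, fixture round-trips.

test_that("spec validation names the offending field", {
  expect_error(cohort_spec(genome_length = 500), "genome_length")
  expect_error(cohort_spec(n_donors = 1), "n_donors")
  expect_error(cohort_spec(true_coefficients = c(nosuch = 1)),
               "true_coefficients")
  expect_error(hotspot_spec(center = 100, width = 10, n_recurrent_donors = 2),
               "width")
  expect_error(cohort_spec(hotspots = list(
    hotspot_spec(center = 3, width = 11, n_recurrent_donors = 2))),
    "hotspots")
  expect_error(cohort_spec(hotspots = list(
    hotspot_spec(center = 5000, width = 11, n_recurrent_donors = 99))),
    "hotspots")
})

test_that("simulation is deterministic under a fixed seed", {
  spec <- cohort_spec(genome_length = 10000, n_donors = 4, n_genes = 2,
                      seed = 1, mean_logit = qlogis(2e-3))
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$records, b$records)
})

test_that("track geometry: ranges, containment, disjoint sorted intervals", {
  co <- small_cohort()
  L <- co$spec$genome_length
  for (tr in co$tracks) {
    d <- tr$data[["1"]]
    expect_true(all(d$start >= 0 & d$end <= L))
    expect_true(all(d$end > d$start))
    expect_true(!is.unsorted(d$start))
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
    if (tr$kind == "continuous") {
      expect_true(all(d$value >= 0 & d$value <= 1))
    }
  }
})

test_that("constant-probability cohorts are calibrated (4-sigma guard)", {
  p <- 1e-3
  spec <- cohort_spec(genome_length = 200000, n_donors = 5,
                      true_coefficients = setNames(numeric(0), character(0)),
                      donor_log_offsets = rep(qlogis(p), 5),
                      covariate_specs = data.frame(name = character(0),
                                                   kind = character(0),
                                                   corlen = numeric(0)),
                      n_genes = 0, seed = 7)
  genome <- simulate_genome(spec)
  recs <- simulate_mutations(spec, genome$tracks, genome$sequence)
  expected <- 5 * 200000 * p
  expect_lt(abs(nrow(recs) - expected), 4 * sqrt(expected))
})

test_that("a probability-zero donor contributes no records", {
  spec <- cohort_spec(genome_length = 20000, n_donors = 3,
                      donor_log_offsets = c(-Inf, qlogis(2e-3), qlogis(2e-3)),
                      n_genes = 0, seed = 5)
  genome <- simulate_genome(spec)
  recs <- simulate_mutations(spec, genome$tracks, genome$sequence)
  expect_false("D001" %in% recs$donor_id)
  expect_true(all(c("D002", "D003") %in% recs$donor_id))
})

test_that("positive coefficient on a binary track elevates the inside rate", {
  spec <- cohort_spec(genome_length = 300000, n_donors = 10,
                      true_coefficients = c(H3K9me3 = 1.0),
                      mean_logit = qlogis(1e-3), seed = 9, n_genes = 0)
  genome <- simulate_genome(spec)
  recs <- simulate_mutations(spec, genome$tracks, genome$sequence)
  inside <- track_values(genome$tracks$H3K9me3, "1", recs$pos) == 1
  bp_in <- sum(with(genome$tracks$H3K9me3$data[["1"]], end - start))
  bp_out <- spec$genome_length - bp_in
  rate_in <- sum(inside) / bp_in
  rate_out <- sum(!inside) / bp_out
  expect_gt(rate_in, rate_out)
  expect_gt(rate_in / rate_out, 1.5)   # exp(1.0) expected, allow sampling noise
})

test_that("unknown coefficient name fails at mutation simulation", {
  spec <- small_cohort()$spec
  bad <- spec
  bad$true_coefficients <- c(missing_track = 1)
  class(bad) <- "cohort_spec"
  genome <- simulate_genome(spec)
  expect_error(simulate_mutations(bad, genome$tracks, genome$sequence),
               "no matching track")
})

test_that("hotspot injection meets its donor-count contract exactly", {
  co <- small_cohort()
  h <- hotspot_spec(center = 25000, width = 11, n_recurrent_donors = 6)
  recs <- inject_hotspot(co$records, h, co$spec, co$sequence)
  inside <- recs$pos >= 24995 & recs$pos <= 25005
  expect_identical(length(unique(recs$donor_id[inside])), 6L)
  # idempotent: re-injecting adds nothing
  again <- inject_hotspot(recs, h, co$spec, co$sequence)
  expect_identical(again, recs)
  # n = 0 leaves the records untouched
  h0 <- hotspot_spec(center = 40000, width = 7, n_recurrent_donors = 0)
  expect_identical(inject_hotspot(co$records, h0, co$spec, co$sequence),
                   co$records)
  # injected alleles follow the allele rule and match the reference
  added <- recs[inside & !paste(recs$donor_id, recs$pos) %in%
                  paste(co$records$donor_id, co$records$pos), ]
  seq_chars <- strsplit(co$sequence[["1"]], "")[[1]]
  expect_identical(added$ref, seq_chars[added$pos])
  expect_identical(added$alt, unname(h$allele_rule[added$ref]))
})

test_that("fixture files round-trip and honour format contracts", {
  outdir <- withr::local_tempdir()
  spec <- cohort_spec(genome_length = 10000, n_donors = 4, n_genes = 2,
                      seed = 13, mean_logit = qlogis(3e-3))
  co <- simulate_cohort(spec)
  paths <- write_fixture(spec, outdir, cohort = co)
  # FASTA: length and content
  fa <- load_fasta(paths[["fasta"]])
  expect_identical(nchar(fa[["1"]]), 10000L)
  expect_identical(fa[["1"]], co$sequence[["1"]])
  # TSV round-trip is the identity on records
  back <- filter_snvs(read_mutations(paths[["tsv"]], "icgc_tsv"))
  expect_equal(back, co$records, ignore_attr = TRUE)
  # VCF carries the same (donor, site, allele) set
  vcf <- filter_snvs(read_mutations(paths[["vcf"]], "vcf"))
  key <- function(d) sort(paste(d$donor_id, d$chrom, d$pos, d$ref, d$alt))
  expect_identical(key(vcf), key(co$records))
  # bedGraph: sorted, non-overlapping, half-open, values preserved
  tr <- load_track(paths[["replication_timing"]], "continuous",
                   "replication_timing")
  d <- tr$data[["1"]]
  expect_true(!is.unsorted(d$start))
  expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  expect_equal(track_values(tr, "1", c(1, 5000, 9999)),
               track_values(co$tracks$replication_timing, "1",
                            c(1, 5000, 9999)))
  # truth file agrees with the emitted records
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_identical(truth$n_records, nrow(co$records))
  expect_length(truth$site_linear_predictor, 10000L)
  # determinism: a second write is byte-identical
  outdir2 <- withr::local_tempdir()
  paths2 <- write_fixture(spec, outdir2)
  for (nm in names(paths)) {
    expect_identical(readLines(paths[[nm]]), readLines(paths2[[nm]]),
                     label = nm)
  }
})
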