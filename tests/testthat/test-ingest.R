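# Format parsing, normalization, and the filter cascade.

test_that("ICGC-TSV, MAF and VCF encodings yield identical records", {
  df <- toy_records()
  tsv <- write_toy_tsv(df, withr::local_tempfile(fileext = ".tsv"))
  maf <- write_toy_maf(df, withr::local_tempfile(fileext = ".maf"))
  vcf <- write_toy_vcf(df, withr::local_tempfile(fileext = ".vcf"))
  key <- function(d) sort(paste(d$donor_id, d$chrom, d$pos, d$ref, d$alt))
  r_tsv <- read_mutations(tsv, "icgc_tsv")
  r_maf <- read_mutations(maf, "maf")   # "chr" prefixes stripped
  r_vcf <- read_mutations(vcf, "vcf")   # lowercase ref uppercased
  expect_identical(key(r_tsv), key(r_maf))
  expect_identical(key(r_tsv), key(r_vcf))
  expect_true(all(r_maf$chrom %in% c("1", "2")))
  expect_true(all(r_vcf$ref %in% c("A", "C", "G", "T")))
})

test_that("malformed rows are reported with their row number", {
  df <- toy_records()
  df$pos[2] <- -5
  tsv <- write_toy_tsv(df, withr::local_tempfile(fileext = ".tsv"))
  expect_error(read_mutations(tsv, "icgc_tsv"), "row 2")
  bad_vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS", "1\t100\t."), bad_vcf)
  expect_error(read_mutations(bad_vcf, "vcf"), "row 1")
  expect_error(read_mutations("nope.tsv", "icgc_tsv"), "no such file")
})

test_that("filter_snvs keeps single-base substitutions only", {
  df <- toy_records()
  df <- rbind(df, data.frame(donor_id = "d4", cancer_type = "T", chrom = "1",
                             pos = 500L, ref = "A", alt = "AT"))   # insertion
  tsv <- write_toy_tsv(df, withr::local_tempfile(fileext = ".tsv"))
  recs <- read_mutations(tsv, "icgc_tsv")
  expect_message(out <- filter_snvs(recs), "removed 1")
  expect_identical(nrow(out), 4L)
  expect_identical(nrow(filter_snvs(out)), 4L)                # all-SNV identity
  expect_identical(nrow(filter_snvs(out[0, ])), 0L)           # empty input
})

test_that("hypermutator rule: dual threshold, degenerate cohorts, summaries", {
  mk <- function(donor, n) data.frame(donor_id = donor, cancer_type = "T",
                                      chrom = "1", pos = seq_len(n),
                                      ref = "A", alt = "C")
  recs <- do.call(rbind, c(lapply(sprintf("d%02d", 1:10), mk, n = 100),
                           list(mk("hyper", 5000))))
  out <- remove_hypermutators(recs, absolute_cap = 100000,
                              fold_over_median = 10)
  expect_identical(sort(unique(out$records$donor_id)), sprintf("d%02d", 1:10))
  s <- out$summaries
  expect_identical(s$exclusion_reason[s$donor_id == "hyper"], "hypermutator")
  expect_true(all(s$excluded == (s$exclusion_reason != "none")))
  expect_identical(sum(s$snv_count), nrow(recs))     # counts cover the input
  # all donors below both thresholds: identity
  quiet <- do.call(rbind, lapply(c("a", "b", "c"), mk, n = 50))
  out2 <- remove_hypermutators(quiet)
  expect_identical(out2$records, quiet)
  expect_false(any(out2$summaries$excluded))
  # single-donor cohort: the fold-over-median rule cannot trigger,
  # only the absolute cap applies
  solo <- mk("only", 150)
  expect_identical(nrow(remove_hypermutators(solo, absolute_cap = 1000)$records),
                   150L)
  expect_identical(nrow(remove_hypermutators(solo, absolute_cap = 100)$records),
                   0L)
})

test_that("SNP removal is allele-aware by default, position-only on request", {
  recs <- filter_snvs(toy_records())
  snps <- data.frame(chrom = "chr1", pos = 100L, alt = "A")
  out <- remove_snp_overlap(recs, snps)            # allele mode
  expect_false(any(out$pos == 100 & out$chrom == "1" & out$alt == "A"))
  expect_identical(nrow(out), 2L)
  # same site, different alt allele survives allele-aware matching
  recs2 <- recs
  recs2$alt[recs2$pos == 100] <- "T"
  expect_identical(nrow(remove_snp_overlap(recs2, snps)), 4L)
  expect_identical(nrow(remove_snp_overlap(recs2, snps, mode = "position")), 2L)
  expect_identical(remove_snp_overlap(recs, snps[0, ]), recs)   # empty set
})

test_that("snp sites load from TSV and VCF alike", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\talt", "chr1\t100\tA", "2\t7\tG"), tsv)
  s1 <- load_snp_sites(tsv, "tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\trs1\tG\tA\t.\tPASS\t.",
               "2\t7\trs2\tT\tG\t.\tPASS\t."), vcf)
  s2 <- load_snp_sites(vcf, "vcf")
  expect_identical(s1[c("chrom", "pos", "alt")], s2[c("chrom", "pos", "alt")])
})

test_that("mappability filter matches the hand count on a toy track", {
  track <- covariate_track("mappability", "continuous",
                           list(`1` = data.frame(start = 0:3, end = 1:4,
                                                 value = c(1, 1, 0.3, 1))))
  recs <- data.frame(donor_id = "d", cancer_type = "T", chrom = "1",
                     pos = 1:4, ref = "A", alt = "C")
  expect_identical(nrow(apply_mappability_filter(recs, track, 0.9)), 3L)
  expect_identical(apply_mappability_filter(recs, track, 0), recs)
  expect_identical(nrow(apply_mappability_filter(recs, track, 1.0)), 3L)
  # outside the track domain: warned and removed
  far <- rbind(recs, data.frame(donor_id = "d", cancer_type = "T",
                                chrom = "1", pos = 999L, ref = "A", alt = "C"))
  expect_warning(out <- apply_mappability_filter(far, track, 0.9),
                 "outside")
  expect_identical(nrow(out), 3L)
})

test_that("filters are subsets and commute on a random fixture", {
  co <- small_cohort()
  recs <- co$records
  snps <- data.frame(chrom = "1", pos = recs$pos[seq(1, nrow(recs), by = 7)],
                     alt = recs$alt[seq(1, nrow(recs), by = 7)])
  n_bins <- 50
  set.seed(31)
  mp <- covariate_track("mappability", "continuous", list(`1` = data.frame(
    start = (0:(n_bins - 1)) * 1000, end = (1:n_bins) * 1000,
    value = sample(c(1, 1, 1, 0.4), n_bins, replace = TRUE))))
  a <- apply_mappability_filter(remove_snp_overlap(recs, snps), mp, 0.9)
  b <- remove_snp_overlap(apply_mappability_filter(recs, mp, 0.9), snps)
  expect_identical(a, b)
  expect_true(nrow(a) <= nrow(recs))
  expect_true(all(paste(a$donor_id, a$pos) %in% paste(recs$donor_id, recs$pos)))
})
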