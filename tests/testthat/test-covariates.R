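# Track queries, site features, binning and the feature/rate correlation.

test_that("binary and continuous tracks answer point queries", {
  bin <- covariate_track("tfbs", "binary",
                         list(`1` = data.frame(start = c(0, 20),
                                               end = c(10, 30))))
  expect_equal(track_values(bin, "1", c(6, 16, 21, 30, 31)),
               c(1, 0, 1, 1, 0))   # 1-based pos 6 = 0-based 5
  cont <- covariate_track("rt", "continuous",
                          list(`1` = data.frame(start = 0, end = 100,
                                                value = 0.7)))
  expect_equal(track_values(cont, "1", 51), 0.7)
  expect_equal(track_values(cont, "1", 101), 0)       # gap -> fill
  expect_equal(track_values(cont, "chr1", 51), 0.7)   # chr-prefix dialect
})

test_that("track files round-trip through bedGraph and BED", {
  dir <- withr::local_tempdir()
  cont <- covariate_track("rt", "continuous",
                          list(`1` = data.frame(start = c(0, 50, 200),
                                                end = c(50, 100, 300),
                                                value = c(0.2, 0.9, 0.5))))
  p <- file.path(dir, "rt.bedGraph")
  write_track(cont, p)
  back <- load_track(p, "continuous", "rt")
  expect_equal(back$data, cont$data)
  bin <- covariate_track("mark", "binary",
                         list(`1` = data.frame(start = c(10, 40),
                                               end = c(20, 60))))
  p2 <- file.path(dir, "mark.bed")
  write_track(bin, p2)
  back2 <- load_track(p2, "binary", "mark")
  expect_equal(back2$data[["1"]][c("start", "end")],
               bin$data[["1"]][c("start", "end")])
})

test_that("overlapping intervals merge and unsorted input sorts, with warnings", {
  expect_warning(
    tr <- covariate_track("m", "binary",
                          list(`1` = data.frame(start = c(0, 5),
                                                end = c(10, 20)))),
    "overlapping")
  expect_identical(tr$data[["1"]], data.frame(start = 0, end = 20))
  expect_warning(
    tr2 <- covariate_track("m", "binary",
                           list(`1` = data.frame(start = c(30, 0),
                                                 end = c(40, 10)))),
    "unsorted")
  expect_identical(tr2$data[["1"]]$start, c(0, 30))
})

test_that("trinucleotide context collapses to a pyrimidine centre", {
  seqs <- c(`1` = "AACGTN")
  # position 3: A[C]G -> already pyrimidine-centred
  expect_identical(trinucleotide_context(3, seqs), "ACG")
  # position 4: C[G]T -> purine centre, reverse complement is ACG
  expect_identical(trinucleotide_context(4, seqs), "ACG")
  expect_identical(trinucleotide_context(1, seqs), "edge")
  expect_identical(trinucleotide_context(6, seqs), "edge")
  expect_identical(trinucleotide_context(5, seqs), "unknown")  # GTN
  expect_length(trinucleotide_categories(), 32L)
  # every category is itself pyrimidine-centred
  expect_true(all(substring(trinucleotide_categories(), 2, 2) %in% c("C", "T")))
})

test_that("site features carry binary indicators and stored z-scores", {
  co <- small_cohort()
  d <- co$tracks$TFBS$data[["1"]]
  inside <- d$start[1] + 1L   # 1-based position in the first TFBS interval
  f <- site_features(inside, co$tracks, co$sequence)
  expect_equal(unname(f$features["TFBS"]), 1)
  norm <- list(replication_timing = c(mean = 0.5, sd = 0.1))
  f2 <- site_features(inside, co$tracks, co$sequence, normalization = norm)
  raw <- track_values(co$tracks$replication_timing, "1", inside)
  expect_equal(unname(f2$features["replication_timing"]), (raw - 0.5) / 0.1)
})

test_that("training z-scores have mean 0 and sd 1 under the stored normalization", {
  co <- small_cohort()
  pos <- seq(101, 49000, by = 13)
  norm <- nchotspot:::compute_normalization("1", pos, co$tracks)
  X <- nchotspot:::build_design("1", pos, co$tracks, co$sequence, norm,
                                use_context = FALSE)
  for (nm in names(norm)) {
    expect_lt(abs(mean(X[, nm])), 1e-9)
    expect_lt(abs(sd(X[, nm]) - 1), 1e-9)
  }
})

test_that("bins tile the domain with a flagged partial tail", {
  b <- build_bins(3500000, 1000000)
  expect_identical(nrow(b), 4L)
  expect_identical(b$end[4] - b$start[4], 500000)
  expect_identical(b$partial, c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(nrow(build_bins(2000000, 1000000)), 2L)
  expect_identical(nrow(build_bins(500000, 1000000)), 1L)
})

test_that("bin mutation rates: arithmetic, empty bins, mask restriction", {
  bins <- build_bins(2000000, 1000000)
  recs <- data.frame(donor_id = "d", cancer_type = "T", chrom = "1",
                     pos = sort(sample.int(900000, 100)), ref = "A", alt = "C")
  bt <- bin_mutation_rate(recs, bins, n_donors = 50)
  expect_equal(bt$rate[1], 100 / (1e6 * 50))   # 2e-6 per bp per donor
  expect_equal(bt$rate[2], 0)
  expect_error(bin_mutation_rate(recs, bins, n_donors = 0), "positive")
  # mask covering the SNV-bearing half doubles the rate
  mask <- data.frame(start = 0, end = 500000)
  recs2 <- recs
  recs2$pos <- recs2$pos %% 400000 + 1   # all in the masked half
  full <- bin_mutation_rate(recs2, bins, 50)
  masked <- bin_mutation_rate(recs2, bins, 50, mask = mask)
  expect_equal(masked$rate[1], 2 * full$rate[1])
  expect_false(masked$usable[2])         # no masked bases in bin 2
})

test_that("bin covariate means reflect coverage and bp-weighted values", {
  bins <- build_bins(10000, 5000)
  bin <- covariate_track("mark", "binary",
                         list(`1` = data.frame(start = 0, end = 2500)))
  cont <- covariate_track("rt", "continuous",
                          list(`1` = data.frame(start = c(0, 5000),
                                                end = c(5000, 10000),
                                                value = c(0.2, 0.8))))
  bt <- bin_covariate_means(bins, list(bin, cont))
  expect_equal(bt$cov_mark, c(0.5, 0))
  expect_equal(bt$cov_rt, c(0.2, 0.8))
})

test_that("correlation: perfect, independent, and generative positive cases", {
  # identical feature: coefficient 1
  d <- data.frame(rate = (1:200) / 1000, usable = TRUE)
  d$cov_self <- d$rate
  out <- correlate_features(d, "spearman")
  expect_equal(out$coefficient[out$feature == "self"], 1)
  # constant feature: missing coefficient
  d$cov_flat <- 1
  out2 <- correlate_features(d)
  expect_true(is.na(out2$coefficient[out2$feature == "flat"]))
  # independent feature at 1000 bins stays near zero
  set.seed(55)
  ind <- data.frame(rate = runif(1000), cov_noise = runif(1000),
                    usable = TRUE)
  out3 <- correlate_features(ind)
  expect_lt(abs(out3$coefficient[1]), 0.1)
  expect_error(correlate_features(d[1:5, ]), "10 usable bins")
  # cohort simulated with positive effect on the heterochromatin-like mark
  spec <- cohort_spec(genome_length = 500000, n_donors = 10,
                      mean_logit = qlogis(2e-3), seed = 17, n_genes = 0)
  co <- simulate_cohort(spec)
  bins <- build_bins(500000, 1000)
  bt <- bin_covariate_means(bin_mutation_rate(co$records, bins, 10), co$tracks)
  cf <- correlate_features(bt, "spearman")
  expect_gt(cf$coefficient[cf$feature == "H3K9me3"], 0.1)
  expect_lt(cf$p[cf$feature == "H3K9me3"], 0.01)
})

test_that("coding and noncoding masks give matching profiles under a shared rate", {
  # rates independent of the masks by construction: correlations agree
  spec <- cohort_spec(genome_length = 400000, n_donors = 10,
                      mean_logit = qlogis(2e-3), seed = 23, n_genes = 0)
  co <- simulate_cohort(spec)
  set.seed(77)
  starts <- sort(sample.int(399000, 150))
  coding <- nchotspot:::merge_intervals(
    data.frame(start = starts, end = starts + 1000))
  noncoding <- data.frame(
    start = c(0, coding$end),
    end = c(coding$start, 400000))
  noncoding <- noncoding[noncoding$end > noncoding$start, ]
  bins <- build_bins(400000, 2000)
  cf <- lapply(list(coding, noncoding), function(mask) {
    bt <- bin_covariate_means(
      bin_mutation_rate(co$records, bins, 10, mask = mask), co$tracks)
    correlate_features(bt, "spearman")
  })
  both <- merge(cf[[1]], cf[[2]], by = "feature")
  h <- both[both$feature == "H3K9me3", ]
  expect_gt(h$coefficient.x, 0)
  expect_gt(h$coefficient.y, 0)
  expect_lt(abs(h$coefficient.x - h$coefficient.y), 0.3)
})
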