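# Shared fixtures (built in code, cached across test files) and independent
# oracles.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_cache)) {
    assign(name, builder(), .fixture_cache)
  }
  get(name, .fixture_cache)
}

# small cohort used by several files: 50 kb, 10 donors, default tracks
small_cohort <- function() {
  fixture("small_cohort", function() {
    spec <- cohort_spec(genome_length = 50000, n_donors = 10, n_genes = 3,
                        seed = 42, mean_logit = qlogis(3e-3))
    simulate_cohort(spec)
  })
}

# brute-force Poisson-binomial upper tail by enumeration over 2^n outcomes
enum_pb_tail <- function(probs, k) {
  n <- length(probs)
  if (k <= 0) return(1)
  if (k > n) return(0)
  total <- 0
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[seq_len(n)]
    if (sum(bits) >= k) {
      total <- total + prod(ifelse(bits == 1, probs, 1 - probs))
    }
  }
  total
}

# toy mutation table used by ingest tests
toy_records <- function() {
  data.frame(donor_id = c("d1", "d1", "d2", "d3"),
             cancer_type = "T",
             chrom = c("1", "1", "1", "2"),
             pos = c(100L, 200L, 100L, 50L),
             ref = c("G", "A", "G", "C"),
             alt = c("A", "T", "A", "G"),
             stringsAsFactors = FALSE)
}

write_toy_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_toy_maf <- function(df, path) {
  maf <- data.frame(Tumor_Sample_Barcode = df$donor_id,
                    Cancer_Type = df$cancer_type,
                    Chromosome = paste0("chr", df$chrom),
                    Start_Position = df$pos,
                    Reference_Allele = df$ref,
                    Tumor_Seq_Allele2 = df$alt)
  write.table(maf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_toy_vcf <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDONOR=%s;CTYPE=%s",
                     df$chrom, df$pos, tolower(df$ref), df$alt, df$donor_id,
                     df$cancer_type), con)
  path
}

# constant-probability model over n donors: alpha = qlogis(p), no covariates
flat_model <- function(n_donors, p) {
  spec <- cohort_spec(genome_length = 1000, n_donors = n_donors,
                      true_coefficients = setNames(numeric(0), character(0)),
                      donor_log_offsets = rep(qlogis(p), n_donors),
                      covariate_specs = data.frame(name = character(0),
                                                   kind = character(0),
                                                   corlen = numeric(0)),
                      n_genes = 0, seed = 1)
  true_background_model(spec)
}
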