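#' @keywords internal
"_PACKAGE"

#' @importFrom stats plogis qlogis rnorm runif rbinom median sd cor.test
#'   binomial glm.fit p.adjust quantile setNames dnorm
#' @importFrom utils read.delim write.table packageVersion head
NULL

# ---- coordinate conversions (single-sourced) --------------------------------
# MutationRecord positions are 1-based inclusive; all interval types are
# 0-based half-open [start, end).

pos_to_zero <- function(pos) pos - 1L

zero_to_pos <- function(z) z + 1L

# 1-based inclusive [lo, hi] -> 0-based half-open [start, end)
inclusive_to_halfopen <- function(lo, hi) list(start = lo - 1L, end = hi)

# position pos (1-based) inside 0-based half-open [start, end)?
pos_in_interval <- function(pos, start, end) (pos - 1L) >= start & (pos - 1L) < end

# ---- chromosome-name harmonization ------------------------------------------
# Canonical internal form has no "chr" prefix; both dialects accepted.

#' Harmonize chromosome names
#'
#' Strips a leading `"chr"` prefix so that `"chr1"` and `"1"` compare equal.
#' All internal containers use the stripped form.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector in canonical (prefix-free) form.
#' @export
harmonize_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

# ---- small helpers ----------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

# 31-bit polynomial rolling hash; stamps output files with a short
# configuration fingerprint (all arithmetic exact in doubles)
string_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

output_header <- function(seed = NA, config_hash = NA) {
  sprintf("# nchotspot %s seed=%s config=%s",
          as.character(packageVersion("nchotspot")),
          as.character(seed), as.character(config_hash))
}

# write a data.frame as TSV with a provenance header comment
write_tsv_header <- function(df, path, seed = NA, config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, config_hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_header <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# reverse complement for plain character strings of A/C/G/T/N
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}
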