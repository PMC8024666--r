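# Megabase-scale binning: per-bin mutation rate and per-bin mean covariate
# values, and their correlation across bins — the regional mutation-rate
# structure analysis (chromatin features vs somatic rate, coding vs
# noncoding).

#' Tile a domain with fixed-width bins
#'
#' Consecutive half-open bins over `[0, domain_length)`; a final partial bin
#' is kept and flagged.
#'
#' @param domain_length domain length in bp.
#' @param bin_size bin width in bp (>= 1000; default 1 Mb).
#' @param chrom chromosome name.
#' @return data frame `chrom`, `start`, `end`, `partial`.
#' @export
build_bins <- function(domain_length, bin_size = 1000000L, chrom = "1") {
  stopifnot(bin_size >= 1000)
  starts <- seq(0, domain_length - 1, by = bin_size)
  ends <- pmin(starts + bin_size, domain_length)
  data.frame(chrom = harmonize_chrom(chrom), start = starts, end = ends,
             partial = (ends - starts) < bin_size, stringsAsFactors = FALSE)
}

# total overlap (bp) of a sorted disjoint interval set with each bin
mask_bp_per_bin <- function(bins, mask) {
  vapply(seq_len(nrow(bins)), function(i) {
    o <- pmin(mask$end, bins$end[i]) - pmax(mask$start, bins$start[i])
    sum(o[o > 0])
  }, numeric(1))
}

#' Per-bin mutation rate
#'
#' Rate = (# SNVs in bin, restricted to the mask) / (masked bp x donors),
#' in mutations per bp per donor. Bins with fewer masked bases than
#' `min_masked_bp` are flagged unusable and excluded from correlation.
#'
#' @param records filtered SNV data frame.
#' @param bins bin table from [build_bins()].
#' @param n_donors number of donors in the cohort (> 0).
#' @param mask optional region mask (data frame `start`, `end`, 0-based
#'   half-open; e.g. coding or noncoding bases). `NULL` uses every base.
#' @param min_masked_bp minimum masked bases for a usable bin (default 200).
#' @return `bins` with `masked_bp`, `n_snv`, `rate`, `usable` columns.
#' @export
bin_mutation_rate <- function(records, bins, n_donors, mask = NULL,
                              min_masked_bp = 200) {
  if (n_donors <= 0) stop("n_donors must be positive")
  pos0 <- records$pos - 1L
  if (!is.null(mask)) {
    mask <- merge_intervals(as.data.frame(mask))
    idx <- findInterval(pos0, mask$start)
    in_mask <- idx >= 1 & pos0 < mask$end[pmax(idx, 1)]
    pos0 <- pos0[in_mask]
    bins$masked_bp <- mask_bp_per_bin(bins, mask)
  } else {
    bins$masked_bp <- bins$end - bins$start
  }
  bidx <- findInterval(pos0, bins$start)
  bidx <- bidx[bidx >= 1 & pos0 < bins$end[pmax(bidx, 1)]]
  cnt <- tabulate(bidx, nbins = nrow(bins))
  bins$n_snv <- cnt
  bins$rate <- ifelse(bins$masked_bp > 0,
                      cnt / (bins$masked_bp * n_donors), 0)
  bins$usable <- bins$masked_bp >= min_masked_bp
  bins
}

#' Per-bin mean covariate values
#'
#' Adds one `cov_<name>` column per track: the bin mean of a continuous
#' track (bp-weighted over its intervals) or the covered fraction for a
#' binary track.
#'
#' @param bins bin table.
#' @param tracks named list of [covariate_track()].
#' @return `bins` with one mean-value column per track.
#' @export
bin_covariate_means <- function(bins, tracks) {
  for (tr in tracks) {
    col <- vapply(seq_len(nrow(bins)), function(i) {
      d <- tr$data[[bins$chrom[i]]]
      width <- bins$end[i] - bins$start[i]
      if (is.null(d) || nrow(d) == 0L || width <= 0) return(0)
      o <- pmin(d$end, bins$end[i]) - pmax(d$start, bins$start[i])
      keep <- o > 0
      if (!any(keep)) return(0)
      if (tr$kind == "binary") {
        sum(o[keep]) / width
      } else {
        # gaps contribute the fill value
        (sum(o[keep] * d$value[keep]) + (width - sum(o[keep])) * tr$fill) / width
      }
    }, numeric(1))
    bins[[paste0("cov_", tr$name)]] <- col
  }
  bins
}

#' Correlate covariates with the regional mutation rate
#'
#' One correlation per covariate between its per-bin mean and the per-bin
#' mutation rate, over usable bins. Spearman by default (robust to the
#' skewed rate distribution); Pearson available. Constant features are
#' reported with `NA` coefficients.
#'
#' @param bin_table output of [bin_mutation_rate()] then
#'   [bin_covariate_means()].
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data frame `feature`, `coefficient`, `p`, `n_bins`.
#' @export
correlate_features <- function(bin_table, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  use <- if ("usable" %in% names(bin_table)) bin_table$usable else
    rep(TRUE, nrow(bin_table))
  d <- bin_table[use, , drop = FALSE]
  if (nrow(d) < 10L) stop("need at least 10 usable bins")
  feats <- grep("^cov_", names(d), value = TRUE)
  rows <- lapply(feats, function(f) {
    x <- d[[f]]
    if (sd(x) == 0 || sd(d$rate) == 0) {
      return(data.frame(feature = sub("^cov_", "", f), coefficient = NA_real_,
                        p = NA_real_, n_bins = nrow(d)))
    }
    ct <- suppressWarnings(cor.test(x, d$rate, method = method, exact = FALSE))
    data.frame(feature = sub("^cov_", "", f),
               coefficient = unname(ct$estimate), p = ct$p.value,
               n_bins = nrow(d))
  })
  do.call(rbind, rows)
}
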