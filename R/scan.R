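# Hotspot scan: recurrent sites -> fixed-width windows -> per-donor window
# probabilities under the background model -> exact Poisson-binomial tail
# test -> multiple-testing adjustment.

#' Find recurrently mutated sites
#'
#' Positions at which at least `min_donors` distinct donors carry a SNV
#' (a donor counts once per site regardless of allele or duplicate rows).
#'
#' @param records filtered SNV data frame.
#' @param min_donors recurrence threshold (default 2).
#' @return data frame `chrom`, `pos`, `donor_count`, sorted by position.
#' @export
find_recurrent_sites <- function(records, min_donors = 2L) {
  if (nrow(records) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      donor_count = integer(0)))
  }
  u <- unique(records[c("donor_id", "chrom", "pos")])
  key <- paste(u$chrom, u$pos)
  counts <- table(key)
  keep <- names(counts)[counts >= min_donors]
  if (!length(keep)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      donor_count = integer(0)))
  }
  parts <- strsplit(keep, " ", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, character(1), 1),
                    pos = as.integer(vapply(parts, `[`, character(1), 2)),
                    donor_count = as.integer(counts[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build fixed-width windows around recurrent sites
#'
#' One window of odd width centred on each seed site; coordinates are
#' 0-based half-open. Windows sharing (chrom, start, width) are
#' deduplicated; windows clipped by a chromosome edge are dropped with a
#' warning.
#'
#' @param sites data frame from [find_recurrent_sites()].
#' @param width odd window width in bp, 7-21 (default 11).
#' @param chrom_lengths named integer vector of chromosome lengths (used to
#'   drop edge-clipped windows); `NULL` skips the right-edge check.
#' @return data frame `chrom`, `start`, `end`, `center` (1-based seed),
#'   `width`.
#' @export
build_windows <- function(sites, width = 11L, chrom_lengths = NULL) {
  width <- as.integer(width)
  if (width %% 2L != 1L) stop("window width must be odd")
  if (width < 7L || width > 21L) stop("window width must be in [7, 21]")
  half <- (width - 1L) %/% 2L
  w <- data.frame(chrom = sites$chrom,
                  start = sites$pos - 1L - half,
                  end = sites$pos + half,
                  center = sites$pos, width = as.integer(width),
                  stringsAsFactors = FALSE)
  clipped <- w$start < 0L
  if (!is.null(chrom_lengths)) {
    names(chrom_lengths) <- harmonize_chrom(names(chrom_lengths))
    clipped <- clipped | w$end > chrom_lengths[w$chrom]
  }
  if (any(clipped)) {
    warning("dropping ", sum(clipped), " window(s) clipped at chromosome edges")
    w <- w[!clipped, , drop = FALSE]
  }
  w <- w[!duplicated(w[c("chrom", "start", "width")]), , drop = FALSE]
  rownames(w) <- NULL
  w
}

#' Window mutation probability from per-site probabilities
#'
#' `1 - prod_i (1 - q_i)`, accumulated in `log1p` space. Degenerate inputs
#' are exact: all zeros give 0, any probability of 1 gives 1.
#'
#' @param q numeric vector of per-site probabilities in \[0, 1\].
#' @return probability of at least one mutation across the sites.
#' @export
window_probability <- function(q) {
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1)) {
    stop("per-site probabilities must lie in [0, 1]")
  }
  if (any(q == 1)) return(1)
  -expm1(sum(log1p(-q)))
}

#' Donor probability of mutating anywhere in a window
#'
#' `p_j = 1 - prod_i (1 - q_ij)` over the window's sites, where `q_ij` are
#' the model's per-site probabilities; accumulated in `log1p` space for
#' stability.
#'
#' @param model a `background_model`.
#' @param donor_id donor identifier.
#' @param window one-row window data frame (as from [build_windows()]).
#' @param tracks,sequence covariate tracks and reference sequence.
#' @return probability that the donor carries at least one SNV in the window.
#' @export
window_donor_probability <- function(model, donor_id, window, tracks, sequence) {
  pos <- (window$start + 1L):window$end
  q <- predict.background_model(model, window$chrom, pos, donor_id, tracks,
                                sequence)
  window_probability(q)
}

# window probabilities for all donors at once from precomputed per-site
# covariate logits g (sites are the window's positions)
window_probs_all <- function(alpha, g) {
  # q[j, i] = plogis(alpha_j + g_i); p_j = 1 - exp(sum_i log1p(-q))
  eta <- outer(alpha, g, `+`)
  q <- clamp_prob(plogis(eta))
  1 - exp(rowSums(log1p(-q)))
}

#' Test a single window
#'
#' Counts the distinct donors mutated in the window and computes the exact
#' Poisson-binomial upper-tail probability of observing at least that many
#' under the supplied per-donor window probabilities.
#'
#' @param candidate one-row window data frame.
#' @param records filtered SNV data frame.
#' @param donor_probs named per-donor window probabilities (every retained
#'   donor).
#' @return list with `k`, `p_value`, `neg_log10_p`, `mutated_donors`.
#' @export
test_window <- function(candidate, records, donor_probs) {
  inside <- records$chrom == candidate$chrom &
    pos_in_interval(records$pos, candidate$start, candidate$end)
  mutated <- unique(records$donor_id[inside])
  k <- length(mutated)
  p <- poisson_binomial_tail(unname(donor_probs), k)
  p_floored <- max(p, 1e-300)
  list(k = k, p_value = p, neg_log10_p = -log10(p_floored),
       mutated_donors = mutated)
}

#' Adjust window p-values for multiple testing
#'
#' Bonferroni by default (`m` = number of windows tested at that width,
#' capped at 1); Benjamini-Hochberg available.
#'
#' @param results scan result data frame with a `p_value` column.
#' @param method `"bonferroni"` or `"BH"`.
#' @return `results` with an `adjusted_p` (and for Bonferroni
#'   `bonferroni_p`) column.
#' @export
adjust_pvalues <- function(results, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  if (nrow(results) == 0L) {
    results$adjusted_p <- numeric(0)
    results$bonferroni_p <- numeric(0)
    return(results)
  }
  results$adjusted_p <- p.adjust(results$p_value, method = method)
  if (method == "bonferroni") results$bonferroni_p <- results$adjusted_p
  results
}

#' Scan a cohort for recurrently mutated windows
#'
#' Full pipeline for each requested width: find recurrent seed sites, build
#' centred windows, compute per-donor window probabilities under the
#' background model, score each window with the exact Poisson-binomial tail
#' test, and adjust for the number of windows tested at that width. Results
#' are ordered by adjusted p ascending, then recurrence `k` descending, then
#' coordinates.
#'
#' @param records filtered SNV data frame (the cohort the model was fitted
#'   on).
#' @param model a `background_model` (fitted or true-parameter).
#' @param tracks,sequence covariate tracks and reference sequence.
#' @param widths odd window widths in bp (default 11).
#' @param min_donors recurrence seed threshold (default 2).
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @param m_mode Bonferroni denominator: `"tested"` (default; the windows
#'   actually tested at that width) or `"genome"` (every possible window
#'   position, which also accounts for the data-dependent seeding of
#'   candidate windows and is required for strict family-wise error
#'   control; see [scan_all_windows()]).
#' @return object of class `hotspot_scan`: per-width result tables plus scan
#'   parameters.
#' @export
scan_hotspots <- function(records, model, tracks, sequence, widths = 11L,
                          min_donors = 2L, adjust = c("bonferroni", "BH"),
                          m_mode = c("tested", "genome")) {
  adjust <- match.arg(adjust)
  m_mode <- match.arg(m_mode)
  names(sequence) <- harmonize_chrom(names(sequence))
  chrom_lengths <- nchar(sequence)
  donors <- names(model$donor_intercepts)
  alpha <- unname(model$donor_intercepts)
  sites <- find_recurrent_sites(records, min_donors)
  results <- lapply(widths, function(w) {
    wins <- build_windows(sites, w, chrom_lengths)
    if (nrow(wins) == 0L) {
      return(adjust_pvalues(
        data.frame(chrom = character(0), start = integer(0), end = integer(0),
                   center = integer(0), width = integer(0), k = integer(0),
                   p_value = numeric(0), neg_log10_p = numeric(0)),
        adjust))
    }
    nw <- nrow(wins)
    # batched per-site covariate logits over all window positions
    win_id <- rep(seq_len(nw), each = w)
    pos_all <- wins$start[win_id] + rep(seq_len(w), nw)   # 1-based
    g_all <- model_linear_predictor(model, wins$chrom[win_id], pos_all,
                                    tracks, sequence)
    # log survival sums per (window, donor): S[w, j] = sum_i log1p(-q_ij)
    eta <- outer(g_all, alpha, `+`)                       # sites x donors
    lsurv <- log1p(-clamp_prob(plogis(eta)))
    S <- rowsum(lsurv, win_id)
    pwin <- 1 - exp(S)                                    # windows x donors
    # distinct-donor recurrence per window
    u <- unique(records[records$is_snv %||% TRUE, c("donor_id", "chrom", "pos")])
    k <- integer(nw)
    for (cn in unique(wins$chrom)) {
      wi <- which(wins$chrom == cn)
      ri <- which(u$chrom == cn)
      if (!length(ri)) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(start = u$pos[ri], width = 1L),
        IRanges::IRanges(start = wins$start[wi] + 1L, end = wins$end[wi]))
      if (!length(ov)) next
      hits <- unique(data.frame(w = S4Vectors::subjectHits(ov),
                                d = u$donor_id[ri][S4Vectors::queryHits(ov)]))
      tk <- table(hits$w)
      k[wi[as.integer(names(tk))]] <- as.integer(tk)
    }
    p_value <- vapply(seq_len(nw), function(i)
      poisson_binomial_tail(pwin[i, ], k[i]), numeric(1))
    res <- data.frame(chrom = wins$chrom, start = wins$start, end = wins$end,
                      center = wins$center, width = wins$width, k = k,
                      p_value = p_value,
                      neg_log10_p = -log10(pmax(p_value, 1e-300)),
                      stringsAsFactors = FALSE)
    if (adjust == "bonferroni" && m_mode == "genome") {
      m <- sum(pmax(chrom_lengths - w + 1L, 0L))
      res$adjusted_p <- pmin(1, m * res$p_value)
      res$bonferroni_p <- res$adjusted_p
    } else {
      res <- adjust_pvalues(res, adjust)
    }
    o <- order(res$adjusted_p, -res$k, res$chrom, res$start)
    res <- res[o, , drop = FALSE]
    rownames(res) <- NULL
    res
  })
  names(results) <- as.character(widths)
  structure(list(results = results, widths = widths, min_donors = min_donors,
                 adjust = adjust, m_mode = m_mode,
                 n_donors = length(donors)),
            class = "hotspot_scan")
}

#' Evaluate the window test at every genome position
#'
#' Computes, for every possible window center (not only recurrently mutated
#' seeds), the distinct-donor recurrence `k` and the exact Poisson-binomial
#' tail `P(K >= k)` under the background model. This is the unconditional
#' view of the scan: at unmutated centers `k = 0` and `p = 1`. Used for
#' null-calibration studies (the per-window test is exactly valid, so the
#' pooled p-values are conservative by discreteness) and for genome-wide
#' family-wise error control, which accounts for the data-dependent
#' selection of seeded windows.
#'
#' The per-donor window probabilities are rolling log-survival sums and the
#' Poisson-binomial mass is propagated for all centers at once by a
#' truncated convolution (exact for all counts up to `max_k`; rarer centers
#' fall back to the full tail computation).
#'
#' @param records filtered SNV data frame.
#' @param model a `background_model`.
#' @param tracks,sequence covariate tracks and reference sequence.
#' @param width odd window width in bp (default 11).
#' @param max_k convolution truncation (default 12).
#' @return data frame `chrom`, `center` (1-based), `k`, `p_value`, covering
#'   every center whose window lies fully inside the chromosome.
#' @export
scan_all_windows <- function(records, model, tracks, sequence, width = 11L,
                             max_k = 12L) {
  width <- as.integer(width)
  if (width %% 2L != 1L) stop("window width must be odd")
  half <- (width - 1L) %/% 2L
  names(sequence) <- harmonize_chrom(names(sequence))
  donors <- names(model$donor_intercepts)
  alpha <- unname(model$donor_intercepts)
  out <- lapply(names(sequence), function(cn) {
    L <- nchar(sequence[[cn]])
    centers <- (half + 1L):(L - half)
    nc <- length(centers)
    g <- model_linear_predictor(model, cn, seq_len(L), tracks, sequence)
    # recurrence k at every center: union coverage of per-donor +/- half hulls
    u <- unique(records[records$chrom == cn, c("donor_id", "pos")])
    dcov <- integer(L + 1L)
    for (d in unique(u$donor_id)) {
      iv <- merge_intervals(data.frame(start = pmax(u$pos[u$donor_id == d] - half, 1L),
                                       end = pmin(u$pos[u$donor_id == d] + half, L)))
      dcov[iv$start] <- dcov[iv$start] + 1L
      dcov[iv$end + 1L] <- dcov[iv$end + 1L] - 1L
    }
    k <- cumsum(dcov[seq_len(L)])[centers]
    # truncated Poisson-binomial convolution across all centers
    kmax <- as.integer(max_k)
    f <- matrix(0, nc, kmax + 1L)
    f[, 1L] <- 1
    pw <- matrix(0, nc, length(alpha))       # per-donor window probabilities
    for (j in seq_along(alpha)) {
      l <- log1p(-clamp_prob(plogis(alpha[j] + g)))
      cs <- c(0, cumsum(l))
      p <- 1 - exp(cs[centers + half + 1L] - cs[centers - half])
      pw[, j] <- p
      for (cc in kmax:1L) {
        f[, cc + 1L] <- f[, cc + 1L] * (1 - p) + f[, cc] * p
      }
      f[, 1L] <- f[, 1L] * (1 - p)
    }
    cdf <- f                                 # P(K <= c), exact for c < kmax
    for (cc in seq_len(kmax)) cdf[, cc + 1L] <- cdf[, cc] + f[, cc + 1L]
    p_value <- rep(1, nc)
    ok <- k >= 1L & k <= kmax
    p_value[ok] <- pmin(pmax(1 - cdf[cbind(which(ok), k[ok])], 0), 1)
    for (i in which(k > kmax)) {             # rare deep-tail centers: exact
      p_value[i] <- poisson_binomial_tail(pw[i, ], k[i])
    }
    data.frame(chrom = cn, center = centers, k = k, p_value = p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.hotspot_scan <- function(x, n = 5L, ...) {
  cat(sprintf("Hotspot scan: %d donor(s), widths {%s}, min_donors = %d, %s\n",
              x$n_donors, paste(x$widths, collapse = ", "), x$min_donors,
              x$adjust))
  for (w in names(x$results)) {
    res <- x$results[[w]]
    cat(sprintf("\nwidth %s bp: %d window(s) tested", w, nrow(res)))
    if (nrow(res)) {
      cat(sprintf(", %d with adjusted p < 0.05\n", sum(res$adjusted_p < 0.05)))
      print(head(res[c("chrom", "start", "end", "k", "p_value",
                       "adjusted_p")], n), row.names = FALSE)
    } else cat("\n")
  }
  invisible(x)
}

#' Recurrence-vs-probability scatter of a scan
#'
#' Plots `-log10` adjusted p against window recurrence `k` — the ranking
#' view used to prioritize candidate noncoding hotspots.
#'
#' @param x a `hotspot_scan`.
#' @param width which width's table to plot (default the first).
#' @param ... passed to [plot()].
#' @return the plotted table, invisibly.
#' @importFrom graphics abline
#' @export
plot.hotspot_scan <- function(x, width = x$widths[1], ...) {
  res <- x$results[[as.character(width)]]
  if (is.null(res) || nrow(res) == 0L) {
    stop("no windows tested at width ", width)
  }
  neg <- -log10(pmax(res$adjusted_p, 1e-300))
  plot(res$k, neg, xlab = "donors mutated in window (k)",
       ylab = expression(-log[10] ~ "adjusted p"),
       main = sprintf("%d bp window scan", as.integer(width)), ...)
  abline(h = -log10(0.05), lty = 2)
  invisible(res)
}
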