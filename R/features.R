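# Per-site feature vectors: pyrimidine-collapsed trinucleotide context,
# z-scored continuous covariates, binary indicators.

#' The 32 pyrimidine-collapsed trinucleotide categories
#'
#' All trinucleotides whose central base is a pyrimidine (C or T);
#' purine-centred trinucleotides are reverse-complemented into this set.
#'
#' @return character vector of length 32.
#' @export
trinucleotide_categories <- function() {
  b <- c("A", "C", "G", "T")
  ctx <- as.vector(outer(b, outer(c("C", "T"), b, paste0), paste0))
  sort(ctx)
}

#' Pyrimidine-collapsed trinucleotide context at positions
#'
#' Reads the reference trinucleotide centred at each position and collapses
#' it so the central base is a pyrimidine (reverse complement otherwise).
#' Positions at chromosome edges give `"edge"`; trinucleotides containing an
#' unknown base give `"unknown"`.
#'
#' @param pos integer vector of 1-based positions.
#' @param sequence named character vector of chromosome sequences.
#' @param chrom chromosome name (scalar or parallel vector).
#' @return character vector of context categories.
#' @export
trinucleotide_context <- function(pos, sequence, chrom = names(sequence)[1]) {
  chrom <- harmonize_chrom(chrom)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  names(sequence) <- harmonize_chrom(names(sequence))
  out <- character(length(pos))
  for (cn in unique(chrom)) {
    sel <- which(chrom == cn)
    s <- sequence[[cn]]
    L <- nchar(s)
    p <- pos[sel]
    edge <- p <= 1L | p >= L
    tri <- rep(NA_character_, length(p))
    ok <- !edge
    if (any(ok)) tri[ok] <- substring(s, p[ok] - 1L, p[ok] + 1L)
    centre <- substring(tri, 2L, 2L)
    flip <- !is.na(tri) & centre %in% c("A", "G")
    if (any(flip)) {                     # vectorized 3-mer reverse complement
      comp <- chartr("ACGTN", "TGCAN", tri[flip])
      tri[flip] <- paste0(substring(comp, 3L, 3L), substring(comp, 2L, 2L),
                          substring(comp, 1L, 1L))
    }
    bad <- !is.na(tri) & grepl("[^ACGT]", tri)
    tri[bad] <- "unknown"
    tri[edge] <- "edge"
    out[sel] <- tri
  }
  out
}

#' Per-site feature vector
#'
#' Assembles the features the background model uses at one site: the
#' trinucleotide-context category, continuous covariate values (z-scored
#' when a stored normalization is supplied) and binary indicators.
#'
#' @param pos 1-based position.
#' @param tracks named list of [covariate_track()].
#' @param sequence named character vector of chromosome sequences.
#' @param chrom chromosome name.
#' @param normalization optional per-feature list of `c(mean, sd)` (as stored
#'   in a fitted [fit_background()] model) applied to continuous features.
#' @return list with `position`, `context`, and named numeric `features`.
#' @export
site_features <- function(pos, tracks, sequence, chrom = names(sequence)[1],
                          normalization = NULL) {
  stopifnot(length(pos) == 1L)
  ctx <- trinucleotide_context(pos, sequence, chrom)
  vals <- vapply(tracks, function(tr) track_values(tr, chrom, pos), numeric(1))
  names(vals) <- vapply(tracks, `[[`, character(1), "name")
  if (!is.null(normalization)) {
    for (nm in names(normalization)) {
      if (nm %in% names(vals)) {
        ms <- normalization[[nm]]
        vals[nm] <- if (ms[2] > 0) (vals[nm] - ms[1]) / ms[2] else 0
      }
    }
  }
  list(position = pos, chrom = harmonize_chrom(chrom), context = ctx,
       features = vals)
}

# design matrix for a set of (chrom, pos) sites: continuous covariates
# (z-scored with `normalization`), binary indicators, and optionally 31
# context indicator columns (baseline = first category; edge/unknown fall in
# the baseline column pattern, i.e. all-zero)
build_design <- function(chrom, pos, tracks, sequence, normalization,
                         use_context = TRUE) {
  n <- length(pos)
  cols <- list()
  for (tr in tracks) {
    v <- track_values(tr, chrom, pos)
    if (tr$kind == "continuous") {
      ms <- normalization[[tr$name]]
      if (!is.null(ms)) {                # no stored normalization: use raw
        v <- if (ms[2] > 0) (v - ms[1]) / ms[2] else rep(0, n)
      }
    }
    cols[[tr$name]] <- v
  }
  X <- do.call(cbind, cols)
  if (use_context) {
    cats <- trinucleotide_categories()
    ctx <- trinucleotide_context(pos, sequence, chrom)
    idx <- match(ctx, cats)             # NA for baseline-equivalent edge/unknown
    C <- matrix(0, n, length(cats) - 1L,
                dimnames = list(NULL, paste0("ctx_", cats[-1])))
    hit <- which(!is.na(idx) & idx > 1L)
    C[cbind(hit, idx[hit] - 1L)] <- 1
    X <- cbind(X, C)
  }
  X
}

# normalization (mean, sd) of continuous tracks over a set of training sites
compute_normalization <- function(chrom, pos, tracks) {
  out <- list()
  for (tr in tracks) {
    if (tr$kind == "continuous") {
      v <- track_values(tr, chrom, pos)
      out[[tr$name]] <- c(mean = mean(v), sd = sd(v))
    }
  }
  out
}
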