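# Covariate tracks: continuous (binned values) or binary (interval sets),
# queryable at any 1-based position. Intervals are 0-based half-open.

#' Construct a covariate track
#'
#' A covariate track holds one named genomic feature, either `continuous`
#' (a step function over non-overlapping bins, e.g. replication timing or GC
#' content) or `binary` (an interval set, e.g. histone-mark peaks or TFBS
#' clusters). Tracks are queryable at any position; positions falling in a
#' gap of a continuous track return the declared `fill` value.
#'
#' @param name feature name.
#' @param kind `"continuous"` or `"binary"`.
#' @param data a named list (one entry per chromosome, canonical names) of
#'   data frames with columns `start`, `end` (0-based half-open) and, for
#'   continuous tracks, `value`.
#' @param fill value returned for continuous-track gaps (default 0).
#' @return an object of class `covariate_track`.
#' @export
covariate_track <- function(name, kind = c("continuous", "binary"), data,
                            fill = 0) {
  kind <- match.arg(kind)
  stopifnot(is.list(data), length(names(data)) == length(data))
  names(data) <- harmonize_chrom(names(data))
  data <- lapply(data, function(d) {
    d <- as.data.frame(d)
    stopifnot(all(c("start", "end") %in% names(d)))
    if (kind == "continuous" && !"value" %in% names(d)) {
      stop("continuous track needs a 'value' column")
    }
    if (nrow(d) > 1 && is.unsorted(d$start)) {
      warning("unsorted intervals in track '", name, "': sorting")
      d <- d[order(d$start), , drop = FALSE]
    }
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      if (kind == "binary") {
        warning("overlapping intervals in track '", name, "': merging")
        d <- merge_intervals(d)
      } else {
        stop("overlapping bins in continuous track '", name, "'")
      }
    }
    stopifnot(all(d$end > d$start))
    if (kind == "continuous" && any(!is.finite(d$value))) {
      stop("non-finite values in continuous track '", name, "'")
    }
    rownames(d) <- NULL
    d
  })
  structure(list(name = name, kind = kind, data = data, fill = fill),
            class = "covariate_track")
}

# merge sorted, possibly-overlapping intervals into a disjoint set
merge_intervals <- function(d) {
  d <- d[order(d$start), , drop = FALSE]
  start <- d$start; end <- d$end
  keep_s <- start[1]; keep_e <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (nrow(d) > 1) {
    for (i in 2:nrow(d)) {
      if (start[i] <= keep_e) {
        keep_e <- max(keep_e, end[i])
      } else {
        out_s <- c(out_s, keep_s); out_e <- c(out_e, keep_e)
        keep_s <- start[i]; keep_e <- end[i]
      }
    }
  }
  data.frame(start = c(out_s, keep_s), end = c(out_e, keep_e))
}

#' @export
print.covariate_track <- function(x, ...) {
  n <- sum(vapply(x$data, nrow, integer(1)))
  cat(sprintf("<covariate_track> '%s' (%s), %d interval(s) on %d chromosome(s)\n",
              x$name, x$kind, n, length(x$data)))
  invisible(x)
}

#' Query a covariate track
#'
#' Returns the track value at 1-based positions. Binary tracks return 0/1
#' membership; continuous tracks return the bin value, or `fill` in gaps or
#' outside the covered extent.
#'
#' @param track a [covariate_track()].
#' @param chrom chromosome name (scalar, or vector parallel to `pos`).
#' @param pos integer vector of 1-based positions.
#' @return numeric vector of values, one per position.
#' @export
track_values <- function(track, chrom, pos) {
  stopifnot(inherits(track, "covariate_track"))
  chrom <- harmonize_chrom(chrom)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos))
  out <- numeric(length(pos))
  fill <- if (track$kind == "binary") 0 else track$fill
  out[] <- fill
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    d <- track$data[[cn]]
    if (is.null(d) || nrow(d) == 0L) next
    z <- pos[sel] - 1L                       # 0-based
    idx <- findInterval(z, d$start)
    hit <- idx >= 1L & z < d$end[pmax(idx, 1L)]
    vals <- rep(fill, sum(sel))
    if (track$kind == "binary") {
      vals[hit] <- 1
    } else {
      vals[hit] <- d$value[idx[hit]]
    }
    out[sel] <- vals
  }
  out
}

#' Load a covariate track from bedGraph or BED
#'
#' Continuous tracks are read from bedGraph (0-based half-open, one value per
#' interval); binary tracks from BED. Unsorted input is sorted with a warning
#' and overlapping BED intervals are merged with a warning.
#'
#' @param path file path.
#' @param kind `"continuous"` (bedGraph) or `"binary"` (BED).
#' @param name feature name; defaults to the file stem.
#' @param fill gap-fill value for continuous tracks.
#' @return a [covariate_track()].
#' @export
load_track <- function(path, kind = c("continuous", "binary"), name = NULL,
                       fill = 0) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  name <- name %||% sub("\\.[^.]+$", "", basename(path))
  gr <- if (kind == "continuous") {
    rtracklayer::import(path, format = "bedGraph")
  } else {
    rtracklayer::import(path, format = "bed")
  }
  df <- data.frame(chrom = harmonize_chrom(as.character(GenomicRanges::seqnames(gr))),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  if (kind == "continuous") df$value <- gr$score
  data <- split(df[setdiff(names(df), "chrom")], df$chrom)
  covariate_track(name, kind, data, fill = fill)
}

#' Write a covariate track to bedGraph or BED
#'
#' @param track a [covariate_track()].
#' @param path output path (bedGraph for continuous, BED for binary).
#' @return the path, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "covariate_track"))
  rows <- lapply(names(track$data), function(cn) {
    d <- track$data[[cn]]
    cbind(data.frame(chrom = cn), d)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(start = df$start + 1L, end = df$end))
  if (track$kind == "continuous") {
    gr$score <- df$value
    rtracklayer::export(gr, path, format = "bedGraph")
  } else {
    gr$name <- track$name
    gr$score <- 0L
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

# extent (max covered end, 0-based) of a track on a chromosome
track_extent <- function(track, chrom) {
  d <- track$data[[harmonize_chrom(chrom)]]
  if (is.null(d) || nrow(d) == 0L) 0 else max(d$end)
}
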