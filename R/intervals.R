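# Low-level interval arithmetic on 0-based half-open [start, end) coordinates.
# All data frames carry at least chrom/start/end columns; coordinates are
# stored as doubles but treated as integers (bp).

#' Validate a chrom/start/end interval table
#'
#' @param x data.frame with columns `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `x`, invisibly.
#' @keywords internal
iv_validate <- function(x, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$end > x$start))
  if (length(bad)) {
    stop(sprintf("%s: invalid coordinates (need 0 <= start < end) at row %d",
                 what, bad[1]), call. = FALSE)
  }
  invisible(x)
}

#' Interval lengths in bp
#' @param x interval data.frame.
#' @return numeric vector `end - start`.
#' @keywords internal
iv_length <- function(x) x$end - x$start

# Order rows by (chrom, start, end); chromosome order is plain lexicographic,
# which is stable and sufficient for the synthetic chromosome names used here.
iv_order <- function(x) order(x$chrom, x$start, x$end)

#' Merge overlapping or bookended intervals per chromosome
#'
#' Distance-0 merge: intervals that overlap by >= 1 bp or abut exactly are
#' collapsed into one. Returns both the merged intervals and, for each input
#' row, the index of the merged interval it belongs to.
#'
#' @param x interval data.frame.
#' @return list with `merged` (data.frame chrom/start/end, sorted) and
#'   `group` (integer vector, same length as `nrow(x)`, in input row order).
#' @keywords internal
iv_merge <- function(x) {
  if (nrow(x) == 0) {
    return(list(merged = data.frame(chrom = character(), start = numeric(),
                                    end = numeric()),
                group = integer()))
  }
  ord <- iv_order(x)
  chrom <- x$chrom[ord]; start <- x$start[ord]; end <- x$end[ord]
  n <- length(start)
  # map chromosomes onto disjoint coordinate blocks so a single 1-D sweep
  # (vectorized cummax) merges all chromosomes at once
  f <- match(chrom, unique(chrom))
  off <- (f - 1) * (max(end) + 1)
  ks <- start + off; ke <- end + off
  cme <- cummax(ke)
  new <- c(TRUE, ks[-1] > cme[-n])
  grp <- cumsum(new)
  first <- which(new)
  last <- c(first[-1] - 1L, n)
  merged <- data.frame(
    chrom = chrom[first],
    start = start[first],
    end   = cme[last] - off[first],
    row.names = NULL, stringsAsFactors = FALSE
  )
  group <- integer(n)
  group[ord] <- grp
  list(merged = merged, group = group)
}

#' Does each query interval overlap any subject interval?
#'
#' Overlap means >= 1 shared bp (bookended intervals do not overlap).
#'
#' @param query,subject interval data.frames.
#' @return logical vector, one entry per query row.
#' @keywords internal
iv_overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  su <- iv_merge(subject)$merged
  out <- rep(FALSE, nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    s <- su[su$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0) next
    # last subject interval with start <= query_end - 1, i.e. start < end_q
    idx <- findInterval(query$end[qi] - 1, s$start)
    hit <- idx >= 1 & s$end[pmax(idx, 1)] > query$start[qi]
    out[qi] <- hit
  }
  out
}

#' Total bp of intersection between two interval sets
#'
#' Computed on the unions of each set, so multiply-covered bases count once.
#' @keywords internal
iv_intersect_bp <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  ua <- iv_merge(a)$merged
  ub <- iv_merge(b)$merged
  both <- rbind(ua[c("chrom", "start", "end")], ub[c("chrom", "start", "end")])
  uu <- iv_merge(both)$merged
  sum(iv_length(ua)) + sum(iv_length(ub)) - sum(iv_length(uu))
}

#' Gap-free spans of a genome
#'
#' Splits each chromosome [0, length) at its assembly gaps and returns the
#' remaining placeable spans.
#'
#' @param genome a [genome()] object.
#' @return data.frame chrom/start/end of gap-free spans.
#' @keywords internal
gapfree_spans <- function(genome) {
  out <- list()
  gaps <- genome$gaps
  for (ch in names(genome$chrom_lengths)) {
    len <- genome$chrom_lengths[[ch]]
    g <- gaps[gaps$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) {
      out[[ch]] <- data.frame(chrom = ch, start = 0, end = len)
      next
    }
    g <- iv_merge(g)$merged
    starts <- c(0, g$end)
    ends <- c(g$start, len)
    keep <- ends > starts
    out[[ch]] <- data.frame(chrom = ch, start = starts[keep], end = ends[keep])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
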