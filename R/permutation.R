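# Genome-randomization null for CNVR-gene overlap statistics. Controls for
# interval size: permuted placements preserve CNVR lengths but not their
# position or chromosome of origin.

# Per-length valid start counts over gap-free spans, and uniform sampling of
# placements. A placement of length L in span [s, e) has e - s - L + 1 valid
# starts; the span is chosen with probability proportional to that count.
place_lengths <- function(lengths, spans) {
  span_len <- spans$end - spans$start
  nL <- length(lengths)
  # counts: nL x nspans matrix of valid start positions
  counts <- pmax(outer(-lengths, span_len, `+`) + 1, 0)
  tot <- rowSums(counts)
  if (any(tot == 0))
    stop(sprintf("interval of length %d exceeds every gap-free span",
                 lengths[which(tot == 0)[1]]), call. = FALSE)
  cum <- counts
  for (j in seq_len(ncol(counts))[-1]) cum[, j] <- cum[, j - 1] + counts[, j]
  u <- stats::runif(nL) * tot
  span_idx <- rowSums(u > cum) + 1L
  # uniform start within the chosen span
  prev <- ifelse(span_idx > 1, cum[cbind(seq_len(nL), pmax(span_idx - 1, 1))],
                 0)
  offset <- pmin(floor(u - prev),  # 0 .. count-1 (guard fp edge)
                 counts[cbind(seq_len(nL), span_idx)] - 1)
  start <- spans$start[span_idx] + offset
  data.frame(chrom = spans$chrom[span_idx], start = start,
             end = start + lengths, stringsAsFactors = FALSE)
}

#' Randomly place interval lengths across a genome
#'
#' Each interval is placed uniformly over all valid start positions across
#' all gap-free spans (chromosome chosen with probability proportional to
#' its number of valid starts). Placements are independent; placed intervals
#' may overlap each other but never overlap gaps.
#'
#' @param lengths numeric vector of interval lengths (bp).
#' @param genome a [genome()] object.
#' @param seed optional integer seed; omit to use the current RNG state.
#' @return data.frame chrom/start/end, one row per input length, in input
#'   order.
#' @export
random_placement <- function(lengths, genome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spans <- gapfree_spans(genome)
  place_lengths(lengths, spans)
}

# number of genes overlapping (>= 1 bp) the union of placed intervals
count_overlapping_genes <- function(placed, genes) {
  sum(iv_overlaps_any(genes, placed))
}

#' Permutation test of CNVR-gene overlap
#'
#' Observed statistic on the real CNVR placement versus a null built by
#' randomly re-placing the same CNVR lengths across the gap-free genome
#' `n_perm` times. Empirical upper-tail p-value with the plus-one
#' correction: p = (r + 1) / (n_perm + 1), r = #\{null >= observed\}.
#'
#' @param cnvrs interval data.frame (e.g. [build_cnvrs()] output).
#' @param genes gene intervals.
#' @param genome a [genome()] object.
#' @param statistic `"n_overlapping_genes"` (genes hit by >= 1 interval) or
#'   `"total_overlap_bp"` (bp of intersection between the two interval
#'   unions).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer RNG seed.
#' @return list of class `permutation_result`: statistic, observed,
#'   null_values, n_perm, p_emp.
#' @export
permutation_test <- function(cnvrs, genes, genome,
                             statistic = c("n_overlapping_genes",
                                           "total_overlap_bp"),
                             n_perm = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  stopifnot(n_perm >= 1)
  stat_fun <- switch(statistic,
    n_overlapping_genes = function(iv) count_overlapping_genes(iv, genes),
    total_overlap_bp = function(iv) iv_intersect_bp(iv, genes))
  observed <- stat_fun(cnvrs)
  set.seed(seed)
  spans <- gapfree_spans(genome)
  lens <- iv_length(cnvrs)
  null_values <- vapply(seq_len(n_perm), function(i) {
    stat_fun(place_lengths(lens, spans))
  }, numeric(1))
  r <- sum(null_values >= observed)
  structure(list(statistic = statistic, observed = observed,
                 null_values = null_values, n_perm = n_perm,
                 p_emp = (r + 1) / (n_perm + 1)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s: observed = %g, null mean = %g, p_emp = %g (%d permutations)\n",
              x$statistic, x$observed, mean(x$null_values), x$p_emp,
              x$n_perm))
  invisible(x)
}
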