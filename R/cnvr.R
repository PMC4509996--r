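# CNV regions: merge calls across individuals, presence spectra, partition
# by segmental-duplication overlap, and distribution comparisons.

#' Merge CNV calls across individuals into CNV regions
#'
#' A CNVR is a connected component of the call-overlap graph on one
#' chromosome: all calls that overlap (or abut; distance-0 merge) transitively
#' are collapsed, and the region borders are the outer coordinates of the
#' merged calls. Duplications and deletions merge together.
#'
#' @param callsets either a single `cnv_calls` data.frame (with `sample_id`
#'   column) or a named list of per-sample call data.frames.
#' @return data.frame of class `cnvr_set` with columns chrom, start, end,
#'   cnvr_id, n_carriers, carriers (comma-separated sample ids), sorted by
#'   (chrom, start). The member calls, annotated with `cnvr_id`, are attached
#'   as attribute `"calls"`.
#' @export
build_cnvrs <- function(callsets) {
  calls <- if (is.data.frame(callsets)) callsets else do.call(rbind, callsets)
  if (is.null(calls) || nrow(calls) == 0) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      cnvr_id = character(), n_carriers = integer(),
                      carriers = character(), stringsAsFactors = FALSE)
    attr(out, "calls") <- calls
    class(out) <- c("cnvr_set", "data.frame")
    return(out)
  }
  rownames(calls) <- NULL
  m <- iv_merge(calls)
  merged <- m$merged
  ids <- sprintf("cnvr_%05d", seq_len(nrow(merged)))
  carrier_list <- split(calls$sample_id, m$group)
  carriers <- vapply(carrier_list,
                     function(s) paste(sort(unique(s)), collapse = ","),
                     character(1))
  n_carriers <- vapply(carrier_list, function(s) length(unique(s)),
                       integer(1))
  out <- data.frame(chrom = merged$chrom, start = merged$start,
                    end = merged$end, cnvr_id = ids,
                    n_carriers = n_carriers[as.character(seq_len(nrow(merged)))],
                    carriers = carriers[as.character(seq_len(nrow(merged)))],
                    stringsAsFactors = FALSE)
  calls$cnvr_id <- ids[m$group]
  attr(out, "calls") <- calls
  class(out) <- c("cnvr_set", "data.frame")
  out
}

#' Presence spectrum of CNVRs across samples
#'
#' Histogram of the number of individuals carrying >= 1 call inside each
#' CNVR, plus the singleton fraction (carried by exactly one sample) and the
#' shared-by-all fraction.
#'
#' @param cnvrs a [build_cnvrs()] result.
#' @param sheet a [sample_sheet()].
#' @return list with `counts` (named integer vector over k = 1..N),
#'   `n_samples`, `n_cnvrs`, `singleton_fraction`, `shared_by_all_fraction`.
#' @export
presence_spectrum <- function(cnvrs, sheet) {
  n <- nrow(sheet)
  all_carriers <- unique(unlist(strsplit(cnvrs$carriers, ",", fixed = TRUE)))
  unknown <- setdiff(all_carriers, sheet$sample_id)
  if (length(unknown))
    stop("carrier(s) not in sample sheet: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  counts <- tabulate(cnvrs$n_carriers, nbins = n)
  names(counts) <- seq_len(n)
  list(counts = counts, n_samples = n, n_cnvrs = nrow(cnvrs),
       singleton_fraction = if (nrow(cnvrs)) counts[[1]] / nrow(cnvrs) else NA_real_,
       shared_by_all_fraction = if (nrow(cnvrs)) counts[[n]] / nrow(cnvrs) else NA_real_)
}

#' Partition CNVRs by segmental-duplication overlap
#'
#' A CNVR belongs to the SD-overlapping set iff it shares >= 1 bp with any
#' (pre-filtered, > 10 kb) segmental duplication.
#'
#' @param cnvrs a [build_cnvrs()] result.
#' @param sds data.frame chrom/start/end of large SDs.
#' @return list with `sd_overlapping` and `sd_nonoverlapping`, each a
#'   `cnvr_set` with its member calls subset accordingly.
#' @export
partition_by_sd <- function(cnvrs, sds) {
  hit <- iv_overlaps_any(cnvrs, sds)
  subset_cnvrs <- function(keep) {
    out <- cnvrs[keep, , drop = FALSE]
    calls <- attr(cnvrs, "calls")
    if (!is.null(calls))
      attr(out, "calls") <- calls[calls$cnvr_id %in% out$cnvr_id, ,
                                  drop = FALSE]
    class(out) <- c("cnvr_set", "data.frame")
    out
  }
  list(sd_overlapping = subset_cnvrs(hit),
       sd_nonoverlapping = subset_cnvrs(!hit))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic two-sample KS distribution.
#'
#' @param x,y nonempty numeric vectors.
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("ks_two_sample: empty sample", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Log2 haploid copy number with the 0.001 floor
#'
#' Converts a diploid copy number to log2(haploid copies); haploid values
#' below 0.001 (in particular absolute deletions, cn = 0) are floored at
#' 0.001 so all data are log2-transformable, producing the ~ -10 bin.
#'
#' @param cn_diploid nonnegative diploid copy number(s).
#' @return log2(max(cn_diploid / 2, 0.001)).
#' @export
cn_log2_haploid <- function(cn_diploid) {
  if (any(cn_diploid < 0)) stop("negative copy number", call. = FALSE)
  log2(pmax(cn_diploid / 2, 0.001))
}

#' Compare the SD-overlapping and SD-nonoverlapping CNVR sets
#'
#' Summaries are call-level (the member calls of each partition): length
#' median/mean, mean haploid copy number, presence spectra, and KS tests of
#' the length and log2-haploid-copy-number distributions.
#'
#' @param sd_overlapping,sd_nonoverlapping `cnvr_set`s from
#'   [partition_by_sd()].
#' @param sheet optional [sample_sheet()] for presence spectra.
#' @return list of per-partition summaries plus `ks_length` and `ks_log2cn`
#'   (`NULL`, with `empty_partition = TRUE`, when a partition is empty).
#' @export
compare_partitions <- function(sd_overlapping, sd_nonoverlapping,
                               sheet = NULL) {
  summarize <- function(cnvrs) {
    calls <- attr(cnvrs, "calls")
    lens <- if (is.null(calls)) numeric() else iv_length(calls)
    cns <- if (is.null(calls)) numeric() else calls$cn
    list(n_cnvrs = nrow(cnvrs),
         n_calls = length(lens),
         median_length = if (length(lens)) stats::median(lens) else NA_real_,
         mean_length = if (length(lens)) mean(lens) else NA_real_,
         mean_haploid_cn = if (length(cns)) mean(cns / 2) else NA_real_,
         spectrum = if (!is.null(sheet) && nrow(cnvrs))
           presence_spectrum(cnvrs, sheet) else NULL)
  }
  s_sd <- summarize(sd_overlapping)
  s_no <- summarize(sd_nonoverlapping)
  empty <- s_sd$n_calls == 0 || s_no$n_calls == 0
  ks_len <- ks_cn <- NULL
  if (!empty) {
    calls_sd <- attr(sd_overlapping, "calls")
    calls_no <- attr(sd_nonoverlapping, "calls")
    ks_len <- ks_two_sample(iv_length(calls_sd), iv_length(calls_no))
    ks_cn <- ks_two_sample(cn_log2_haploid(calls_sd$cn),
                           cn_log2_haploid(calls_no$cn))
  }
  list(sd_overlapping = s_sd, sd_nonoverlapping = s_no,
       ks_length = ks_len, ks_log2cn = ks_cn, empty_partition = empty)
}
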