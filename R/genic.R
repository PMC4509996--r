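# CNV genes: whole-transcription-unit containment, per-individual gene copy
# number genotyping (length-weighted average over the gene body), high-copy
# genes, and the SD-association hypergeometric test.

#' Does a call fully contain a gene?
#'
#' Containment is closed at both ends on half-open intervals: call [a, b)
#' contains gene [c, d) iff a <= c and d <= b, on the same chromosome.
#'
#' @param call one-row `cnv_calls` data.frame (or list with chrom/start/end).
#' @param gene one-row gene data.frame (chrom/start/end).
#' @return logical.
#' @export
contains_gene <- function(call, gene) {
  call$chrom == gene$chrom && call$start <= gene$start && gene$end <= call$end
}

#' Find CNV genes: transcription units wholly inside a call of >= 1 sample
#'
#' The containment test is per call: a gene covered only by the union of two
#' abutting calls (neither alone containing it) is not a CNV gene, unless
#' `per_call = FALSE`, in which case containment is tested against the
#' merged per-sample call union.
#'
#' @param callsets named list of per-sample `cnv_calls` (or one data.frame).
#' @param genes data.frame chrom/start/end/gene_id.
#' @param per_call containment against individual calls (default) or against
#'   the per-sample merged call union.
#' @return the subset of `genes` contained in >= 1 call, each gene once, in
#'   (chrom, start) order.
#' @export
find_cnv_genes <- function(callsets, genes, per_call = TRUE) {
  calls <- if (is.data.frame(callsets)) callsets else do.call(rbind, callsets)
  if (is.null(calls) || nrow(calls) == 0 || nrow(genes) == 0)
    return(genes[0, , drop = FALSE])
  if (!per_call) {
    merged <- lapply(split(calls, calls$sample_id), function(cs) {
      m <- iv_merge(cs)$merged
      m$sample_id <- cs$sample_id[1]
      m
    })
    calls <- do.call(rbind, merged)
  }
  hit <- rep(FALSE, nrow(genes))
  for (ch in unique(calls$chrom)) {
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    gs <- genes$start[gi]; ge <- genes$end[gi]
    for (j in seq_len(nrow(cc))) {
      hit[gi] <- hit[gi] | (cc$start[j] <= gs & ge <= cc$end[j])
    }
  }
  out <- genes[hit, , drop = FALSE]
  out[iv_order(out), , drop = FALSE]
}

#' Genotype one gene in one sample
#'
#' Length-weighted average diploid copy number over the gene body: bases
#' under a call take the call's cn, all other bases take the sex-aware
#' baseline (2 on autosomes and female X, 1 on male X). Two same-sample
#' calls that overlap the gene on shared bases with different cn signal a
#' malformed callset and raise an error.
#'
#' @param gene one-row gene data.frame (chrom/start/end).
#' @param calls `cnv_calls` for one sample.
#' @param sex `"male"` or `"female"`.
#' @param sex_chrom name of the X chromosome.
#' @return diploid copy number (real >= 0).
#' @export
genotype_gene <- function(gene, calls, sex, sex_chrom = "chrX") {
  base <- cn_baseline(gene$chrom, sex, sex_chrom)
  glen <- gene$end - gene$start
  if (is.null(calls) || nrow(calls) == 0) return(base)
  ov <- calls$chrom == gene$chrom & calls$start < gene$end &
    calls$end > gene$start
  cc <- calls[ov, , drop = FALSE]
  if (nrow(cc) == 0) return(base)
  s <- pmax(cc$start, gene$start)
  e <- pmin(cc$end, gene$end)
  ord <- order(s, e)
  s <- s[ord]; e <- e[ord]; cn <- cc$cn[ord]
  # conflict check on clipped intervals (overlapping bases must agree on cn)
  if (length(s) > 1) {
    for (i in seq_len(length(s) - 1)) {
      later <- which(s[(i + 1):length(s)] < e[i]) + i
      if (any(cn[later] != cn[i]))
        stop(sprintf(
          "conflicting copy numbers from overlapping calls over gene %s",
          if (!is.null(gene$gene_id)) gene$gene_id else
            sprintf("%s:%d-%d", gene$chrom, gene$start, gene$end)),
          call. = FALSE)
    }
  }
  # disjointify; overlapping pieces have equal cn, so attribution is exact
  cur_end <- -Inf; covered <- 0; wsum <- 0
  for (i in seq_along(s)) {
    si <- max(s[i], cur_end)
    if (e[i] > si) {
      covered <- covered + (e[i] - si)
      wsum <- wsum + (e[i] - si) * cn[i]
    }
    cur_end <- max(cur_end, e[i])
  }
  (wsum + (glen - covered) * base) / glen
}

#' Build the genes x samples copy-number matrix
#'
#' @param callsets named list of per-sample `cnv_calls`.
#' @param genes gene data.frame (typically the [find_cnv_genes()] output).
#' @param sheet [sample_sheet()]; drives sex-aware baselines.
#' @param sex_chrom name of the X chromosome.
#' @return numeric matrix (genes x samples) of diploid copy numbers with
#'   rownames `gene_id` and colnames `sample_id`; the gene table is attached
#'   as attribute `"gene_info"`.
#' @export
build_cn_matrix <- function(callsets, genes, sheet, sex_chrom = "chrX") {
  samples <- sheet$sample_id
  m <- matrix(NA_real_, nrow = nrow(genes), ncol = length(samples),
              dimnames = list(genes$gene_id, samples))
  for (j in seq_along(samples)) {
    sid <- samples[j]
    sex <- sheet$sex[j]
    calls <- callsets[[sid]]
    base <- cn_baseline(genes$chrom, sex, sex_chrom)
    m[, j] <- base
    if (is.null(calls) || nrow(calls) == 0) next
    # only genes touched by a call need the weighted average
    touched <- iv_overlaps_any(genes, calls)
    for (i in which(touched)) {
      m[i, j] <- genotype_gene(genes[i, , drop = FALSE], calls, sex,
                               sex_chrom)
    }
  }
  attr(m, "gene_info") <- genes
  m
}

#' High copy number genes
#'
#' Genes whose grand mean diploid copy number across all samples reaches the
#' threshold (inclusive), with population-wise means.
#'
#' @param matrix copy-number matrix from [build_cn_matrix()].
#' @param sheet [sample_sheet()].
#' @param threshold grand-mean copies flagging a gene (default 10).
#' @return data.frame gene_id, mean_cn, then one `mean_<population>` column
#'   per population, sorted by decreasing mean_cn.
#' @export
high_copy_genes <- function(matrix, sheet, threshold = 10) {
  grand <- rowMeans(matrix)
  keep <- which(grand >= threshold)
  pops <- unique(sheet$population)
  out <- data.frame(gene_id = rownames(matrix)[keep],
                    mean_cn = unname(grand[keep]),
                    stringsAsFactors = FALSE)
  for (p in pops) {
    cols <- sheet$sample_id[sheet$population == p]
    out[[paste0("mean_", p)]] <-
      if (length(keep)) rowMeans(matrix[keep, cols, drop = FALSE]) else
        numeric(0)
  }
  out[order(-out$mean_cn, out$gene_id), , drop = FALSE]
}

#' Hypergeometric test of CNV gene association with segmental duplications
#'
#' Tests whether CNV genes overlap large SDs (>= 1 bp) more often than
#' expected from the full gene set: upper tail P(X >= k) under
#' hypergeometric(N, K, n).
#'
#' @param cnv_genes gene data.frame (subset of `all_genes`).
#' @param all_genes background gene data.frame.
#' @param sds large-SD intervals.
#' @return list with k (CNV genes on SDs), n (CNV genes), K (background
#'   genes on SDs), N (background genes), and `p`.
#' @export
sd_association <- function(cnv_genes, all_genes, sds) {
  n <- nrow(cnv_genes); N <- nrow(all_genes)
  if (n > N) stop("cnv_genes larger than background", call. = FALSE)
  k <- sum(iv_overlaps_any(cnv_genes, sds))
  K <- sum(iv_overlaps_any(all_genes, sds))
  if (k > K) stop("k > K: cnv_genes not a subset of all_genes?",
                  call. = FALSE)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, n = n, K = K, N = N, p = p)
}
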