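# Population differentiation of gene copy numbers: V_ST, deletion allele
# frequencies with X hemizygosity, ANOVA/FDR/Tukey divergence scan,
# standardization and nonmetric MDS.

# population variance (divisor n); gives v_st = 0 exactly for identical
# populations, which is the boundary behaviour we document and test
var_n <- function(v) mean((v - mean(v))^2)

#' Round to nearest integer, halves up
#'
#' Discretization rule for allele counting: 1.5 -> 2, 0.5 -> 1, 1.4 -> 1.
#' @param x numeric vector.
#' @return numeric vector of integers.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' V_ST differentiation statistic for one gene and one population pair
#'
#' V_ST = (V_T - V_S) / V_T, where V_T is the total variance of the pooled
#' copy numbers and V_S the sample-size-weighted mean within-population
#' variance. Variances use divisor n (see package vignette); negative values
#' are reported, not clipped, and V_T = 0 yields v_st = NA (undefined).
#'
#' @param x,y copy-number vectors for the two populations (each length >= 2).
#' @return list with `v_t`, `v_s`, `v_st`, `defined`.
#' @export
vst <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("vst: each population needs >= 2 samples", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  v_t <- var_n(c(x, y))
  v_s <- (n1 * var_n(x) + n2 * var_n(y)) / (n1 + n2)
  v_st <- if (v_t == 0) NA_real_ else (v_t - v_s) / v_t
  list(v_t = v_t, v_s = v_s, v_st = v_st, defined = v_t > 0)
}

#' Pairwise V_ST scan over a copy-number matrix
#'
#' One row per gene per unordered population pair (populations with >= 2
#' samples). The per-pair mean V_ST across genes (the quantity reported as
#' average pairwise differentiation) is attached as attribute
#' `"pair_means"`.
#'
#' @param matrix copy-number matrix (genes x samples).
#' @param sheet [sample_sheet()].
#' @return data.frame gene_id, pop1, pop2, v_t, v_s, v_st.
#' @export
vst_scan <- function(matrix, sheet) {
  pops <- unique(sheet$population)
  pops <- pops[vapply(pops, function(p) sum(sheet$population == p) >= 2,
                      logical(1))]
  if (length(pops) < 2)
    stop("vst_scan: need >= 2 populations with >= 2 samples", call. = FALSE)
  pairs <- utils::combn(pops, 2)
  res <- list()
  for (j in seq_len(ncol(pairs))) {
    p1 <- pairs[1, j]; p2 <- pairs[2, j]
    c1 <- sheet$sample_id[sheet$population == p1]
    c2 <- sheet$sample_id[sheet$population == p2]
    x <- matrix[, c1, drop = FALSE]
    y <- matrix[, c2, drop = FALSE]
    vs <- lapply(seq_len(nrow(matrix)),
                 function(i) vst(x[i, ], y[i, ]))
    res[[j]] <- data.frame(
      gene_id = rownames(matrix), pop1 = p1, pop2 = p2,
      v_t = vapply(vs, `[[`, numeric(1), "v_t"),
      v_s = vapply(vs, `[[`, numeric(1), "v_s"),
      v_st = vapply(vs, `[[`, numeric(1), "v_st"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  pm <- stats::aggregate(v_st ~ pop1 + pop2, data = out, FUN = mean,
                         na.rm = TRUE, na.action = stats::na.pass)
  attr(out, "pair_means") <- pm
  out
}

#' Deletion allele frequency for one gene
#'
#' Counts deletion alleles from integer-rounded copy numbers: on autosomes
#' and the female X each sample carries 2 alleles (CN 0 -> 2 deletion
#' alleles, CN 1 -> 1); on the male X each sample carries 1 allele (CN 0 ->
#' 1). Samples with integer CN >= 3 contribute all their alleles as
#' non-deletion: allelic configurations cannot be resolved there, so the
#' estimate is a lower bound.
#'
#' @param gene one-row gene data.frame (needs `chrom`; `gene_id` optional).
#' @param cn_row named numeric vector of diploid copy numbers per sample.
#' @param sheet [sample_sheet()].
#' @param sex_chrom name of the X chromosome.
#' @return list gene_id, n_alleles, n_del, freq.
#' @export
deletion_allele_frequency <- function(gene, cn_row, sheet,
                                      sex_chrom = "chrX") {
  if (length(cn_row) == 0) stop("empty copy-number row", call. = FALSE)
  cn <- round_half_up(cn_row[sheet$sample_id])
  hemi <- gene$chrom == sex_chrom & sheet$sex == "male"
  alleles <- ifelse(hemi, 1L, 2L)
  ndel <- ifelse(hemi,
                 as.integer(cn == 0),
                 ifelse(cn == 0, 2L, ifelse(cn == 1, 1L, 0L)))
  list(gene_id = if (!is.null(gene$gene_id)) gene$gene_id else NA_character_,
       n_alleles = sum(alleles), n_del = sum(ndel),
       freq = sum(ndel) / sum(alleles))
}

#' Deletion allele frequencies for all genes with a deletion carrier
#'
#' @param matrix copy-number matrix with `gene_info` attribute.
#' @param sheet [sample_sheet()].
#' @param sex_chrom name of the X chromosome.
#' @return data.frame gene_id, chrom, n_alleles, n_del, freq for every gene
#'   with >= 1 deletion allele counted.
#' @export
deletion_frequency_table <- function(matrix, sheet, sex_chrom = "chrX") {
  genes <- attr(matrix, "gene_info")
  rows <- lapply(seq_len(nrow(matrix)), function(i) {
    r <- deletion_allele_frequency(genes[i, , drop = FALSE], matrix[i, ],
                                   sheet, sex_chrom)
    data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
               n_alleles = r$n_alleles, n_del = r$n_del, freq = r$freq,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[out$n_del > 0, , drop = FALSE]
}

#' Genes lost per population (homozygous deletion in every member)
#'
#' A gene is lost in a population when every member has integer CN 0 (on the
#' male X, CN 0 against a baseline of 1 counts as loss). Also reports genes
#' homozygous-deleted in at least one and in more than one individual
#' overall.
#'
#' @inheritParams deletion_frequency_table
#' @return list with `per_population` (population -> gene_id vector),
#'   `deleted_in_any`, `deleted_in_multiple`.
#' @export
population_loss <- function(matrix, sheet, sex_chrom = "chrX") {
  cn <- round_half_up(matrix)
  zero <- cn == 0
  per_pop <- lapply(split(sheet$sample_id, sheet$population), function(ids) {
    rownames(matrix)[rowSums(!zero[, ids, drop = FALSE]) == 0]
  })
  n_zero <- rowSums(zero)
  list(per_population = per_pop,
       deleted_in_any = rownames(matrix)[n_zero >= 1],
       deleted_in_multiple = rownames(matrix)[n_zero > 1])
}

#' One-way ANOVA
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return list F, df_between, df_within, p. MSE = 0 with MSB > 0 gives
#'   F = Inf, p = 0; MSE = MSB = 0 gives F = NA (flagged undefined).
#' @export
anova_oneway <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  n <- lengths(groups)
  if (any(n < 2)) stop("each group needs >= 2 observations", call. = FALSE)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- k - 1; dfw <- N - k
  msb <- ssb / dfb; mse <- sse / dfw
  if (mse == 0) {
    if (msb == 0) return(list(F = NA_real_, df_between = dfb,
                              df_within = dfw, p = NA_real_))
    return(list(F = Inf, df_between = dfb, df_within = dfw, p = 0))
  }
  f <- msb / mse
  list(F = f, df_between = dfb, df_within = dfw,
       p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, clipped at 1, order-preserving with the input.
#' @param p probabilities in \[0, 1\] (NAs passed through).
#' @return adjusted values q, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Tukey HSD post hoc test
#'
#' All-pairs comparison via the studentized range distribution;
#' Tukey-Kramer for unequal group sizes. Requires within-group variance
#' (MSE > 0).
#'
#' @param groups named list of numeric vectors (>= 2 each).
#' @return data.frame group1, group2, mean_diff (absolute), q_statistic,
#'   p_adj.
#' @export
tukey_hsd <- function(groups) {
  a <- anova_oneway(groups)
  means <- vapply(groups, mean, numeric(1))
  n <- lengths(groups)
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  mse <- sse / a$df_within
  if (mse == 0) stop("tukey_hsd: MSE = 0, post hoc test undefined",
                     call. = FALSE)
  k <- length(groups)
  labs <- if (!is.null(names(groups))) names(groups) else
    as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  diffs <- abs(means[pairs[1, ]] - means[pairs[2, ]])
  se <- sqrt(mse / 2 * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]]))
  q <- diffs / se
  data.frame(group1 = labs[pairs[1, ]], group2 = labs[pairs[2, ]],
             mean_diff = unname(diffs), q_statistic = unname(q),
             p_adj = stats::ptukey(unname(q), nmeans = k, df = a$df_within,
                                   lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Population divergence scan: ANOVA -> BH FDR -> mean-difference filter ->
#' Tukey HSD
#'
#' Per gene: one-way ANOVA across populations; BH adjustment across all
#' scanned genes (once, not per pair); genes with q < `alpha` AND a maximum
#' pairwise population-mean difference >= `min_mean_diff` copies are
#' selected and receive Tukey HSD per-pair adjusted p-values. For genes with
#' zero within-population variance (F = Inf) the studentized range is
#' degenerate; per-pair p is set to 0 where the pair means differ and 1
#' where they are equal.
#'
#' @param matrix copy-number matrix (genes x samples).
#' @param sheet [sample_sheet()].
#' @param populations populations to scan; default all with >=
#'   `min_pop_size` samples.
#' @param alpha FDR level (default 0.05).
#' @param min_mean_diff minimum pairwise mean copy-number difference
#'   (default 1).
#' @param min_pop_size smallest population admitted to the scan (default 4;
#'   set to 2 to keep every testable population).
#' @return data.frame of class `scan_result`: gene_id, F, df_between,
#'   df_within, p, q, max_pair_mean_diff, selected, then one
#'   `tukey_<pop1>.<pop2>` column per pair (NA for unselected genes).
#' @export
divergence_scan <- function(matrix, sheet, populations = NULL, alpha = 0.05,
                            min_mean_diff = 1.0, min_pop_size = 4) {
  if (is.null(populations)) {
    tab <- table(sheet$population)
    populations <- names(tab)[tab >= max(2, min_pop_size)]
  }
  if (length(populations) < 2)
    stop("divergence_scan: need >= 2 populations", call. = FALSE)
  cols <- lapply(populations, function(p)
    sheet$sample_id[sheet$population == p])
  names(cols) <- populations
  ngene <- nrow(matrix)
  pairs <- utils::combn(populations, 2)
  pair_lab <- paste(pairs[1, ], pairs[2, ], sep = ".")
  Fv <- pv <- maxdiff <- rep(NA_real_, ngene)
  dfb <- dfw <- rep(NA_real_, ngene)
  groups_of <- function(i) lapply(cols, function(cs) matrix[i, cs])
  for (i in seq_len(ngene)) {
    g <- groups_of(i)
    a <- anova_oneway(g)
    Fv[i] <- a$F; pv[i] <- a$p; dfb[i] <- a$df_between; dfw[i] <- a$df_within
    means <- vapply(g, mean, numeric(1))
    maxdiff[i] <- max(abs(means[pairs[1, ]] - means[pairs[2, ]]))
  }
  qv <- bh_fdr(pv)
  selected <- !is.na(qv) & qv < alpha & maxdiff >= min_mean_diff
  tk <- matrix(NA_real_, nrow = ngene, ncol = ncol(pairs),
               dimnames = list(NULL, paste0("tukey_", pair_lab)))
  for (i in which(selected)) {
    g <- groups_of(i)
    means <- vapply(g, mean, numeric(1))
    if (is.infinite(Fv[i])) {
      d <- abs(means[pairs[1, ]] - means[pairs[2, ]])
      tk[i, ] <- ifelse(d > 0, 0, 1)
    } else {
      th <- tukey_hsd(g)
      tk[i, ] <- th$p_adj
    }
  }
  out <- data.frame(gene_id = rownames(matrix), F = Fv, df_between = dfb,
                    df_within = dfw, p = pv, q = qv,
                    max_pair_mean_diff = maxdiff, selected = selected,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(tk))
  attr(out, "populations") <- populations
  attr(out, "n_fdr_significant") <- sum(!is.na(qv) & qv < alpha)
  attr(out, "n_selected") <- sum(selected)
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Standardize a copy-number matrix gene-wise
#'
#' Per-gene z-score across samples (mean 0, divisor-n standard deviation 1).
#' Zero-variance genes carry no ordination information and are dropped with
#' a warning.
#'
#' @param matrix copy-number matrix (genes x samples).
#' @return standardized matrix (possibly fewer rows).
#' @export
standardize_matrix <- function(matrix) {
  mu <- rowMeans(matrix)
  sdn <- sqrt(rowMeans((matrix - mu)^2))
  drop <- sdn == 0
  if (any(drop))
    warning(sprintf("dropping %d zero-variance gene(s)", sum(drop)),
            call. = FALSE)
  m <- matrix[!drop, , drop = FALSE]
  (m - mu[!drop]) / sdn[!drop]
}

#' Nonmetric multidimensional scaling of samples
#'
#' Kruskal NMDS (stress-1, monotone regression) on Euclidean distances
#' between samples computed over genes, via [vegan::monoMDS()]. One
#' classical-scaling start plus `n_starts` random starts; the lowest-stress
#' configuration wins. Fully reproducible under `seed`.
#'
#' @param matrix standardized copy-number matrix (genes x samples), or a
#'   `dist` object over samples.
#' @param dims embedding dimension (default 2).
#' @param seed integer RNG seed.
#' @param n_starts number of random starts in addition to the classical
#'   start (default 8).
#' @param ties tie treatment in the monotone regression: `"secondary"`
#'   (default; tied dissimilarities keep tied disparities, so degenerate
#'   all-equal inputs have positive stress) or Kruskal's `"primary"`. The
#'   two are identical on tie-free Euclidean input.
#' @return list with `points` (samples x dims matrix) and `stress`
#'   (Kruskal stress-1, in \[0, 1\]).
#' @export
nmds <- function(matrix, dims = 2, seed = 1, n_starts = 8,
                 ties = c("secondary", "primary")) {
  ties <- match.arg(ties)
  d <- if (inherits(matrix, "dist")) matrix else stats::dist(t(matrix))
  n <- attr(d, "Size")
  if (n < 3) stop("nmds: need >= 3 samples", call. = FALSE)
  if (all(d == 0)) stop("nmds: all distances are zero", call. = FALSE)
  set.seed(seed)
  run <- function(init) vegan::monoMDS(d, y = init, k = dims,
                                       model = "global", itmax = 1000,
                                       weakties = (ties == "primary"),
                                       smin = 1e-7, sratmax = 0.9999999)
  init0 <- stats::cmdscale(d, k = dims)
  if (ncol(init0) < dims)  # degenerate configurations span fewer axes
    init0 <- cbind(init0, matrix(0, n, dims - ncol(init0)))
  best <- run(init0)
  for (r in seq_len(n_starts)) {
    init <- matrix(stats::rnorm(n * dims), n, dims)
    fit <- run(init)
    if (fit$stress < best$stress) best <- fit
  }
  pts <- best$points
  rownames(pts) <- labels(d)
  colnames(pts) <- paste0("dim", seq_len(dims))
  list(points = pts, stress = best$stress)
}
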