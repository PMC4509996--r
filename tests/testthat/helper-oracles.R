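# Independent oracles used against the package implementation. These are
# deliberately written with different algorithms (per-base expansion,
# event-based sweep, explicit sums, exhaustive enumeration) than the code
# they check.

# event-based sweep-line union: +1 at starts, -1 at ends, emit segments
# where coverage > 0
oracle_union <- function(iv) {
  out <- list()
  for (ch in sort(unique(iv$chrom))) {
    d <- iv[iv$chrom == ch, , drop = FALSE]
    ev <- rbind(data.frame(pos = d$start, delta = 1),
                data.frame(pos = d$end, delta = -1))
    ev <- ev[order(ev$pos, -ev$delta), ]  # starts before ends at same pos
    covg <- cumsum(ev$delta)
    opens <- which(covg > 0 & c(0, covg[-length(covg)]) == 0)
    closes <- which(covg == 0)
    out[[ch]] <- data.frame(chrom = ch, start = ev$pos[opens],
                            end = ev$pos[closes])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# carriers per union region by direct membership scan
oracle_carriers <- function(union_iv, calls) {
  vapply(seq_len(nrow(union_iv)), function(i) {
    hit <- calls$chrom == union_iv$chrom[i] &
      calls$start < union_iv$end[i] & calls$end > union_iv$start[i]
    paste(sort(unique(calls$sample_id[hit])), collapse = ",")
  }, character(1))
}

# per-base genotype average (genes small enough to expand)
oracle_genotype <- function(gene, calls, base) {
  v <- rep(base, gene$end - gene$start)
  pos <- seq(gene$start, gene$end - 1)
  for (i in seq_len(nrow(calls))) {
    if (calls$chrom[i] != gene$chrom) next
    sel <- pos >= calls$start[i] & pos < calls$end[i]
    v[sel] <- calls$cn[i]
  }
  mean(v)
}

# KS D by ECDF enumeration at all observed values
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

# V_ST from explicit sums (no var()/mean() reuse on the pooled path)
oracle_vst <- function(x, y) {
  pool <- c(x, y)
  m <- sum(pool) / length(pool)
  v_t <- sum((pool - m)^2) / length(pool)
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  vx <- sum((x - mx)^2) / length(x)
  vy <- sum((y - my)^2) / length(y)
  v_s <- (length(x) * vx + length(y) * vy) / length(pool)
  if (v_t == 0) NA_real_ else (v_t - v_s) / v_t
}

# hypergeometric upper tail by explicit enumeration of draw outcomes
oracle_hyper_upper <- function(N, K, n, k) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# deletion allele counting by per-sample enumeration
oracle_delfreq <- function(cn_int, is_male_x) {
  alleles <- del <- 0
  for (i in seq_along(cn_int)) {
    if (is_male_x[i]) {
      alleles <- alleles + 1
      if (cn_int[i] == 0) del <- del + 1
    } else {
      alleles <- alleles + 2
      if (cn_int[i] == 0) del <- del + 2
      else if (cn_int[i] == 1) del <- del + 1
    }
  }
  list(n_alleles = alleles, n_del = del, freq = del / alleles)
}

# random call collection on a small multi-chromosome genome
random_calls <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                         samples = paste0("s", 1:4)) {
  start <- sample(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample(500, n, replace = TRUE),
             call_type = sample(c("duplication", "deletion"), n,
                                replace = TRUE),
             cn = round(stats::runif(n, 0, 6), 2),
             sample_id = sample(samples, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# minimal sheet builders
mk_sheet <- function(pops, sexes = NULL) {
  n <- sum(lengths(pops))
  ids <- unlist(lapply(names(pops), function(p)
    paste0(p, "_", seq_along(pops[[p]]))))
  df <- data.frame(sample_id = ids,
                   population = rep(names(pops), lengths(pops)),
                   sex = if (is.null(sexes)) "male" else sexes,
                   stringsAsFactors = FALSE)
  sample_sheet(df)
}

# matrix from a named list of gene rows (gene_id -> named cn vector)
mk_matrix <- function(rows, genes_chrom = NULL) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  info <- data.frame(chrom = if (is.null(genes_chrom)) "chr1" else
    genes_chrom, start = seq_along(rows) * 1000,
    end = seq_along(rows) * 1000 + 500, gene_id = names(rows),
    stringsAsFactors = FALSE)
  attr(m, "gene_info") <- info
  m
}

# small fast simulation config for tests
small_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_autosomes = 1, chrom_length = 8e6,
             n_genes = 400, n_sd_blocks = 15, n_sd_cnvrs = 10,
             nonsd_rate = 40, n_divergent_genes = 8, n_deletion_genes = 10,
             n_high_copy_genes = 3, ...)
}
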