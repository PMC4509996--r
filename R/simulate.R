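# Seeded generator of population-structured CNV call sets. The stated world:
# four populations of unequal size (8/8/8/3, the small island-like one
# containing both females), a few large synthetic autosomes plus an X with
# male hemizygosity, SD-associated high-frequency large CNVs versus mostly
# rare small deletions elsewhere, segregating whole-gene deletion alleles,
# a minority of very-high-copy genes, and per-gene population mean shifts.

#' Simulation configuration
#'
#' Defaults mirror the shape of a wild-mouse resequencing study: 4
#' populations (8 + 8 + 8 + 3 animals, the 3-animal one containing the two
#' females), 3 synthetic autosomes of 25 Mb plus an X, ~2000 transcription
#' units, ~50 segmental-duplication blocks. Call-length and copy-number
#' distributions target the empirical medians of SD-associated versus other
#' CNVs (about 10.7 kb at a mean of ~1.27 haploid copies versus 3.8 kb at
#' ~0.67 haploid copies, deletion-biased).
#'
#' @param seed integer RNG seed.
#' @param n_autosomes,chrom_length,include_x genome shape.
#' @param populations named list: population -> list(n, males).
#' @param n_genes,gene_meanlog,gene_sdlog,gene_min_len log-normal gene
#'   lengths (bp) and how many transcription units to place.
#' @param n_gaps_per_chrom,gap_length assembly-gap planting.
#' @param n_sd_blocks,sd_meanlog,sd_sdlog segmental-duplication blocks (all
#'   kept > 10 kb).
#' @param n_sd_cnvrs,sd_cnvr_meanlog,sd_cnvr_sdlog,sd_carrier_shape1,sd_carrier_shape2,sd_dup_prob,sd_dup_cn,sd_del_cn
#'   SD-associated CNVR planting: carrier frequency ~ Beta(shape1, shape2)
#'   (U-shaped: many near-fixed and many rare regions), per-carrier call
#'   lengths log-normal, copy numbers a duplication-skewed mixture.
#' @param nonsd_rate,nonsd_meanlog,nonsd_sdlog,nonsd_del_prob,nonsd_del_cn,nonsd_dup_cn
#'   background (non-SD) calls: Poisson count per sample, small lengths,
#'   deletion-biased copy numbers.
#' @param n_divergent_genes,mean_shift,within_sd planted population
#'   mean-copy-number shifts (diploid copies) with within-population
#'   Gaussian spread.
#' @param n_deletion_genes,del_freq_range planted segregating whole-gene
#'   deletions, Hardy-Weinberg at a per-population frequency drawn uniform
#'   from `del_freq_range`.
#' @param n_high_copy_genes,high_copy_range planted high-copy genes:
#'   per-population mean copies drawn uniform from `high_copy_range`.
#' @param noise_sd Gaussian genotyping noise (diploid copies, truncated at
#'   0) added to every emitted call cn.
#' @param jitter breakpoint jitter in bp: planted calls extend 0..jitter bp
#'   beyond each gene end, exercising containment edge cases.
#' @param min_call_len minimum emitted call length.
#' @param plant_filter_fodder also emit one sub-1-kb call and one
#'   gap-overlapping call (for filter tests); default off.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_autosomes = 3, chrom_length = 25e6,
                       include_x = TRUE,
                       populations = list(
                         FRA = list(n = 8, males = 8),
                         GER = list(n = 8, males = 8),
                         IRA = list(n = 8, males = 8),
                         HEL = list(n = 3, males = 1)),
                       n_genes = 2000, gene_meanlog = log(8000),
                       gene_sdlog = 0.6, gene_min_len = 300,
                       n_gaps_per_chrom = 2, gap_length = 50000,
                       n_sd_blocks = 50, sd_meanlog = log(22000),
                       sd_sdlog = 0.5,
                       n_sd_cnvrs = 40, sd_cnvr_meanlog = log(10700),
                       sd_cnvr_sdlog = 0.8,
                       sd_carrier_shape1 = 0.6, sd_carrier_shape2 = 0.6,
                       sd_dup_prob = 0.55, sd_dup_cn = c(3, 5),
                       sd_del_cn = c(0, 1.5),
                       nonsd_rate = 150, nonsd_meanlog = log(3800),
                       nonsd_sdlog = 0.7, nonsd_del_prob = 0.8,
                       nonsd_del_cn = c(0, 1.475),
                       nonsd_dup_cn = c(3, 4.5),
                       n_divergent_genes = 30, mean_shift = 3,
                       within_sd = 0.5,
                       n_deletion_genes = 40, del_freq_range = c(0.05, 0.6),
                       n_high_copy_genes = 8, high_copy_range = c(10, 40),
                       noise_sd = 0.2, jitter = 200, min_call_len = 1000,
                       plant_filter_fodder = FALSE) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_autosomes >= 1, chrom_length > 0, n_genes >= 0,
              n_sd_blocks >= 0, n_sd_cnvrs <= max(n_sd_blocks, 0),
              all(unlist(del_freq_range) >= 0),
              all(unlist(del_freq_range) <= 1),
              noise_sd >= 0, jitter >= 0)
  })
  if (cfg$n_divergent_genes + cfg$n_deletion_genes + cfg$n_high_copy_genes >
        cfg$n_genes)
    stop("infeasible config: more planted genes than n_genes", call. = FALSE)
  for (p in names(cfg$populations)) {
    pp <- cfg$populations[[p]]
    if (pp$males > pp$n) stop("infeasible config: males > n in ", p,
                              call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Plant a segregating whole-gene deletion under Hardy-Weinberg
#'
#' Draws integer copy-number genotypes for one gene: autosomes and the
#' female X draw two alleles (CN = 2 - #deletion alleles), the male X draws
#' one (CN in \{0, 1\}). Uses the current RNG state.
#'
#' @param gene one-row gene data.frame (needs `chrom`).
#' @param pop_freqs named numeric vector/list: population -> deletion allele
#'   frequency in \[0, 1\].
#' @param sheet [sample_sheet()].
#' @param sex_chrom name of the X chromosome.
#' @return named integer vector of CN genotypes per sample.
#' @export
plant_deletion_gene <- function(gene, pop_freqs, sheet,
                                sex_chrom = "chrX") {
  freqs <- unlist(pop_freqs)[sheet$population]
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must be in [0, 1]",
                                       call. = FALSE)
  n_alleles <- ifelse(gene$chrom == sex_chrom & sheet$sex == "male", 1L, 2L)
  del <- stats::rbinom(nrow(sheet), n_alleles, freqs)
  cn <- n_alleles - del
  names(cn) <- sheet$sample_id
  cn
}

# place m non-overlapping lengths in [lo, hi) with >= minsp spacing via
# stick breaking; drops lengths that do not fit
place_in_span <- function(lengths, lo, hi, minsp) {
  m <- length(lengths)
  while (m > 0 && sum(lengths[seq_len(m)]) + (m - 1) * minsp > hi - lo)
    m <- m - 1
  if (m == 0) return(numeric(0))
  l <- lengths[seq_len(m)]
  extra <- (hi - lo) - sum(l) - (m - 1) * minsp
  cuts <- sort(floor(stats::runif(m, 0, extra + 1)))
  lo + cuts + cumsum(c(0, l[-m] + minsp))
}

#' Generate a complete synthetic CNV study
#'
#' Deterministic under `config$seed`. Returns the genome (with gaps), gene
#' and SD annotations, the sample sheet, per-sample CNV call sets in the
#' package's TSV dialect, and a truth table recording every planted feature.
#'
#' @param config a [sim_config()].
#' @return list of class `cnv_simulation`: genome, genes, sds, sheet,
#'   callsets (named list of `cnv_calls`), truth (long data.frame: feature,
#'   id, key, value), config.
#' @export
simulate_cnv_data <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- config

  # genome and gaps -----------------------------------------------------
  chroms <- paste0("chr", seq_len(cf$n_autosomes))
  if (cf$include_x) chroms <- c(chroms, "chrX")
  chrom_lengths <- stats::setNames(rep(cf$chrom_length, length(chroms)),
                                   chroms)
  gaps <- do.call(rbind, lapply(chroms, function(ch) {
    k <- cf$n_gaps_per_chrom
    if (k == 0) return(NULL)
    anchors <- cf$chrom_length * seq_len(k) / (k + 1) +
      floor(stats::runif(k, -0.04, 0.04) * cf$chrom_length)
    data.frame(chrom = ch, start = anchors,
               end = anchors + cf$gap_length, stringsAsFactors = FALSE)
  }))
  if (is.null(gaps))
    gaps <- data.frame(chrom = character(), start = numeric(),
                       end = numeric())
  gen <- genome(chrom_lengths, sex_chrom = "chrX", gaps = gaps)

  # sample sheet ---------------------------------------------------------
  sheet <- do.call(rbind, lapply(names(cf$populations), function(p) {
    pp <- cf$populations[[p]]
    data.frame(sample_id = sprintf("%s_%02d", p, seq_len(pp$n)),
               population = p,
               sex = rep(c("male", "female"), c(pp$males, pp$n - pp$males)),
               stringsAsFactors = FALSE)
  }))
  sheet <- sample_sheet(sheet)

  # genes ----------------------------------------------------------------
  margin <- cf$jitter + 100
  spans <- gapfree_spans(gen)
  spans$start <- spans$start + margin
  spans$end <- spans$end - margin
  spans <- spans[spans$end > spans$start, , drop = FALSE]
  span_len <- spans$end - spans$start
  n_per_span <- floor(cf$n_genes * span_len / sum(span_len))
  gene_rows <- list()
  minsp <- 2 * cf$jitter + 50  # planted calls of adjacent genes never touch
  for (i in seq_len(nrow(spans))) {
    m <- n_per_span[i]
    if (m == 0) next
    lens <- pmin(pmax(floor(stats::rlnorm(m, cf$gene_meanlog,
                                          cf$gene_sdlog)),
                      cf$gene_min_len), 100000)
    starts <- place_in_span(lens, spans$start[i], spans$end[i], minsp)
    if (!length(starts)) next
    gene_rows[[length(gene_rows) + 1]] <-
      data.frame(chrom = spans$chrom[i], start = starts,
                 end = starts + lens[seq_along(starts)],
                 stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  genes <- genes[iv_order(genes), , drop = FALSE]
  genes$gene_id <- sprintf("gene_%05d", seq_len(nrow(genes)))
  rownames(genes) <- NULL

  # segmental duplications -----------------------------------------------
  sd_lens <- pmax(floor(stats::rlnorm(cf$n_sd_blocks, cf$sd_meanlog,
                                      cf$sd_sdlog)), 10001)
  sds <- place_lengths(sd_lens, gapfree_spans(gen))

  # planted gene selection ------------------------------------------------
  sd_zone <- sds
  sd_zone$start <- pmax(sd_zone$start - 210000, 0)
  sd_zone$end <- sd_zone$end + 210000
  eligible <- which(iv_length(genes) >= cf$min_call_len &
                      !iv_overlaps_any(genes, sd_zone))
  auto_eligible <- eligible[genes$chrom[eligible] != "chrX"]
  need_auto <- cf$n_divergent_genes + cf$n_high_copy_genes
  if (length(auto_eligible) < need_auto ||
        length(eligible) < need_auto + cf$n_deletion_genes)
    stop("infeasible config: not enough eligible genes to plant",
         call. = FALSE)
  div_idx <- sample(auto_eligible, cf$n_divergent_genes)
  hc_idx <- sample(setdiff(auto_eligible, div_idx), cf$n_high_copy_genes)
  del_idx <- sample(setdiff(eligible, c(div_idx, hc_idx)),
                    cf$n_deletion_genes)

  truth <- list()
  note <- function(feature, id, key, value)
    truth[[length(truth) + 1]] <<- data.frame(
      feature = feature, id = id, key = key, value = as.character(value),
      stringsAsFactors = FALSE)

  calls <- stats::setNames(
    lapply(sheet$sample_id, function(s) list()), sheet$sample_id)
  add_call <- function(sid, chrom, start, end, type, cn)
    calls[[sid]][[length(calls[[sid]]) + 1]] <<- data.frame(
      chrom = chrom, start = start, end = end, call_type = type, cn = cn,
      sample_id = sid, stringsAsFactors = FALSE)
  gene_call <- function(sid, g, cn, type) {
    s <- g$start - floor(stats::runif(1, 0, cf$jitter + 1))
    e <- g$end + floor(stats::runif(1, 0, cf$jitter + 1))
    add_call(sid, g$chrom, s, e, type, cn)
  }

  # divergent genes: one scan-eligible population shifted by mean_shift
  scan_pops <- names(cf$populations)[
    vapply(cf$populations, function(pp) pp$n >= 4, logical(1))]
  for (i in div_idx) {
    g <- genes[i, ]
    pop <- sample(scan_pops, 1)
    note("divergent", g$gene_id, "shifted_pop", pop)
    for (p in names(cf$populations))
      note("divergent", g$gene_id, paste0("mean_", p),
           2 + if (p == pop) cf$mean_shift else 0)
    for (j in which(sheet$population == pop)) {
      cn <- max(0, 2 + cf$mean_shift + stats::rnorm(1, 0, cf$within_sd))
      gene_call(sheet$sample_id[j], g, cn,
                if (cn >= 2) "duplication" else "deletion")
    }
  }

  # segregating whole-gene deletions under Hardy-Weinberg
  for (i in del_idx) {
    g <- genes[i, ]
    freqs <- stats::setNames(
      stats::runif(length(cf$populations), cf$del_freq_range[1],
                   cf$del_freq_range[2]), names(cf$populations))
    cn <- plant_deletion_gene(g, freqs, sheet)
    for (p in names(freqs))
      note("deletion", g$gene_id, paste0("freq_", p), freqs[[p]])
    for (j in seq_len(nrow(sheet))) {
      b <- cn_baseline(g$chrom, sheet$sex[j])
      if (cn[j] < b)
        gene_call(sheet$sample_id[j], g, cn[j], "deletion")
    }
  }

  # high-copy genes: every sample amplified around a per-population mean
  for (i in hc_idx) {
    g <- genes[i, ]
    pm <- stats::setNames(
      stats::runif(length(cf$populations), cf$high_copy_range[1],
                   cf$high_copy_range[2]), names(cf$populations))
    for (p in names(pm))
      note("high_copy", g$gene_id, paste0("mean_", p), pm[[p]])
    for (j in seq_len(nrow(sheet)))
      gene_call(sheet$sample_id[j], g, pm[[sheet$population[j]]],
                "duplication")
  }

  # SD-associated CNVRs: shared large events anchored on SD blocks
  anchors <- sample(seq_len(nrow(sds)), cf$n_sd_cnvrs)
  spans_all <- gapfree_spans(gen)
  for (a in seq_along(anchors)) {
    sd <- sds[anchors[a], ]
    sp <- spans_all[spans_all$chrom == sd$chrom &
                      spans_all$start <= sd$start &
                      spans_all$end >= sd$end, ][1, ]
    freq <- stats::rbeta(1, cf$sd_carrier_shape1, cf$sd_carrier_shape2)
    carriers <- sheet$sample_id[stats::runif(nrow(sheet)) < freq]
    if (!length(carriers)) carriers <- sample(sheet$sample_id, 1)
    note("sd_cnvr", sprintf("sdcnvr_%02d", a), "chrom", sd$chrom)
    note("sd_cnvr", sprintf("sdcnvr_%02d", a), "start", sd$start)
    note("sd_cnvr", sprintf("sdcnvr_%02d", a), "end", sd$end)
    note("sd_cnvr", sprintf("sdcnvr_%02d", a), "carriers",
         paste(sort(carriers), collapse = ","))
    for (sid in carriers) {
      L <- min(max(floor(stats::rlnorm(1, cf$sd_cnvr_meanlog,
                                       cf$sd_cnvr_sdlog)),
                   cf$min_call_len), 200000)
      lo <- max(sp$start, sd$start - L + 1)
      hi <- min(sd$end - 1, sp$end - L)
      if (hi < lo) { lo <- sd$start; L <- min(L, sp$end - sd$start) }
      s <- floor(stats::runif(1, lo, max(lo, hi) + 1))
      dup <- stats::runif(1) < cf$sd_dup_prob
      cn <- if (dup) stats::runif(1, cf$sd_dup_cn[1], cf$sd_dup_cn[2]) else
        stats::runif(1, cf$sd_del_cn[1], cf$sd_del_cn[2])
      sex <- sheet$sex[sheet$sample_id == sid]
      b <- cn_baseline(sd$chrom, sex)
      cn <- cn * b / 2  # hemizygous X scale for males
      add_call(sid, sd$chrom, s, s + L,
               if (dup) "duplication" else "deletion", cn)
    }
  }

  # background calls outside SDs: many, small, deletion-biased, mostly rare
  for (j in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[j]
    nb <- stats::rpois(1, cf$nonsd_rate)
    if (nb == 0) next
    lens <- pmax(floor(stats::rlnorm(nb, cf$nonsd_meanlog, cf$nonsd_sdlog)),
                 cf$min_call_len)
    placed <- place_lengths(lens, spans_all)
    del <- stats::runif(nb) < cf$nonsd_del_prob
    cn <- ifelse(del,
                 stats::runif(nb, cf$nonsd_del_cn[1], cf$nonsd_del_cn[2]),
                 stats::runif(nb, cf$nonsd_dup_cn[1], cf$nonsd_dup_cn[2]))
    b <- cn_baseline(placed$chrom, sheet$sex[j])
    cn <- cn * b / 2
    placed$call_type <- ifelse(del, "deletion", "duplication")
    placed$cn <- cn
    placed$sample_id <- sid
    calls[[sid]][[length(calls[[sid]]) + 1]] <- placed
  }

  # assemble, add genotyping noise, resolve same-sample overlap conflicts
  callsets <- lapply(sheet$sample_id, function(sid) {
    cs <- do.call(rbind, calls[[sid]])
    if (is.null(cs) || nrow(cs) == 0) {
      cs <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), call_type = character(),
                       cn = numeric(), sample_id = character(),
                       stringsAsFactors = FALSE)
      class(cs) <- c("cnv_calls", "data.frame")
      return(cs)
    }
    sex <- sheet$sex[sheet$sample_id == sid]
    b <- cn_baseline(cs$chrom, sex)
    if (cf$noise_sd > 0) {
      cs$cn <- pmax(0, cs$cn + stats::rnorm(nrow(cs), 0, cf$noise_sd))
      # keep type consistent with cn relative to baseline
      cs$cn <- ifelse(cs$call_type == "deletion",
                      pmin(cs$cn, b - 0.05), pmax(cs$cn, b + 0.05))
      cs$cn <- pmax(cs$cn, 0)
    }
    # priority pruning: planted calls first (input order), background last;
    # keep a call only if it overlaps no already-kept call of this sample
    keep <- logical(nrow(cs))
    kept <- cs[0, ]
    for (i in seq_len(nrow(cs))) {
      if (!any(iv_overlaps_any(cs[i, , drop = FALSE], kept))) {
        keep[i] <- TRUE
        kept <- rbind(kept, cs[i, , drop = FALSE])
      }
    }
    cs <- cs[keep, , drop = FALSE]
    cs <- cs[iv_order(cs), , drop = FALSE]
    rownames(cs) <- NULL
    class(cs) <- c("cnv_calls", "data.frame")
    cs
  })
  names(callsets) <- sheet$sample_id

  if (cf$plant_filter_fodder) {
    sid <- sheet$sample_id[1]
    fodder <- data.frame(
      chrom = chroms[1],
      start = c(1000, if (nrow(gaps)) gaps$start[1] - 500 else 2000),
      end = c(1500, if (nrow(gaps)) gaps$start[1] + 500 else 3500),
      call_type = "deletion", cn = 0.5, sample_id = sid,
      stringsAsFactors = FALSE)
    cs <- rbind(callsets[[sid]], fodder)
    cs <- cs[iv_order(cs), , drop = FALSE]
    rownames(cs) <- NULL
    class(cs) <- c("cnv_calls", "data.frame")
    callsets[[sid]] <- cs
  }

  truth <- do.call(rbind, truth)
  structure(list(genome = gen, genes = genes, sds = sds, sheet = sheet,
                 callsets = callsets, truth = truth, config = cf),
            class = "cnv_simulation")
}

#' Write a simulation to disk in the package's TSV dialects
#'
#' Emits chrom.sizes, gaps.bed, genes.bed, sds.bed, sample_sheet.tsv,
#' truth.tsv and one calls/<sample>.tsv per sample.
#'
#' @param sim a [simulate_cnv_data()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cnv_simulation"))
  dir.create(file.path(dir, "calls"), recursive = TRUE, showWarnings = FALSE)
  writeLines(sprintf("%s\t%d", names(sim$genome$chrom_lengths),
                     as.integer(sim$genome$chrom_lengths)),
             file.path(dir, "chrom.sizes"))
  write_table(sim$genome$gaps, file.path(dir, "gaps.bed"))
  write_table(sim$genes, file.path(dir, "genes.bed"))
  write_table(sim$sds, file.path(dir, "sds.bed"))
  write_table(as.data.frame(sim$sheet), file.path(dir, "sample_sheet.tsv"))
  write_table(sim$truth, file.path(dir, "truth.tsv"))
  for (sid in names(sim$callsets)) {
    cs <- sim$callsets[[sid]]
    write_table(cs[c("chrom", "start", "end", "call_type", "cn")],
                file.path(dir, "calls", paste0(sid, ".tsv")))
  }
  invisible(dir)
}

#' @export
print.cnv_simulation <- function(x, ...) {
  cat(sprintf(
    "<cnv_simulation> %d samples / %d populations, %d genes, %d SDs, %d calls (seed %d)\n",
    nrow(x$sheet), length(unique(x$sheet$population)), nrow(x$genes),
    nrow(x$sds), sum(vapply(x$callsets, nrow, integer(1))),
    x$config$seed))
  invisible(x)
}
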