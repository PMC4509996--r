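# V_ST, deletion allele frequencies, ANOVA/FDR/Tukey scan, NMDS

test_that("vst matches hand arithmetic and boundary cases", {
  # all variance between populations
  r <- vst(c(2, 2, 2, 2), c(4, 4, 4, 4))
  expect_equal(r$v_s, 0)
  expect_equal(r$v_t, 1)
  expect_equal(r$v_st, 1)
  # identical distributions, divisor-n variance
  expect_equal(vst(c(1, 3), c(1, 3))$v_st, 0)
  # hand-computed mixed case
  r <- vst(c(0, 1, 2), c(4, 5))
  expect_equal(r$v_s, 0.5)
  expect_equal(r$v_t, 3.44)
  expect_equal(r$v_st, (3.44 - 0.5) / 3.44, tolerance = 1e-12)
  # undefined when pooled variance is zero
  r <- vst(c(2, 2), c(2, 2))
  expect_true(is.na(r$v_st))
  expect_false(r$defined)
  expect_error(vst(1, c(1, 2)), ">= 2")
})

test_that("vst is shift-invariant and symmetric", {
  withr::with_seed(2, {
    for (rep in 1:20) {
      x <- rnorm(sample(2:10, 1), sd = 2)
      y <- rnorm(sample(2:10, 1), sd = 2)
      v <- vst(x, y)$v_st
      expect_equal(vst(x + 7.3, y + 7.3)$v_st, v, tolerance = 1e-9)
      expect_equal(vst(y, x)$v_st, v, tolerance = 1e-12)
      expect_lte(v, 1)
    }
  })
})

test_that("vst_scan runs per gene per pair and averages per pair", {
  sheet <- mk_sheet(list(A = 1:3, B = 1:3, C = 1:2))
  m <- mk_matrix(list(
    flat = rep(2, 8),
    shifted = c(2, 2, 2, 6, 6, 6, 2, 2),   # B shifted by +4, no within-var
    noisy = c(1, 2, 3, 2, 3, 4, 1, 3)))
  colnames(m) <- sheet$sample_id
  vs <- vst_scan(m, sheet)
  expect_equal(nrow(vs), 3 * 3)  # 3 genes x 3 pairs
  expect_true(all(is.na(vs$v_st[vs$gene_id == "flat"])))
  expect_equal(vs$v_st[vs$gene_id == "shifted" & vs$pop1 == "A" &
                         vs$pop2 == "B"], 1)
  expect_equal(vs$v_st[vs$gene_id == "shifted" & vs$pop1 == "B"], 1)
  expect_true(is.na(vs$v_st[vs$gene_id == "shifted" & vs$pop1 == "A" &
                              vs$pop2 == "C"]))
  # elementwise oracle on a random matrix
  withr::with_seed(14, {
    m2 <- matrix(rnorm(50 * 8, mean = 2), 50, 8,
                 dimnames = list(sprintf("g%02d", 1:50), sheet$sample_id))
    vs2 <- vst_scan(m2, sheet)
    for (i in sample(nrow(vs2), 20)) {
      x <- m2[vs2$gene_id[i], sheet$sample_id[sheet$population ==
                                                vs2$pop1[i]]]
      y <- m2[vs2$gene_id[i], sheet$sample_id[sheet$population ==
                                                vs2$pop2[i]]]
      expect_equal(vs2$v_st[i], oracle_vst(x, y), tolerance = 1e-12)
    }
    pm <- attr(vs2, "pair_means")
    ab <- vs2$v_st[vs2$pop1 == "A" & vs2$pop2 == "B"]
    expect_equal(pm$v_st[pm$pop1 == "A" & pm$pop2 == "B"], mean(ab))
  })
})

test_that("deletion_allele_frequency counts alleles with hemizygous X", {
  sheet8 <- mk_sheet(list(P = 1:8))
  cn <- c(0, 0, 1, 2, 2, 2, 2, 2)
  names(cn) <- sheet8$sample_id
  r <- deletion_allele_frequency(data.frame(chrom = "chr1"), cn, sheet8)
  expect_equal(r$n_alleles, 16)
  expect_equal(r$n_del, 5)
  expect_equal(r$freq, 0.3125)
  # all CN 2 -> 0
  cn2 <- stats::setNames(rep(2, 8), sheet8$sample_id)
  expect_equal(deletion_allele_frequency(data.frame(chrom = "chr1"), cn2,
                                         sheet8)$freq, 0)
  # X gene: males CN {0,1,1}, one female CN 1 -> (1+1)/(3+2)
  sheetX <- mk_sheet(list(P = 1:4),
                     sexes = c("male", "male", "male", "female"))
  cnx <- stats::setNames(c(0, 1, 1, 1), sheetX$sample_id)
  r <- deletion_allele_frequency(data.frame(chrom = "chrX"), cnx, sheetX)
  expect_equal(r$n_alleles, 5)
  expect_equal(r$n_del, 2)
  expect_equal(r$freq, 0.4)
  # CN >= 3 contributes non-deletion alleles (lower-bound rule)
  cn3 <- stats::setNames(c(0, 3, 4, 2, 2, 2, 2, 2), sheet8$sample_id)
  r <- deletion_allele_frequency(data.frame(chrom = "chr1"), cn3, sheet8)
  expect_equal(r$n_del, 2)
  expect_equal(r$n_alleles, 16)
  # rounding is half-up: 1.4 -> 1, 1.5 -> 2, 0.5 -> 1
  expect_equal(round_half_up(c(1.4, 1.5, 0.5, 2.5)), c(1, 2, 1, 3))
  expect_error(deletion_allele_frequency(data.frame(chrom = "chr1"),
                                         numeric(0), sheet8), "empty")
})

test_that("population_loss finds fully deleted genes per population", {
  sheet <- mk_sheet(list(A = 1:3, B = 1:2))
  m <- mk_matrix(list(
    lostA = c(0, 0, 0.2, 2, 2),      # rounds to 0 in all of A
    keptA = c(0, 0, 1, 2, 2),
    lostB = c(2, 2, 2, 0, 0),
    never = c(2, 2, 2, 2, 2)))
  colnames(m) <- sheet$sample_id
  loss <- population_loss(m, sheet)
  expect_equal(loss$per_population$A, "lostA")
  expect_equal(loss$per_population$B, "lostB")
  expect_setequal(loss$deleted_in_any, c("lostA", "keptA", "lostB"))
  expect_setequal(loss$deleted_in_multiple, c("lostA", "keptA", "lostB"))
  # brute-force recount on a random integer matrix
  withr::with_seed(8, {
    m2 <- matrix(sample(0:3, 40 * 5, TRUE, prob = c(.2, .2, .5, .1)), 40, 5,
                 dimnames = list(sprintf("g%02d", 1:40), sheet$sample_id))
    loss2 <- population_loss(m2, sheet)
    for (p in c("A", "B")) {
      ids <- sheet$sample_id[sheet$population == p]
      brute <- rownames(m2)[apply(m2[, ids] == 0, 1, all)]
      expect_setequal(loss2$per_population[[p]], brute)
    }
  })
})

test_that("anova_oneway matches hand-computed sums of squares", {
  r <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  r <- anova_oneway(list(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(r$F, 4)
  expect_equal(r$df_between, 2)
  expect_equal(r$df_within, 3)
  expect_equal(r$p, stats::pf(4, 2, 3, lower.tail = FALSE))
  # degenerate within-variance
  r <- anova_oneway(list(c(0, 0), c(1, 1)))
  expect_equal(r$F, Inf)
  expect_equal(r$p, 0)
  r <- anova_oneway(list(c(1, 1), c(1, 1)))
  expect_true(is.na(r$F))
  expect_error(anova_oneway(list(1, c(1, 2))), ">= 2")
})

test_that("bh_fdr reproduces the step-up recursion", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # hand recursion: q_(i) = min_{j >= i} min(1, p_(j) * m / j)
  withr::with_seed(4, {
    p <- runif(20)
    o <- order(p)
    q_hand <- numeric(20)
    q_sorted <- pmin(1, p[o] * 20 / seq_len(20))
    q_sorted <- rev(cummin(rev(q_sorted)))
    q_hand[o] <- q_sorted
    expect_equal(bh_fdr(p), q_hand)
  })
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
})

test_that("tukey_hsd computes the studentized range statistic", {
  g <- list(a = c(1, 2), b = c(2, 3), c = c(3, 4))
  th <- tukey_hsd(g)
  row <- th[th$group1 == "a" & th$group2 == "c", ]
  expect_equal(row$q_statistic, 4)
  expect_equal(row$p_adj,
               stats::ptukey(4, nmeans = 3, df = 3, lower.tail = FALSE))
  # identical means -> q = 0, p = 1
  th0 <- tukey_hsd(list(a = c(1, 2), b = c(1, 2)))
  expect_equal(th0$q_statistic, 0)
  expect_equal(th0$p_adj, 1)
  # p decreases as mean difference grows (fixed MSE, n)
  th2 <- tukey_hsd(list(a = c(1, 2), b = c(2, 3), c = c(5, 6)))
  expect_lt(th2$p_adj[th2$group1 == "a" & th2$group2 == "c"],
            th2$p_adj[th2$group1 == "a" & th2$group2 == "b"])
  expect_error(tukey_hsd(list(a = c(1, 1), b = c(2, 2))), "MSE")
})

test_that("divergence_scan chains ANOVA, BH, mean filter and Tukey", {
  sheet <- mk_sheet(list(A = 1:2, B = 1:2, C = 1:2))
  m <- mk_matrix(list(
    big = c(2, 2, 2, 2, 6, 6),        # C shifted by +4, zero within-var
    small = c(2, 2, 2, 2, 2.5, 2.5),  # shift 0.5: significant but filtered
    flat = c(2, 2, 2, 2, 2, 2)))
  colnames(m) <- sheet$sample_id
  sc <- divergence_scan(m, sheet, min_pop_size = 2)
  expect_s3_class(sc, "scan_result")
  big <- sc[sc$gene_id == "big", ]
  expect_true(big$selected)
  expect_equal(big$tukey_A.C, 0)
  expect_equal(big$tukey_B.C, 0)
  expect_equal(big$tukey_A.B, 1)
  small <- sc[sc$gene_id == "small", ]
  expect_lt(small$q, 0.05)
  expect_false(small$selected)          # mean-diff filter boundary
  expect_false(sc$selected[sc$gene_id == "flat"])
  # q >= p and the invariant selected => q < alpha & diff >= 1
  ok <- is.na(sc$q) | sc$q >= sc$p
  expect_true(all(ok))
  expect_true(all(!sc$selected | (sc$q < 0.05 &
                                    sc$max_pair_mean_diff >= 1)))
})

test_that("standardize_matrix z-scores rows and drops constants", {
  m <- mk_matrix(list(a = c(1, 3), b = c(5, 5)))
  colnames(m) <- c("s1", "s2")
  expect_warning(std <- standardize_matrix(m), "zero-variance")
  expect_equal(rownames(std), "a")
  expect_equal(unname(std["a", ]), c(-1, 1))
  withr::with_seed(5, {
    m2 <- matrix(rnorm(100), 10, 10)
    std2 <- standardize_matrix(m2)
    expect_equal(unname(rowMeans(std2)), rep(0, 10), tolerance = 1e-12)
    expect_equal(unname(sqrt(rowMeans(std2^2))), rep(1, 10),
                 tolerance = 1e-12)
  })
})

test_that("nmds embeds small configurations sensibly", {
  # 3 points always embed in the plane
  d3 <- stats::dist(matrix(c(0, 0, 3, 0, 0, 4), 3, 2, byrow = TRUE))
  fit <- nmds(d3, seed = 1)
  expect_lt(fit$stress, 1e-3)
  # 4 mutually equidistant points cannot
  d4 <- stats::as.dist(matrix(1, 4, 4) - diag(4))
  expect_gt(nmds(d4, seed = 1)$stress, 0)
  # degenerate input
  expect_error(nmds(stats::as.dist(matrix(0, 3, 3)), seed = 1),
               "zero")
  expect_error(nmds(stats::dist(matrix(1:2, 2, 1)), seed = 1), ">= 3")
})
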