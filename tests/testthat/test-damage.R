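test_that("region enrichment is the bp-weighted mean with uncovered bases as zero", {
  # constant track: enrichment equals the constant for any region length
  tr <- mutaset:::validate_signal_track(
    data.frame(chrom = "chr1", start = 0, end = 1000, value = 2.0))
  for (w in c(10, 100, 500)) {
    r <- region_enrichment(tr, data.frame(region_id = "r", chrom = "chr1",
                                          start = 0, end = w))
    expect_equal(r$enrichment, 2.0)
  }
  # region [0,10): half covered at 4.0 -> 2.0
  tr2 <- mutaset:::validate_signal_track(
    data.frame(chrom = "chr1", start = 0, end = 5, value = 4.0))
  r2 <- region_enrichment(tr2, data.frame(region_id = "r", chrom = "chr1",
                                          start = 0, end = 10))
  expect_equal(r2$enrichment, 2.0)
  # CDS union of two equal-width pieces at 1.0 and 3.0 -> 2.0
  tr3 <- mutaset:::validate_signal_track(
    data.frame(chrom = "chr1", start = c(0, 50), end = c(20, 70),
               value = c(1, 3)))
  r3 <- region_enrichment(tr3, data.frame(region_id = c("g", "g"),
                                          chrom = "chr1",
                                          start = c(0, 50),
                                          end = c(20, 70)))
  expect_equal(r3$enrichment, 2.0)
  expect_error(region_enrichment(tr3, data.frame(region_id = "z",
                                                 chrom = "chr1",
                                                 start = 5, end = 5)),
               "width")
})

test_that("region enrichment is invariant to splitting track intervals", {
  coarse <- mutaset:::validate_signal_track(
    data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 300),
               value = c(1.5, 0.5)))
  fine <- mutaset:::validate_signal_track(
    data.frame(chrom = "chr1", start = c(0, 40, 100, 180),
               end = c(40, 100, 180, 300), value = c(1.5, 1.5, 0.5, 0.5)))
  regions <- data.frame(region_id = c("a", "b"), chrom = "chr1",
                        start = c(10, 90), end = c(150, 260))
  expect_equal(region_enrichment(coarse, regions),
               region_enrichment(fine, regions))
})

test_that("one-way ANOVA matches the hand decomposition and t-squared identity", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  res <- one_way_anova(g)
  expect_equal(res$statistic, 3.0, tolerance = 1e-12)
  expect_equal(res$df, c(2, 6))
  expect_equal(res$p.value, pf(3, 2, 6, lower.tail = FALSE))
  # identical groups -> F = 0, p = 1
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  res0 <- one_way_anova(same)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)
  # two groups: F equals the square of the pooled-variance t statistic
  set.seed(20)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  f2 <- one_way_anova(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(f2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  # invariant to adding a constant
  shift <- one_way_anova(lapply(g, `+`, 100))
  expect_equal(shift$statistic, res$statistic)
})

test_that("pairwise contrasts use the pooled error variance with BH adjustment", {
  set.seed(21)
  g <- list(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10, 2))
  res <- pairwise_contrasts_fdr(g)
  expect_equal(nrow(res), 3L)
  # cross-check raw p-values against pairwise.t.test with pooled sd
  vals <- unlist(g); grp <- rep(names(g), lengths(g))
  ref <- pairwise.t.test(vals, grp, pool.sd = TRUE,
                         p.adjust.method = "none")$p.value
  expect_equal(res$p_value[res$group1 == "a" & res$group2 == "b"],
               ref["b", "a"], tolerance = 1e-12)
  expect_equal(res$p_value[res$group1 == "b" & res$group2 == "c"],
               ref["c", "b"], tolerance = 1e-12)
  expect_equal(res$p_adjusted, p.adjust(res$p_value, "BH"))
  # k = 2: single contrast, adjusted equals raw
  res2 <- pairwise_contrasts_fdr(g[1:2])
  expect_equal(nrow(res2), 1L)
  expect_equal(res2$p_adjusted, res2$p_value)
  # identical groups -> all adjusted p = 1
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_true(all(pairwise_contrasts_fdr(same)$p_adjusted == 1))
  # BH step-up arithmetic on a known triple
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
})

test_that("Kruskal-Wallis matches the hand rank computation", {
  g <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  res <- kruskal_wallis(g)
  expect_equal(res$statistic, 32 / 7, tolerance = 1e-6)  # 4.571429
  expect_equal(res$df, 2)
  expect_error(kruskal_wallis(list(a = c(2, 2), b = c(2, 2))), "tied")
  # invariant to strictly monotone transforms
  res_exp <- kruskal_wallis(lapply(g, exp))
  expect_equal(res_exp$statistic, res$statistic)
  res_shift <- kruskal_wallis(lapply(g, `+`, 5))
  expect_equal(res_shift$statistic, res$statistic)
})

test_that("Dunn's z matches a brute-force implementation with tie correction", {
  dunn_brute <- function(groups) {
    vals <- unlist(groups); grp <- rep(names(groups), lengths(groups))
    N <- length(vals); r <- rank(vals)
    ties <- table(vals)
    v0 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
    pairs <- combn(names(groups), 2)
    sapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      (mean(r[grp == a]) - mean(r[grp == b])) /
        sqrt(v0 * (1 / sum(grp == a) + 1 / sum(grp == b)))
    })
  }
  set.seed(22)
  g <- list(a = round(rnorm(8), 1), b = round(rnorm(9, 0.8), 1),
            c = round(rnorm(7, 1.6), 1))  # rounding induces ties
  res <- dunns_test(g)
  expect_equal(res$z, dunn_brute(g), tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pnorm(-abs(res$z)))
  # equal-mean-rank groups give z = 0, p = 1
  sym <- list(a = c(1, 4), b = c(2, 3))
  res_s <- dunns_test(sym)
  expect_equal(res_s$z, 0)
  expect_equal(res_s$p_value, 1)
  # bonferroni is 3x raw capped at 1; "none" leaves p untouched
  rb <- dunns_test(g, adjust = "bonferroni")
  rn <- dunns_test(g, adjust = "none")
  expect_equal(rb$p_adjusted, pmin(1, rn$p_value * 3))
  expect_equal(rn$p_adjusted, rn$p_value)
})

test_that("permutation-null rejection rate of the group tests is near alpha", {
  set.seed(23)
  vals <- rnorm(60)
  grp <- rep(c("a", "b", "c"), each = 20)
  n_perm <- 400
  rej_kw <- rej_f <- logical(n_perm)
  for (i in seq_len(n_perm)) {
    g <- split(vals, sample(grp))
    rej_kw[i] <- kruskal_wallis(g)$p.value < 0.05
    rej_f[i] <- one_way_anova(g)$p.value < 0.05
  }
  expect_gt(mean(rej_kw), 0.02)
  expect_lt(mean(rej_kw), 0.08)
  expect_gt(mean(rej_f), 0.02)
  expect_lt(mean(rej_f), 0.08)
})

test_that("per-set damage labelling pulls the right genes at both levels", {
  genes <- toy_gene_models(
    toy_gene("g1", "chr1", 101, 200, cds1 = list(c(121, 150)),
             symbol = "S1"),
    toy_gene("g2", "chr1", 301, 400, symbol = "S2"))
  tr <- mutaset:::validate_signal_track(
    data.frame(chrom = "chr1", start = c(100, 300), end = c(200, 400),
               value = c(2, 6)))
  sets <- list(ndd = "S1", other = "S2")
  d <- damage_by_set(tr, genes, sets, level = "gene")
  expect_equal(d$enrichment[d$gene_set == "ndd"], 2)
  expect_equal(d$enrichment[d$gene_set == "other"], 6)
  d_cds <- damage_by_set(tr, genes, sets, level = "cds")
  expect_equal(d_cds$gene_set, "ndd")  # g2 has no CDS
  expect_equal(d_cds$enrichment, 2)
})
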