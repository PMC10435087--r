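test_that("random null sets are uniform, reproducible and size-exact", {
  u300 <- paste0("g", 1:300)
  sets <- sample_null_sets(u300, n_sets = 5, set_size = 300, seed = 1)
  for (s in sets) expect_setequal(s, u300)

  expect_identical(sample_null_sets(u300, 10, 50, seed = 9),
                   sample_null_sets(u300, 10, 50, seed = 9))
  expect_error(sample_null_sets(paste0("g", 1:10), 5, 20), "smaller")

  # inclusion frequency ~ Binomial(n_sets, set_size/|universe|)
  u4 <- paste0("g", 1:4)
  sets <- sample_null_sets(u4, n_sets = 1000, set_size = 2, seed = 2)
  freq <- sapply(u4, function(g) mean(vapply(sets, function(s) g %in% s,
                                             logical(1))))
  se <- sqrt(0.5 * 0.5 / 1000)
  expect_true(all(abs(freq - 0.5) < 3 * se))
})

test_that("null rate is the mean per-set mutations per gene per subclone", {
  man <- toy_manifest("PAH", n_per = 3)
  genes <- paste0("g", 1:4)
  # set1 = {g1,g2} totals 4; set2 = {g3,g4} totals 8
  cnt <- toy_counts(rep(paste0("PAH_s", 1:3), times = c(2, 1, 1)),
                    c("g1", "g3", "g2", "g4"), c(1, 5, 3, 3))
  nm <- null_rate(cnt, list(c("g1", "g2"), c("g3", "g4")), "PAH", man,
                  genes)
  expect_equal(nm$per_set_rates, c(4, 8) / 6)
  expect_equal(nm$p0, 1.0)

  # no mutations in the class -> p0 = 0
  empty <- toy_counts(character(0), character(0), integer(0))
  expect_equal(null_rate(empty, list(c("g1", "g2")), "PAH", man,
                         genes)$p0, 0)
  # homogeneous counts c per gene per subclone -> p0 = c for any sets
  cnt_h <- toy_counts(rep(paste0("PAH_s", 1:3), each = 4),
                      rep(genes, 3), rep(2L, 12))
  sets <- sample_null_sets(genes, 20, 2, seed = 5)
  expect_equal(null_rate(cnt_h, sets, "PAH", man, genes)$p0, 2)
  # unknown class errors
  expect_error(null_rate(cnt, list(genes), "radiation", man, genes),
               "no subclones")
})

test_that("exact binomial p-values match enumeration, worked values and binom.test", {
  expect_equal(binomial_enrichment(0, 5, 0), 1.0)
  expect_equal(binomial_enrichment(7, 10, 0.5), 0.34375)
  expect_equal(binomial_enrichment(10, 10, 0.5), 0.001953125)

  # independent oracle: full pmf enumeration with the same tie tolerance
  enum_p <- function(x, n, p) {
    d <- dbinom(0:n, n, p)
    min(1, sum(d[d <= d[x + 1] * (1 + 1e-7)]))
  }
  set.seed(4)
  for (i in 1:60) {
    n <- sample(1:50, 1)
    x <- sample(0:n, 1)
    p0 <- sample(c(0.1, 0.3, 0.5, 0.9), 1)
    expect_equal(binomial_enrichment(x, n, p0), enum_p(x, n, p0),
                 tolerance = 1e-12)
    expect_equal(binomial_enrichment(x, n, p0),
                 stats::binom.test(x, n, p0)$p.value, tolerance = 1e-12)
  }
  # central (doubled one-tail) option
  expect_equal(binomial_enrichment(7, 10, 0.5, method = "central"),
               min(1, 2 * min(pbinom(7, 10, .5),
                              pbinom(6, 10, .5, lower.tail = FALSE))))
  expect_error(binomial_enrichment(1, 10, 1.2), "p0")
  # multiplicity beyond n -> Poisson fallback with warning
  expect_warning(p <- binomial_enrichment(12, 10, 0.5), "Poisson")
  expect_true(p > 0 && p < 1)
})

test_that("upper-tail contribution is monotone in the observed count", {
  n <- 40; p0 <- 0.2
  upper <- sapply(10:40, function(x) pbinom(x - 1, n, p0,
                                            lower.tail = FALSE))
  expect_true(all(diff(upper) <= 0))
  # and the reported p is non-increasing while observed/n > p0
  ps <- sapply(10:40, function(x) binomial_enrichment(x, n, p0))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("Monte-Carlo p follows the smaller-tail-times-two counting rule", {
  expect_equal(as.numeric(montecarlo_enrichment(10, 1:10)), 0.2)
  p <- montecarlo_enrichment(0, 1:1000)
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "below_resolution"))
  p1 <- montecarlo_enrichment(5, rep(5, 100))
  expect_equal(as.numeric(p1), 1.0)
  expect_false(attr(p1, "below_resolution"))
  expect_error(montecarlo_enrichment(1, numeric(0)), "empty")
})

test_that("table-wide Bonferroni thresholds behave as stated", {
  expect_false(bonferroni_significant(0.001, 120))
  expect_true(bonferroni_significant(1e-6, 120))
  expect_equal(bonferroni_significant(0.04, 1), TRUE)
  expect_equal(bonferroni_significant(0.06, 1), FALSE)
})

test_that("length-quartile stratification balances sizes with longest-first remainder", {
  lens <- setNames(seq_len(220) * 10, paste0("g", sprintf("%03d", 1:220)))
  q <- quartile_stratify(names(lens), lens)
  expect_equal(lengths(q), c(Q1 = 55L, Q2 = 55L, Q3 = 55L, Q4 = 55L))
  expect_true(min(lens[q$Q1]) >= max(lens[q$Q2]))

  lens10 <- setNames(c(100, 90, 80, 70, 60, 50, 40, 30, 20, 10),
                     paste0("g", 1:10))
  q10 <- quartile_stratify(names(lens10), lens10)
  expect_equal(unname(lengths(q10)), c(3L, 3L, 2L, 2L))
  expect_setequal(q10$Q1, c("g1", "g2", "g3"))

  # all-equal lengths: symbol order, still balanced
  lens_eq <- setNames(rep(5, 10), paste0("g", sprintf("%02d", 1:10)))
  q_eq <- quartile_stratify(names(lens_eq), lens_eq)
  expect_equal(q_eq$Q1, paste0("g", c("01", "02", "03")))
})

test_that("set-size sweep is flat per gene and linear per subclone", {
  # homogeneous rates: every gene has the same expected count
  man <- toy_manifest("PAH", n_per = 5)
  genes <- paste0("g", sprintf("%03d", 1:200))
  set.seed(8)
  cnt_rows <- expand.grid(subclone_id = man$subclone_id, gene_id = genes,
                          stringsAsFactors = FALSE)
  cnt <- toy_counts(cnt_rows$subclone_id, cnt_rows$gene_id,
                    rpois(nrow(cnt_rows), 0.4))
  sw <- setsize_sweep(cnt, genes, "PAH", man, sizes = seq(10, 100, 10),
                      n_sets = 400, seed = 3)
  expect_equal(sw$set_size, seq(10L, 100L, 10L))
  # per-gene-per-subclone curve flat within 3 SE of its mean
  dev <- abs(sw$mean_mutations_per_gene_per_subclone -
               mean(sw$mean_mutations_per_gene_per_subclone))
  expect_true(all(dev < 3 * pmax(sw$se_per_gene_per_subclone, 1e-12)))
  # per-subclone curve linear with slope ~ the per-gene rate
  slope <- coef(lm(mean_mutations_per_subclone ~ set_size, sw))[["set_size"]]
  rate <- mean(cnt$gene_count) * length(genes) /
    (length(genes) * 5)  # mutations per gene per subclone
  expect_equal(slope, mean(sw$mean_mutations_per_gene_per_subclone),
               tolerance = 0.05)
  # ratio of per-subclone means between sizes 100 and 10 ~ 10
  r <- sw$mean_mutations_per_subclone[10] / sw$mean_mutations_per_subclone[1]
  expect_equal(r, 10, tolerance = 0.1)
  # zero mutations -> both curves identically zero
  sw0 <- setsize_sweep(toy_counts(character(0), character(0), integer(0)),
                       genes, "PAH", man, sizes = c(10, 20), n_sets = 20,
                       seed = 1)
  expect_true(all(sw0$mean_mutations_per_subclone == 0))
  expect_true(all(sw0$mean_mutations_per_gene_per_subclone == 0))
})

test_that("enrichment table cells carry obs-exp, direction and markers", {
  cfg <- small_config(seed = 21)
  st <- simulate_study(cfg)
  e <- enrich_gene_sets(st$counts, st$genes, st$sets, st$manifest,
                        n_sets = 200, set_size = 40, seed = 5,
                        monte_carlo = TRUE)
  tab <- e$table
  expect_equal(nrow(tab), 3 * 3)  # 3 sets x 3 classes
  expect_equal(tab$obs_minus_exp, tab$observed - tab$expected)
  expect_equal(tab$direction == "more", tab$observed > tab$expected)
  expect_equal(e$m, 9)
  expect_true(all(tab$significant_bonferroni ==
                    (tab$p_binomial < 0.05 / 9)))
  expect_true(all(is.finite(tab$p_montecarlo)))
  # the delta = 2 set is the strongest signal in the most intense class
  ndd <- tab[tab$gene_set == "NDD_like" & tab$exposure_class == "radiation", ]
  expect_equal(ndd$direction, "more")
  expect_true(ndd$significant_bonferroni)
})

test_that("enrichment is reproducible under a fixed seed", {
  cfg <- small_config(seed = 22)
  st <- simulate_study(cfg)
  e1 <- enrich_gene_sets(st$counts, st$genes, st$sets, st$manifest,
                         n_sets = 100, set_size = 30, seed = 77)
  e2 <- enrich_gene_sets(st$counts, st$genes, st$sets, st$manifest,
                         n_sets = 100, set_size = 30, seed = 77)
  expect_identical(e1$table, e2$table)
})
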