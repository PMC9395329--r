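test_that("Mann-Whitney matches the exact-enumeration oracle", {
  # worked case: complete separation of {1,2,3} vs {4,5,6}
  res <- scan_one(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$test, "mann_whitney")
  expect_equal(res$p, 0.1)
  expect_equal(res$p, mw_exact_oracle(c(1, 2, 3), c(4, 5, 6)))

  # random small instances: exact branch equals the oracle
  set.seed(14)
  for (i in 1:10) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    v <- sample(100, n1 + n2)  # unique values, no ties
    p_pkg <- scan_one(v, rep(c("a", "b"), c(n1, n2)))$p
    expect_equal(p_pkg, mw_exact_oracle(v[1:n1], v[-(1:n1)]))
  }
})

test_that("normal approximation stays within 0.02 of the exact oracle", {
  set.seed(15)
  for (i in 1:10) {
    n1 <- sample(5:8, 1); n2 <- sample(5:8, 1)
    v <- sample(1000, n1 + n2)
    p_norm <- scan_one(v, rep(c("a", "b"), c(n1, n2)), exact_max = 0)$p
    p_exact <- mw_exact_oracle(v[1:n1], v[-(1:n1)])
    expect_lt(abs(p_norm - p_exact), 0.02)
  }
})

test_that("identical groups sit at the null center", {
  res <- scan_one(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3),
                  exact_max = 0)
  expect_equal(res$p, 1)
})

test_that("more than two groups dispatches to Kruskal-Wallis", {
  set.seed(16)
  res <- scan_one(rnorm(30), rep(c("a", "b", "c"), 10))
  expect_equal(res$test, "kruskal_wallis")
  expect_true(res$p > 0 && res$p <= 1)
})

test_that("undersized groups are skipped with a logged reason", {
  res <- scan_one(c(1, 2, 3, 4, 5), c("a", "a", "a", "a", "b"))
  expect_equal(nrow(res), 0)
  expect_match(attr(res, "skipped"), "group with <2")
})

test_that("Pearson scan reproduces hand-computed r and the t-transform p", {
  feats <- data.frame(sample_id = paste0("S", 1:5), f = 1:5)
  meta <- data.frame(sample_id = paste0("S", 1:5), y = 2 * (1:5) + 1)
  res <- pearson_scan(feats, meta, "y")
  expect_equal(res$statistic, 1)
  expect_lt(res$p, 1e-8)

  meta$y <- -(1:5)
  expect_equal(pearson_scan(feats, meta, "y")$statistic, -1)

  feats4 <- data.frame(sample_id = paste0("S", 1:4), f = c(1, 2, 3, 4))
  meta4 <- data.frame(sample_id = paste0("S", 1:4), y = c(2, 1, 4, 3))
  res4 <- pearson_scan(feats4, meta4, "y")
  expect_equal(res4$statistic, 0.6)
  t_stat <- 0.6 * sqrt(2) / sqrt(1 - 0.36)
  expect_equal(res4$p, 2 * pt(-abs(t_stat), df = 2))

  # zero variance is skipped, not an error
  feats4$f <- rep(1, 4)
  res0 <- pearson_scan(feats4, meta4, "y")
  expect_equal(nrow(res0), 0)
  expect_match(attr(res0, "skipped"), "zero variance")
})

test_that("categorical tests pick Fisher or chi-squared as specified", {
  # [[5,0],[0,5]] -> Fisher two-sided p = 2/252
  meta <- data.frame(a = rep(c("x", "y"), each = 5),
                     b = rep(c("u", "v"), each = 5))
  res <- categorical_test(meta, "a", "b")
  expect_equal(res$test, "fisher_exact")
  expect_equal(res$p, 2 / 252, tolerance = 1e-9)
  expect_equal(res$p, fisher_exact_oracle(table(meta$a, meta$b)),
               tolerance = 1e-9)

  # identical row distributions: chi-squared statistic 0, p 1
  meta2 <- data.frame(a = rep(c("x", "y"), each = 20),
                      b = rep(rep(c("u", "v"), each = 10), 2))
  res2 <- categorical_test(meta2, "a", "b")
  expect_equal(res2$test, "chi_squared")
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p, 1)

  expect_error(categorical_test(data.frame(a = rep("x", 4),
                                           b = c("u", "v", "u", "v")),
                                "a", "b"), "two levels")
})

test_that("p-value adjustment matches hand-applied BH and Bonferroni", {
  rec <- scan_one(rnorm(20), rep(c("a", "b"), 10))
  mk <- function(p) {
    r <- rec[rep(1, length(p)), ]
    r$p <- p
    r
  }
  bh <- adjust_pvalues(mk(c(0.01, 0.02, 0.03, 0.5)), "bh_fdr", 0.05)
  expect_equal(bh$adjusted_p, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh$adjusted_p, bh_oracle(c(0.01, 0.02, 0.03, 0.5)))
  expect_equal(sum(bh$significant), 3)

  bon <- adjust_pvalues(mk(rep(0.02, 10)), "bonferroni", 0.15)
  expect_equal(bon$adjusted_p, rep(0.2, 10))
  expect_false(any(bon$significant))

  single <- adjust_pvalues(mk(0.03), "bh_fdr")
  expect_equal(single$adjusted_p, 0.03)
  expect_equal(adjust_pvalues(mk(0.03), "bonferroni")$adjusted_p, 0.03)

  expect_error(adjust_pvalues(rec[0, ], "bh_fdr"), "empty")

  # monotone in raw p within a family
  set.seed(17)
  p <- runif(30)
  adj <- adjust_pvalues(mk(p), "bh_fdr")$adjusted_p
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("planted species reach BH significance with high power", {
  cat_ <- feature_catalog()
  eff <- list(effect_spec("motivation", c("SGB_01", "SGB_02"), 2))
  hits <- replicate(20, {
    coh <- generate_cohort(cat_, n_dogs = 100, effects = eff,
                           seed = sample.int(1e6, 1))
    feats <- data.frame(sample_id = coh$metadata$dog_id,
                        log(coh$truths), check.names = FALSE)
    meta <- coh$metadata
    meta$motivation_hi <- meta$motivation >= 3
    sc <- adjust_pvalues(rank_test_scan(feats, meta, "motivation_hi"),
                         "bh_fdr", 0.15)
    all(sc$significant[sc$feature %in% c("SGB_01", "SGB_02")])
  })
  expect_gte(mean(hits), 0.8)
})
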