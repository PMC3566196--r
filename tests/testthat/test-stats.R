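test_that("midrank transform handles order, ties and missing values", {
  expect_equal(rank_transform(c(3.1, 1.2, 2.0)), c(3, 1, 2))
  expect_equal(rank_transform(c(5, 5, 7)), c(1.5, 1.5, 3))
  x <- c(2.3, 9, 1, 4, 4, 7)
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(rank_transform(x[perm]), rank_transform(x)[perm])
  expect_equal(rank_transform(c(1, NA, 3)), c(1, NA, 2))
  expect_error(rank_transform(c(NA_real_, NA_real_)), "missing")
})

test_that("the rank LMM returns the exact null when pairs are identical", {
  d <- data.frame(group = rep(c("mTBI", "control"), each = 6),
                  pair_id = rep(1:6, 2),
                  y = rep(c(3.2, 5.1, 4.4, 7.7, 1.2, 6.3), 2))
  res <- paired_rank_lmm_test(d, "y")
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)
})

test_that("the rank LMM equals the paired t-test on rank differences", {
  # strong pair heterogeneity keeps the pair variance component interior
  set.seed(21)
  for (i in 1:5) {
    n <- 12
    pair_eff <- rnorm(n, sd = 30)
    d <- data.frame(group = rep(c("control", "mTBI"), each = n),
                    pair_id = rep(1:n, 2),
                    y = c(pair_eff + rnorm(n), pair_eff + 1.2 + rnorm(n)))
    res <- paired_rank_lmm_test(d, "y")
    r <- rank_transform(d$y)
    diffs <- r[d$group == "mTBI"] - r[d$group == "control"]
    tt <- t.test(diffs)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-6)
    expect_equal(abs(res$statistic), abs(unname(tt$statistic)),
                 tolerance = 1e-6)
  }
})

test_that("the rank LMM validates its design assumptions", {
  d <- data.frame(group = rep(c("mTBI", "control"), each = 3),
                  pair_id = c(1, 1, 2, 1, 2, 3), y = rnorm(6))
  expect_error(paired_rank_lmm_test(d, "y"), "at most one record")
  d2 <- data.frame(group = rep(c("mTBI", "control"), each = 2),
                   pair_id = rep(1:2, 2), y = rnorm(4))
  expect_error(paired_rank_lmm_test(d2, "y"), "complete pairs")
})

test_that("Mann-Whitney U matches hand-worked small cases", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$method, "exact")
  # identical multisets: perfect exchangeability
  expect_equal(mann_whitney_u(c(2, 2, 5, 7), c(2, 2, 5, 7))$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty input")
})

test_that("Mann-Whitney U agrees with enumeration and base wilcox.test", {
  set.seed(31)
  for (i in 1:25) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    a <- sample(1:10, na, replace = TRUE)
    b <- sample(1:10, nb, replace = TRUE) + sample(0:2, 1)
    res <- mann_whitney_u(a, b)
    expect_lt(abs(res$p_value - mwu_enum_p(a, b)), 0.02)
    if (!anyDuplicated(c(a, b))) {
      # tie-free: exact on both routes, and identical to wilcox.test
      expect_equal(res$p_value, mwu_enum_p(a, b), tolerance = 1e-12)
      w <- wilcox.test(a, b, exact = TRUE)
      expect_equal(res$statistic, unname(w$statistic))
      expect_equal(res$p_value, w$p.value, tolerance = 1e-12)
    }
  }
})

test_that("Mann-Whitney U is invariant under strictly monotone transforms", {
  set.seed(5)
  a <- rnorm(8); b <- rnorm(10) + 0.5
  f <- function(x) exp(2 * x) - 1
  r1 <- mann_whitney_u(a, b)
  r2 <- mann_whitney_u(f(a), f(b))
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("Spearman correlation handles monotone, tied and degenerate inputs", {
  x <- c(1, 2, 5, 9, 12)
  expect_equal(spearman_correlation(x, x^3 + 2)$statistic, 1)
  expect_equal(spearman_correlation(x, -sqrt(x))$statistic, -1)
  set.seed(6)
  xx <- sample(1:5, 30, replace = TRUE)
  yy <- xx + sample(1:4, 30, replace = TRUE)
  res <- spearman_correlation(xx, yy)
  expect_equal(res$statistic, cor(rank(xx), rank(yy)), tolerance = 1e-12)
  expect_equal(res$statistic,
               unname(suppressWarnings(
                 cor.test(xx, yy, method = "spearman")$estimate)),
               tolerance = 1e-12)
  expect_error(spearman_correlation(c(1, 1, 1), c(2, 3, 4)),
               "undefined correlation")
  expect_error(spearman_correlation(1:2, 2:3), "at least 3")
})

test_that("group summaries reproduce printed cells of the packaged tables", {
  rec <- load_subject_records()
  gs <- group_summary(rec, "jvf_pct", "mean")
  expect_equal(round(gs$value[gs$group == "mTBI"], 1), 60.9)
  gm <- group_summary(rec, "mrv_grade", "median")
  expect_equal(gm$value[gm$group == "mTBI"], 4)
  expect_equal(gm$n[gm$group == "mTBI"], 14L)   # one n.a. excluded
  expect_equal(gm$value[gm$group == "control"], 3)
  expect_equal(gm$n[gm$group == "control"], 13L)
  g2 <- group_summary(rec, "icvc", "mean")
  expect_equal(round(g2$value[g2$group == "control"], 2), 0.61)
})
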