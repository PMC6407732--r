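test_that("boxplot statistics follow the quartile and whisker conventions", {
  b <- boxplot_stats(1:9)
  expect_equal(c(b$q1, b$median, b$q3), c(3, 5, 7))
  expect_equal(c(b$whisker_lo, b$whisker_hi), c(1, 9))
  expect_equal(b$n_outliers, 0)

  bc <- boxplot_stats(rep(4.2, 10))
  expect_equal(c(bc$median, bc$q1, bc$q3, bc$whisker_lo, bc$whisker_hi),
               rep(4.2, 5))
  expect_equal(bc$n_outliers, 0)

  # fences at q3 + 1.5 iqr: for 1,2,3,4,100 that is 4 + 1.5*2 = 7
  bo <- boxplot_stats(c(1, 2, 3, 4, 100))
  expect_equal(bo$outliers[[1]], 100)
  expect_equal(bo$whisker_hi, 4)
  expect_error(boxplot_stats(numeric(0)), "no data")
})

test_that("whisker points and outliers partition the data", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      x <- rcauchy(sample(5:50, 1))
      b <- boxplot_stats(x)
      inside <- x[x >= b$whisker_lo & x <= b$whisker_hi]
      expect_equal(sort(c(inside, b$outliers[[1]])), sort(x))
    }
  })
})

test_that("PS_dep is the proportion of positive paired differences", {
  x <- c(2, 3, 4, 0)
  y <- c(1, 1, 1, 1)   # differences 1, 2, 3, -1
  r <- wilcoxon_psdep(x, y)
  expect_equal(r$effect_size, 0.75)
  expect_equal(wilcoxon_psdep(1:6, 0:5)$effect_size, 1.0)
  same <- wilcoxon_psdep(1:4, 1:4)
  expect_equal(same$effect_size, 0)
  expect_true(is.na(same$statistic) && is.na(same$p_value))
  # zeros stay in the PS_dep denominator but leave the test
  z <- wilcoxon_psdep(c(5, 5, 7, 9, 11, 13), c(5, 5, 1, 1, 1, 1))
  expect_equal(z$effect_size, 4 / 6)
  expect_equal(z$n_nonzero, 4)
})

test_that("the signed-rank test agrees with the reference implementation", {
  withr::with_seed(9, {
    x <- rnorm(12, 0.5)
    y <- rnorm(12)
  })
  r <- wilcoxon_psdep(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)
})

test_that("swapping the pair members mirrors PS_dep", {
  withr::with_seed(5, {
    x <- rnorm(30)
    y <- rnorm(30)
  })
  fwd <- wilcoxon_psdep(x, y)$effect_size
  bwd <- wilcoxon_psdep(y, x)$effect_size
  expect_equal(bwd, sum(x - y < 0) / 30)
  expect_equal(fwd + bwd + sum(x == y) / 30, 1)
})

test_that("Kruskal-Wallis eta squared follows the H -> F -> eta2 chain", {
  # identical groups: no rank variance at all
  same <- kruskal_eta2(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$effect_size, 0)

  g <- list(c(1, 2, 3), c(10, 11, 12), c(20, 21, 22))
  r <- kruskal_eta2(g)
  # independent oracle: ranks by hand, H formula, chi-square p, F quantile
  values <- unlist(g)
  ranks <- rank(values)
  n <- length(values)
  groups <- rep(1:3, each = 3)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(ranks, groups, function(r) length(r) *
                 (mean(r) - (n + 1) / 2)^2))
  p <- pchisq(h, df = 2, lower.tail = FALSE)
  f <- qf(1 - p, 2, n - 3)
  eta2 <- f * 2 / (f * 2 + (n - 3))
  expect_equal(r$statistic, h)
  expect_equal(r$p_value, p)
  expect_equal(r$effect_size, eta2)

  # two groups of one value each still yield a defined H on df = 1
  r2 <- kruskal_eta2(list(1, 2))
  expect_equal(r2$df1, 1)
  expect_true(is.finite(r2$statistic))
  expect_error(kruskal_eta2(list(1:3, numeric(0))), "empty group")
})

test_that("rank-based statistics are invariant under monotone transforms", {
  withr::with_seed(13, {
    g <- list(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  })
  h1 <- kruskal_eta2(g)
  h2 <- kruskal_eta2(lapply(g, function(v) exp(v)))
  expect_equal(h1$statistic, h2$statistic)
  expect_equal(h1$effect_size, h2$effect_size)
})

test_that("search tests tidy into one-row tibbles", {
  td <- tidy(wilcoxon_psdep(c(1, 3, 5, 2, 8), c(0, 1, 2, 3, 4)))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("method", "statistic", "p.value", "effect_size",
                     "effect_name", "n"))
  expect_equal(td$effect_name, "ps_dep")
  gl <- glance(kruskal_eta2(list(1:4, 2:5)))
  expect_equal(gl$effect_name, "eta_squared")
})

test_that("the percentile bootstrap is seeded and honours degenerate cases", {
  const <- percentile_bootstrap(rep(3, 20), mean, n_boot = 200, seed = 4)
  expect_equal(c(const$lo, const$hi), c(3, 3))

  x <- withr::with_seed(2, rnorm(30))
  b1 <- percentile_bootstrap(x, mean, n_boot = 200, seed = 8)
  b2 <- percentile_bootstrap(x, mean, n_boot = 200, seed = 8)
  expect_equal(b1[, c("lo", "hi")], b2[, c("lo", "hi")])

  # n = 2 data {0, 1}: resample means can only be 0, 0.5 or 1
  b01 <- percentile_bootstrap(c(0, 1), mean, n_boot = 500, seed = 1)
  expect_true(all(c(b01$lo, b01$hi) %in% c(0, 0.5, 1)))
})

test_that("bootstrap interval coverage for a normal mean is sensible", {
  hits <- withr::with_seed(20, {
    vapply(1:200, function(i) {
      x <- rnorm(50, mean = 1)
      ci <- percentile_bootstrap(x, mean, n_boot = 200, seed = i)
      ci$lo <= 1 && 1 <= ci$hi
    }, logical(1))
  })
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})
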