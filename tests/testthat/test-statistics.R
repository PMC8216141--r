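# nonparametric statistical layer, verified against independent oracles

test_that("normal quantiles and the power formula", {
  expect_equal(round(normal_quantile(0.975), 2), 1.96)
  expect_equal(round(normal_quantile(0.80), 2), 0.84)
  expect_equal(normal_quantile(0.5), 0)
  expect_error(normal_quantile(0), "\\(0, 1\\)")

  # oracle: direct evaluation with full-precision quantiles
  n_oracle <- ceiling((qnorm(0.975) + qnorm(0.8))^2 * 2)
  ss <- sample_size(sd = 1, mean_diff = 1, dropout = 0)
  expect_equal(ss$n_per_group, n_oracle)  # = 16
  expect_equal(ss$n_per_group, 16L)
  expect_equal(ss$n_total, 2L * ss$n_per_group)  # dropout 0 -> N = 2n

  # quadratic scaling in the effect size (before ceiling)
  grid <- expand.grid(sd = c(0.5, 1, 2), d = c(0.5, 1, 3),
                      a = c(0.05, 0.01), pw = c(0.8, 0.9))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expected <- ceiling((qnorm(1 - g$a / 2) + qnorm(g$pw))^2 *
                          2 * g$sd^2 / g$d^2)
    expect_equal(sample_size(g$sd, g$d, g$a, g$pw)$n_per_group, expected)
  }
  expect_error(sample_size(1, 0), "non-zero")
})

test_that("Mann-Whitney exact p matches enumeration of labelings", {
  # oracle: enumerate all C(4,2) = 6 group labelings of {1,2,3,4}; only
  # the observed one puts both small values in x, so two-sided p = 2/6
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_true(r$exact)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)

  # exchangeability: identical multisets give p near 1
  r2 <- mann_whitney(c(1, 3, 5), c(5, 1, 3))
  expect_gt(r2$p_value, 0.9)

  # shifting one group monotonically decreases p
  set.seed(1)
  x <- rnorm(15)
  ps <- vapply(c(0, 1, 2, 4), function(sh)
    mann_whitney(x, rnorm(15, sh))$p_value, numeric(1))
  expect_true(all(diff(ps) <= 0))

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Kruskal-Wallis agrees with its two-group special case", {
  g <- list(a = rep(1, 5), b = rep(1, 5), c = rep(1, 5))
  # three identical groups -> H = 0 (all ties), p = 1
  r <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_gt(r$p_value, 0.99)

  set.seed(2)
  x <- rnorm(20); y <- rnorm(20, 0.6)
  pkw <- kruskal_wallis(list(x, y))$p_value
  pmw <- mann_whitney(x, y)$p_value  # normal approx at n = 40
  expect_lt(abs(pkw - pmw), 0.01)

  expect_error(kruskal_wallis(list(1:3)), ">= 2")
})

test_that("signed-rank exact p matches enumeration of sign assignments", {
  # n = 6 all positive: 2 of 2^6 = 64 assignments are as extreme -> 1/32
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))
  expect_true(r$exact)
  expect_equal(r$p_value, 2 / 64, tolerance = 1e-12)

  # n = 5 all positive cannot reach 0.05
  r5 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(r5$p_value, 0.0625, tolerance = 1e-12)

  # antisymmetric differences sit at the center
  ra <- wilcoxon_signed_rank(c(-2, 2, -5, 5))
  expect_gt(ra$p_value, 0.99)

  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")
})

test_that("Spearman correlation matches the rank formula", {
  expect_equal(spearman(1:10, 1:10)$r_s, 1)
  expect_equal(spearman(1:10, 10:1)$r_s, -1)
  # oracle: 1 - 6 * sum(d^2) / (n(n^2-1)) with d = (0,1,-1,0)
  r <- spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$r_s, 0.8, tolerance = 1e-12)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("Bonferroni caps and never decreases", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 10), 1)
  p <- c(0.001, 0.2, 0.9)
  expect_equal(bonferroni(p, m = 1), p)
  expect_true(all(bonferroni(p, m = 7) >= p))
  expect_true(all(bonferroni(p, m = 7) <= 1))
})

test_that("IQR outlier flags match hand quartiles and are affine-invariant", {
  # oracle by hand (type-7): Q1 = 2, Q3 = 4, IQR = 2, fences [-1, 7]
  v <- c(1, 2, 3, 4, 100)
  expect_equal(which(iqr_outliers(v)), 5L)
  expect_false(any(iqr_outliers(rep(3, 6))))  # constant: closed fences
  set.seed(3)
  z <- rnorm(50)
  expect_equal(iqr_outliers(z), iqr_outliers(3.2 * z - 17))
  expect_error(iqr_outliers(c(1, 2, 3)), ">= 4")
})

test_that("ANCOVA group effect equals the direct nested-model F-test", {
  set.seed(4)
  n <- 30
  group <- rep(c("A", "B", "C"), each = n / 3)
  age <- rnorm(n, 70, 8)
  y <- c(A = 0, B = 1, C = 2)[group] + rnorm(n)
  a <- ancova(y, group, age)

  # independent oracle: partial F from residual sums of squares
  sse_full <- sum(resid(lm(y ~ factor(group) + age))^2)
  sse_red <- sum(resid(lm(y ~ age))^2)
  f <- ((sse_red - sse_full) / 2) / (sse_full / (n - 4))
  p_oracle <- pf(f, 2, n - 4, lower.tail = FALSE)
  expect_equal(a$group_F, f, tolerance = 1e-9)
  expect_equal(a$group_p, p_oracle, tolerance = 1e-9)

  # y driven by age only: age p small, group p not extreme
  y2 <- 0.5 * age + rnorm(n)
  a2 <- ancova(y2, group, age)
  expect_lt(a2$age_p, 1e-6)
  expect_gt(a2$group_p, 0.001)

  # constant response: zero effects
  a3 <- tryCatch(suppressWarnings(ancova(rep(1, n), group, age)),
                 error = function(e) NULL)
  if (!is.null(a3)) expect_equal(a3$age_coef, 0, tolerance = 1e-9)
})

test_that("variance partition behaves at the null and in extremes", {
  # donors with far-apart means and tiny within-donor spread
  set.seed(5)
  donor <- rep(sprintf("D%d", 1:5), each = 6)
  v <- rep(c(0, 10, 20, 30, 40), each = 6) + rnorm(30, 0, 0.01)
  vp <- variance_partition(v, donor)
  expect_lt(vp$anova_p, 1e-10)
  expect_lt(vp$kw_p, 1e-4)
  expect_gt(vp$ms_between, vp$ms_within)

  # degenerate: repeated shared value per donor -> capped/flagged F
  v0 <- rep(c(1, 2, 3), each = 3)
  vp0 <- suppressWarnings(
    variance_partition(v0, rep(c("a", "b", "c"), each = 3)))
  expect_true(is.infinite(vp0$anova_F))
  expect_equal(vp0$anova_p, 0)

  # donors with < 2 values are excluded with a warning
  expect_warning(variance_partition(c(1, 2, 3, 4, 5),
                                    c("a", "a", "b", "b", "c")),
                 "excluding")

  # null: empirical size near alpha (light Monte Carlo; the full-size
  # check lives in the acceptance suite)
  set.seed(6)
  rej <- mean(replicate(300, {
    variance_partition(rnorm(24), rep(1:4, each = 6))$anova_p < 0.05
  }))
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.11)
})

test_that("compare_groups produces a long-format table with adjustment", {
  set.seed(8)
  d <- data.frame(group = rep(c("CTRL", "FRAC"), each = 12),
                  band = rep(c("a", "b", "c"), 8),
                  E_pr = rlnorm(24, log(5), 0.3),
                  eta = rlnorm(24, log(4), 0.4))
  tab <- compare_groups(d, c("E_pr", "eta"), c("group", "band"))
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$p_adjusted >= tab$p_value))
  expect_equal(tab$test[tab$grouping == "group"][1], "Mann-Whitney U")
  expect_equal(tab$test[tab$grouping == "band"][1], "Kruskal-Wallis")
})
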