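test_that("Clopper-Pearson reproduces published screening intervals", {
  ci <- clopper_pearson(34, 1093)
  expect_equal(round(100 * ci[["low"]], 1), 2.2)
  expect_equal(round(100 * ci[["high"]], 1), 4.3)
  ci2 <- clopper_pearson(20, 808)
  expect_equal(round(100 * ci2[["low"]], 1), 1.5)
  expect_equal(round(100 * ci2[["high"]], 1), 3.8)
})

test_that("Clopper-Pearson boundaries follow the closed forms", {
  ci <- clopper_pearson(0, 50)
  expect_identical(ci[["low"]], 0)
  expect_equal(ci[["high"]], 1 - 0.025^(1 / 50), tolerance = 1e-12)
  ci <- clopper_pearson(50, 50)
  expect_identical(ci[["high"]], 1)
  expect_error(clopper_pearson(5, 4), "0 <= x <= n")
  expect_error(clopper_pearson(2, 10, confidence = 1.2), "confidence")
})

test_that("Clopper-Pearson agrees with binom.test across random inputs", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:500, 1)
    x <- sample(0:n, 1)
    conf <- sample(c(0.9, 0.95, 0.99), 1)
    expect_equal(unname(clopper_pearson(x, n, conf)),
                 unname(binom.test(x, n, conf.level = conf)$conf.int[1:2]),
                 tolerance = 1e-12)
  }
})

test_that("Fisher test handles symmetric, small and published-style tables", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)), 1 / 3,
               tolerance = 1e-12)
  # recessive-fraction contrast of a 14/34 vs 0/20 comparison
  p <- fisher_exact(matrix(c(14, 20, 0, 20), 2, byrow = TRUE))
  expect_equal(p, oracle_fisher_p(14, 34, 20, 14), tolerance = 1e-12)
  expect_lt(p, 1e-3)
  expect_gt(p, 5e-4)
})

test_that("Fisher test matches fisher.test and warns on zero margins", {
  set.seed(21)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab), fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_warning(p <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "zero margin")
  expect_equal(p, 1)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("conditional MLE odds ratio and exact CI behave on reference tables", {
  null_tab <- matrix(c(10, 10, 10, 10), 2)
  r <- odds_ratio_exact(null_tab)
  expect_equal(r$or, 1, tolerance = 1e-8)
  expect_lt(r$ci_low, 1)
  expect_gt(r$ci_high, 1)

  r2 <- odds_ratio_exact(matrix(c(20, 10, 5, 40), 2, byrow = TRUE))
  expect_equal(r2$sample_or, 16)
  ft <- fisher.test(matrix(c(20, 5, 10, 40), 2))
  expect_equal(r2$or, unname(ft$estimate), tolerance = 1e-4)
  grid <- oracle_or_ci_grid(20, 10, 5, 40)
  expect_equal(r2$ci_low, grid[["low"]], tolerance = 1e-4)
  expect_equal(r2$ci_high, grid[["high"]], tolerance = 1e-4)
})

test_that("odds ratio boundaries give one-sided intervals and errors", {
  r <- odds_ratio_exact(matrix(c(5, 3, 0, 7), 2, byrow = TRUE))
  expect_identical(r$ci_high, Inf)
  expect_gt(r$ci_low, 0)
  r2 <- odds_ratio_exact(matrix(c(0, 3, 5, 7), 2, byrow = TRUE))
  expect_identical(r2$or, 0)
  expect_identical(r2$ci_low, 0)
  expect_lt(r2$ci_high, Inf)
  # a whole zero row/column leaves the odds ratio undefined
  expect_error(odds_ratio_exact(matrix(c(0, 0, 5, 7), 2, byrow = TRUE)), "margin")
  expect_error(odds_ratio_exact(matrix(c(0, 3, 0, 7), 2, byrow = TRUE)), "margin")
})

test_that("exact CI endpoints are monotone in the confidence level", {
  tab <- matrix(c(12, 7, 4, 20), 2, byrow = TRUE)
  levels <- c(0.8, 0.9, 0.95, 0.99)
  cis <- lapply(levels, function(cl) odds_ratio_exact(tab, cl))
  lows <- vapply(cis, `[[`, numeric(1), "ci_low")
  highs <- vapply(cis, `[[`, numeric(1), "ci_high")
  expect_true(all(diff(lows) < 0))
  expect_true(all(diff(highs) > 0))
})

test_that("two-sample proportion test: identity, symmetry, published counts", {
  r <- two_sample_proportion(10, 100, 10, 100)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  a <- two_sample_proportion(34, 1093, 20, 808)
  b <- two_sample_proportion(20, 808, 34, 1093)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  # pooled z for the Turkey-vs-UK prevalence contrast
  expect_equal(round(a$p, 2), 0.41)
  # matches prop.test without continuity correction
  pt <- suppressWarnings(prop.test(c(34, 20), c(1093, 808), correct = FALSE))
  expect_equal(a$z^2, unname(pt$statistic), tolerance = 1e-12)
  expect_warning(r0 <- two_sample_proportion(0, 10, 0, 20), "degenerate")
  expect_equal(r0$p, 1)
})

test_that("Mann-Whitney exact branch matches enumeration, ties included", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  r <- mann_whitney(1:3, 4:6)
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  set.seed(31)
  for (i in 1:20) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(1:7, nx, replace = TRUE)
    y <- sample(1:7, ny, replace = TRUE)
    expect_equal(mann_whitney(x, y)$p, oracle_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney agrees with wilcox.test on untied data", {
  set.seed(32)
  x <- rnorm(8); y <- rnorm(9) + 0.5
  r <- mann_whitney(x, y)
  wt <- wilcox.test(x, y, exact = TRUE)
  expect_equal(r$U, unname(wt$statistic))
  expect_equal(r$p, wt$p.value, tolerance = 1e-12)
  # large samples switch to the tie-corrected normal approximation
  xl <- rnorm(25); yl <- rnorm(25)
  rl <- mann_whitney(xl, yl)
  expect_false(rl$exact)
  wl <- wilcox.test(xl, yl, exact = FALSE, correct = FALSE)
  expect_equal(rl$p, wl$p.value, tolerance = 1e-12)
})

test_that("Kolmogorov-Smirnov statistic and exact p match enumeration", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$D, 1)
  set.seed(33)
  for (i in 1:12) {
    nx <- sample(2:4, 1); ny <- sample(2:4, 1)
    x <- sample(1:5, nx, replace = TRUE)
    y <- sample(1:5, ny, replace = TRUE)
    r <- ks_two_sample(x, y)
    expect_equal(r$D, ks_D_stat(x, y), tolerance = 1e-12)
    expect_equal(r$p, oracle_ks_p(x, y), tolerance = 1e-9)
  }
})
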