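toy_weights <- function(w = c(1, 2, 1)) {
  validate_weight_table(data.frame(
    snp_id = paste0("s", seq_along(w)), chrom = "1",
    pos = seq_along(w), risk_allele = "A", other_allele = "G",
    weight = w, stringsAsFactors = FALSE))
}

test_that("score normalisation: empty load is 0, full load is 1, toy is 0.5", {
  w <- toy_weights()
  d <- matrix(c(0, 0, 0,
                2, 2, 2,
                2, 1, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), w$snp_id))
  res <- compute_grs(d, w)
  expect_equal(res$score, c(0, 1, 0.5))
  expect_equal(res$n_missing, rep(0L, 3))
  expect_false(any(res$flagged))
})

test_that("missing data renormalises: equals the reduced weight table", {
  w <- default_weight_table()
  set.seed(41)
  d <- matrix(rbinom(3 * nrow(w), 2, 0.3), nrow = 3,
              dimnames = list(c("a", "b", "c"), w$snp_id))
  drop_snp <- w$snp_id[7]
  d_miss <- d
  d_miss[2, drop_snp] <- NA
  full <- compute_grs(d_miss, w)
  reduced <- compute_grs(d[, setdiff(colnames(d), drop_snp)],
                         w[w$snp_id != drop_snp, ])
  expect_equal(full$score[2], reduced$score[2], tolerance = 1e-12)
  expect_equal(full$n_missing[2], 1L)
})

test_that("children over the missingness ceiling are flagged, not zeroed", {
  w <- default_weight_table()
  d <- matrix(1, nrow = 2, ncol = nrow(w),
              dimnames = list(c("ok", "bad"), w$snp_id))
  d[2, 1:7] <- NA # 7/30 > 20%
  res <- compute_grs(d, w)
  expect_false(res$flagged[1])
  expect_true(res$flagged[2])
  expect_true(is.na(res$score[2]))
  expect_equal(res$score[1], 0.5)
})

test_that("unknown SNP columns are a load-time error naming the SNP", {
  w <- toy_weights()
  d <- matrix(1, 1, 4, dimnames = list("a", c(w$snp_id, "rs_rogue")))
  expect_error(compute_grs(d, w), "rs_rogue")
})

test_that("score is monotone in any dosage and invariant to SNP order", {
  w <- default_weight_table()
  set.seed(42)
  for (i in 1:20) {
    d <- matrix(rbinom(nrow(w), 2, 0.3), nrow = 1,
                dimnames = list("a", w$snp_id))
    s0 <- compute_grs(d, w)$score
    j <- sample(which(d < 2), 1)
    d2 <- d; d2[j] <- d2[j] + 1
    expect_gt(compute_grs(d2, w)$score, s0)
    perm <- sample(ncol(d))
    expect_equal(compute_grs(d[, perm, drop = FALSE], w)$score, s0,
                 tolerance = 1e-12)
  }
})

test_that("threshold calibration defaults to the published pair", {
  ref <- calibrate_thresholds()
  expect_equal(ref$threshold_low, 0.234)
  expect_equal(ref$threshold_high, 0.280)
  expect_length(ref$scores, 0)
})

test_that("empirical thresholds match an independent quantile oracle", {
  expect_equal(calibrate_thresholds(1:100)$threshold_high, 50.5)
  set.seed(43)
  x <- rnorm(1000)
  ref <- calibrate_thresholds(x)
  expect_equal(ref$threshold_low, oracle_quantile7(x, 0.05), tolerance = 1e-12)
  expect_equal(ref$threshold_high, oracle_quantile7(x, 0.50), tolerance = 1e-12)
  for (i in 1:20) {
    y <- runif(sample(100:400, 1))
    r <- calibrate_thresholds(y, centiles = c(10, 60))
    expect_equal(r$threshold_low, oracle_quantile7(y, 0.10), tolerance = 1e-12)
    expect_equal(r$threshold_high, oracle_quantile7(y, 0.60), tolerance = 1e-12)
  }
  expect_error(calibrate_thresholds(rnorm(50)), "at least 100")
  expect_error(calibrate_thresholds(c(rnorm(100), NA)), "finite")
})

test_that("category boundaries: moderate is the closed interval", {
  ref <- calibrate_thresholds()
  expect_equal(categorize_grs(c(0.233, 0.234, 0.280, 0.2801, NA), ref),
               c("low", "moderate", "moderate", "high", NA))
})

test_that("centiles are empirical and undefined without reference scores", {
  ref <- calibrate_thresholds(seq(0, 1, length.out = 101))
  expect_equal(grs_centile(0.5, ref), 100 * 51 / 101)
  expect_true(is.na(grs_centile(0.5, calibrate_thresholds())))
})

test_that("distribution comparison: identical samples and disjoint supports", {
  x <- c(0.25, 0.26, 0.27, 0.28)
  r <- compare_grs_distributions(x, x)
  expect_equal(r$mw_p, 1)
  expect_equal(r$ks_D, 0)
  r2 <- compare_grs_distributions(c(1, 2), c(3, 4))
  expect_equal(r2$ks_D, 1)
  expect_error(compare_grs_distributions(1, c(1, 2)), "at least 2")
})

test_that("distribution comparison p values equal enumeration at small n", {
  set.seed(44)
  x <- rnorm(5); y <- rnorm(6)
  r <- compare_grs_distributions(x, y)
  expect_equal(r$mw_p, oracle_mw_p(x, y), tolerance = 1e-12)
  expect_equal(r$ks_p, oracle_ks_p(x, y), tolerance = 1e-9)
  expect_equal(r$median_x, median(x))
  expect_equal(r$iqr_x, oracle_quantile7(x, c(0.25, 0.75)), tolerance = 1e-12)
})
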