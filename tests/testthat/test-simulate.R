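test_that("generator parameters validate their inputs", {
  expect_s3_class(generator_params(), "generator_params")
  expect_error(generator_params(monogenic_prevalence = 1.2), "\\[0, 1\\]")
  expect_error(generator_params(recessive_fraction_of_monogenic = 0.8,
                                other_fraction_of_monogenic = 0.3), "exceed 1")
  expect_error(generator_params(n_cohort = 0), "at least 1")
  expect_error(generator_params(
    criterion_odds = list(non_insulin_treatment = c(dominant = -2, recessive = NA)),
    baseline_rates = c(non_insulin_treatment = 0.01)), "positive")
  expect_error(generator_params(
    criterion_odds = list(foo = c(dominant = 2, recessive = NA))),
    "baseline rate")
})

test_that("reference simulation is deterministic and centred near 0.280", {
  p <- generator_params(seed = 1)
  r1 <- generate_reference(p)
  r2 <- generate_reference(p)
  expect_identical(r1, r2)
  expect_length(r1, 1963)
  expect_lt(abs(median(r1) - 0.280), 0.005)
  # the empirical 5th centile sits near the published low threshold
  expect_lt(abs(unname(quantile(r1, 0.05)) - 0.234), 0.01)
  expect_length(generate_reference(generator_params(n_reference = 0)), 0)
})

test_that("cohort generation is deterministic given params and seed", {
  p <- generator_params(seed = 5)
  c1 <- generate_cohort(p)
  c2 <- generate_cohort(p)
  expect_identical(c1$children, c2$children)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$calls, c2$calls)
  c3 <- generate_cohort(generator_params(seed = 6))
  expect_false(identical(c1$children, c3$children))
})

test_that("class counts concentrate around their expectations", {
  p <- generator_params(seed = 2)
  co <- generate_cohort(p)
  n <- p$n_cohort
  expected <- c(
    definite_t1d = (1 - p$monogenic_prevalence) * p$antibody_positive_rate_t1d,
    ab_negative_nonmonogenic = (1 - p$monogenic_prevalence) *
      (1 - p$antibody_positive_rate_t1d),
    monogenic_AD = p$monogenic_prevalence *
      (1 - p$recessive_fraction_of_monogenic - p$other_fraction_of_monogenic),
    monogenic_AR = p$monogenic_prevalence * p$recessive_fraction_of_monogenic,
    monogenic_other = p$monogenic_prevalence * p$other_fraction_of_monogenic)
  counts <- table(factor(co$truth$true_class, levels = names(expected)))
  for (cl in names(expected)) {
    mu <- n * expected[[cl]]
    tol <- 3 * sqrt(n * expected[[cl]] * (1 - expected[[cl]]))
    expect_lt(abs(counts[[cl]] - mu), tol + 1)
  }
  # every monogenic child has exactly one pathogenic truth call
  mono_ids <- co$truth$child_id[grepl("^monogenic", co$truth$true_class)]
  expect_setequal(co$calls$child_id, mono_ids)
  expect_false(anyDuplicated(co$calls$child_id) > 0)
})

test_that("zero prevalence produces no monogenic children or calls", {
  co <- generate_cohort(generator_params(monogenic_prevalence = 0, seed = 3))
  expect_equal(nrow(co$calls), 0)
  expect_false(any(grepl("^monogenic", co$truth$true_class)))
  dx <- classify_cases(co$calls, default_gene_panel())
  expect_equal(nrow(dx), 0)
})

test_that("definite type 1 diabetes scores resemble the reference distribution", {
  p <- generator_params(seed = 4)
  co <- generate_cohort(p)
  scored <- score_cohort(co$genotypes, co$weights)
  def <- is_definite_t1d(co$children)
  cmp <- compare_grs_distributions(scored$score[def], generate_reference(p))
  expect_lt(abs(cmp$median_x - cmp$median_y), 0.01)
  expect_gt(cmp$ks_p, 0.01)
})

test_that("most monogenic children fall inside the tested triage subset", {
  hits <- 0; total <- 0
  for (seed in 1:20) {
    co <- generate_cohort(generator_params(seed = seed))
    scored <- score_cohort(co$genotypes, co$weights)
    ch <- co$children
    ch$grs_category <- scored$category
    dec <- triage_cohort(ch)
    mono <- co$truth$child_id[grepl("^monogenic", co$truth$true_class)]
    hits <- hits + sum(dec$tested[dec$child_id %in% mono])
    total <- total + length(mono)
  }
  expect_gte(hits / total, 0.9)
})

test_that("recessive truth calls favour WFS1 and SLC19A2", {
  co <- generate_cohort(generator_params(seed = 8, n_cohort = 20000,
                                         monogenic_prevalence = 0.05))
  rec <- co$calls[co$calls$zygosity == "biallelic", ]
  tab <- sort(table(rec$gene_symbol), decreasing = TRUE)
  expect_setequal(names(tab)[1:2], c("WFS1", "SLC19A2"))
})
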