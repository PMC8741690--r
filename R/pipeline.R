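#' Compare two cohorts' prevalence and recessive fraction
#'
#' Prevalence is compared with the two-sample proportion test (pooled z, no
#' continuity correction); the recessive fraction among monogenic cases is
#' compared with the two-tailed Fisher exact test on
#' \code{[[recessive1, cases1 - recessive1], [recessive2, cases2 - recessive2]]}.
#'
#' @param cases1,n1,recessive1 monogenic case count, cohort size and
#'   recessive case count in the first cohort.
#' @param cases2,n2,recessive2 the same for the comparison cohort;
#'   \code{n2 = NA} skips the prevalence comparison (no denominator, e.g.
#'   referral series).
#' @return list with \code{prevalence1}, \code{prevalence2},
#'   \code{proportion_z}, \code{proportion_p}, \code{recessive_fraction1},
#'   \code{recessive_fraction2}, \code{fisher_p}.
#' @examples
#' cc <- compare_cohorts(34, 1093, 14, 20, 808, 0)
#' round(cc$proportion_p, 2)
#' @export
compare_cohorts <- function(cases1, n1, recessive1, cases2, n2, recessive2) {
  if (cases1 > n1 || (!is.na(n2) && cases2 > n2))
    stop_("cases cannot exceed cohort size")
  if (recessive1 > cases1 || recessive2 > cases2)
    stop_("recessive cases cannot exceed total cases")
  if (!is.na(n2)) {
    pt <- two_sample_proportion(cases1, n1, cases2, n2)
    prev2 <- cases2 / n2
  } else {
    pt <- list(z = NA_real_, p = NA_real_)
    prev2 <- NA_real_
  }
  fp <- fisher_exact(matrix(c(recessive1, cases1 - recessive1,
                              recessive2, cases2 - recessive2),
                            nrow = 2, byrow = TRUE))
  list(prevalence1 = cases1 / n1, prevalence2 = prev2,
       proportion_z = pt$z, proportion_p = pt$p,
       recessive_fraction1 = recessive1 / cases1,
       recessive_fraction2 = recessive2 / cases2,
       fisher_p = fp)
}

#' Run the full screening pipeline
#'
#' Orchestrates simulate (or load) -> score -> triage -> classify ->
#' analyse. Genetic testing is applied only to the triaged (tested) subset,
#' as in the study design, so the estimated prevalence is a minimum
#' prevalence.
#'
#' @param cohort either a \code{synthetic_cohort} from [generate_cohort()],
#'   or a phenotype data frame that already carries \code{grs_category}
#'   (e.g. [printed_partition_fixture()]).
#' @param calls variant calls for tested children; taken from the synthetic
#'   cohort's truth calls when \code{cohort} is a \code{synthetic_cohort}
#'   and \code{calls} is \code{NULL}. An empty or \code{NULL} calls table
#'   yields zero diagnoses.
#' @param panel gene panel (default [default_gene_panel()]).
#' @param ref GRS reference (default: published thresholds).
#' @param confidence confidence level for all intervals.
#' @param projection_k hypothetical extra cases for the projected
#'   prevalence (default 2).
#' @param uk_comparison logical; compare against the bundled UK literature
#'   counts (default TRUE).
#' @return object of class \code{results_bundle}: list with \code{seed},
#'   \code{partition}, \code{prevalence}, \code{projected_prevalence},
#'   \code{inheritance}, \code{criteria}, \code{cohort_comparisons},
#'   \code{grs_results}, \code{diagnoses}.
#' @export
run_pipeline <- function(cohort, calls = NULL, panel = default_gene_panel(),
                         ref = calibrate_thresholds(), confidence = 0.95,
                         projection_k = 2, uk_comparison = TRUE) {
  seed <- NA_integer_
  grs_results <- NULL
  if (inherits(cohort, "synthetic_cohort")) {
    seed <- cohort$params$seed
    if (is.null(calls)) calls <- cohort$calls
    grs_results <- score_cohort(cohort$genotypes, cohort$weights, ref)
    children <- cohort$children
    children$grs_score <- grs_results$score[match(children$child_id,
                                                  grs_results$child_id)]
    children$grs_category <- grs_results$category[match(children$child_id,
                                                        grs_results$child_id)]
  } else {
    children <- cohort
    if (!"grs_category" %in% names(children))
      stop_("cohort must be a synthetic_cohort or carry a grs_category column")
  }

  decisions <- triage_cohort(children)
  part <- partition_summary(decisions)

  tested_ids <- decisions$child_id[decisions$tested]
  if (is.null(calls) || nrow(calls) == 0) {
    tested_calls <- data.frame(child_id = character(0),
                               gene_symbol = character(0),
                               zygosity = character(0),
                               pathogenic = logical(0))
  } else {
    tested_calls <- calls[calls$child_id %in% tested_ids, , drop = FALSE]
  }
  diagnoses <- classify_cases(tested_calls, panel)
  causes <- summarize_causes(diagnoses)

  n_cohort <- nrow(children)
  prev <- prevalence(nrow(diagnoses), n_cohort, confidence, minimum = TRUE)
  proj <- project_prevalence(nrow(diagnoses), n_cohort, k = projection_k,
                             confidence = confidence)
  crit <- criteria_report(children, diagnoses, confidence = confidence)

  comparisons <- NULL
  if (uk_comparison) {
    uk <- uk_literature_counts()
    n_rec <- sum(diagnoses$inheritance == "autosomal_recessive")
    comparisons <- lapply(seq_len(nrow(uk)), function(i) {
      compare_cohorts(nrow(diagnoses), n_cohort, n_rec,
                      uk$n_cases[i], uk$n_cohort[i], uk$n_recessive[i])
    })
    names(comparisons) <- uk$cohort
  }

  bundle <- list(seed = seed, partition = part, prevalence = prev,
                 projected_prevalence = proj, inheritance = causes,
                 criteria = crit, cohort_comparisons = comparisons,
                 grs_results = grs_results, diagnoses = diagnoses,
                 decisions = decisions, confidence = confidence)
  class(bundle) <- "results_bundle"
  bundle
}

#' @export
print.results_bundle <- function(x, ...) {
  p <- x$prevalence
  cat(sprintf("Tested %d of %d children (low GRS: %d, moderate antibody-negative: %d)\n",
              x$partition$tested_total, x$partition$total,
              x$partition$low_grs, x$partition$moderate_ab_negative))
  cat(sprintf("%s prevalence: %.1f%% (%d/%d; %d%% CI %.1f, %.1f)\n",
              if (p$minimum) "Minimum" else "Estimated",
              100 * p$proportion, p$n_cases, p$n_cohort,
              round(100 * p$confidence), 100 * p$ci_low, 100 * p$ci_high))
  cat(sprintf("Projected prevalence with %d added case(s): %.1f%%\n",
              x$projected_prevalence$k_added,
              100 * x$projected_prevalence$proportion))
  if (nrow(x$inheritance$by_inheritance) > 0) {
    cat("Causes by inheritance:\n")
    print(x$inheritance$by_inheritance)
  }
  invisible(x)
}

#' Write a results bundle to disk
#'
#' Serialises the machine-readable results: a JSON summary plus CSV tables
#' for the criteria report, diagnoses and triage decisions. Numbers are
#' stored at full precision; rounding belongs to the report layer.
#'
#' @param bundle a \code{results_bundle} from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    summary = file.path(dir, "summary.json"),
    criteria = file.path(dir, "criteria_report.csv"),
    diagnoses = file.path(dir, "diagnoses.csv"),
    decisions = file.path(dir, "triage_decisions.csv"))
  summary <- list(seed = bundle$seed, partition = bundle$partition,
                  prevalence = bundle$prevalence,
                  projected_prevalence = bundle$projected_prevalence,
                  inheritance = bundle$inheritance$by_inheritance,
                  cohort_comparisons = bundle$cohort_comparisons,
                  confidence = bundle$confidence)
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  write.csv(bundle$criteria, paths["criteria"], row.names = FALSE)
  write.csv(bundle$diagnoses, paths["diagnoses"], row.names = FALSE)
  write.csv(bundle$decisions, paths["decisions"], row.names = FALSE)
  invisible(paths)
}
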