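# Built-in clinical selection criteria. Each is a predicate over the
# phenotype table returning TRUE/FALSE/NA per child; NA (not evaluable) is
# excluded pairwise by evaluate_criterion, with the count recorded.

builtin_criteria <- function() {
  list(
    non_insulin_treatment = function(df) !df$insulin_treated,
    parent_with_diabetes = function(df) df$parent_with_diabetes,
    hba1c_le_58 = function(df) df$hba1c_mmol_mol <= 58,
    mody_probability_ge_10 = function(df) df$mody_probability >= 0.10,
    extra_pancreatic_features = function(df) {
      f <- df$extra_pancreatic_features
      ifelse(is.na(f), NA, nzchar(trimws(f)))
    },
    parental_consanguinity = function(df) df$parental_consanguinity
  )
}

#' Names of the built-in selection criteria
#'
#' @return character vector of criterion names usable with
#'   [evaluate_criterion()].
#' @export
criterion_names <- function() names(builtin_criteria())

#' Evaluate a clinical selection criterion against diagnosed cases
#'
#' Builds the 2x2 table of criterion presence against case status — children
#' diagnosed with monogenic diabetes of the target inheritance class versus
#' the rest of the cohort — then computes the exact conditional
#' maximum-likelihood odds ratio, its exact confidence interval and the
#' two-tailed Fisher p value. Children for whom the criterion is not
#' evaluable (missing value) are excluded pairwise and counted.
#'
#' Built-in criteria: \code{non_insulin_treatment},
#' \code{parent_with_diabetes}, \code{hba1c_le_58} (HbA1c at or below 58
#' mmol/mol, i.e. 7.5\%), \code{mody_probability_ge_10} (composite clinical
#' MODY probability at or above 10\%), \code{extra_pancreatic_features}
#' (any non-autoimmune extra-pancreatic feature) and
#' \code{parental_consanguinity}.
#'
#' @param cohort phenotype data frame (see [read_phenotypes()]).
#' @param diagnoses diagnoses data frame from [classify_cases()].
#' @param criterion a built-in criterion name, or a function of the cohort
#'   returning a logical vector (then \code{criterion_label} names it).
#' @param target_group \code{"autosomal_dominant"} or
#'   \code{"autosomal_recessive"}.
#' @param confidence confidence level for the odds-ratio interval.
#' @param criterion_label label used when \code{criterion} is a function.
#' @return object of class \code{criterion_result}: list with
#'   \code{criterion}, \code{target_group}, \code{table} (2x2 matrix),
#'   \code{or}, \code{ci_low}, \code{ci_high}, \code{sample_or},
#'   \code{fisher_p}, \code{n_excluded}.
#' @export
evaluate_criterion <- function(cohort, diagnoses, criterion,
                               target_group = c("autosomal_recessive",
                                                "autosomal_dominant"),
                               confidence = 0.95,
                               criterion_label = "custom") {
  target_group <- match.arg(target_group)
  if (is.character(criterion)) {
    reg <- builtin_criteria()
    if (!criterion %in% names(reg))
      stop_("unknown criterion '", criterion, "'; available: ",
            paste(names(reg), collapse = ", "))
    criterion_label <- criterion
    criterion <- reg[[criterion]]
  }
  stopifnot(is.function(criterion))
  crit <- criterion(cohort)
  if (length(crit) != nrow(cohort))
    stop_("criterion must return one value per cohort row")
  is_case <- cohort$child_id %in%
    diagnoses$child_id[diagnoses$inheritance == target_group]
  keep <- !is.na(crit)
  n_excluded <- sum(!keep)
  crit <- crit[keep]; is_case <- is_case[keep]
  tab <- matrix(c(sum(crit & is_case), sum(crit & !is_case),
                  sum(!crit & is_case), sum(!crit & !is_case)),
                nrow = 2, byrow = TRUE,
                dimnames = list(criterion = c("present", "absent"),
                                group = c("case", "comparison")))
  orx <- odds_ratio_exact(tab, confidence)
  res <- list(criterion = criterion_label, target_group = target_group,
              table = tab, or = orx$or, ci_low = orx$ci_low,
              ci_high = orx$ci_high, sample_or = orx$sample_or,
              fisher_p = fisher_exact(tab), n_excluded = n_excluded)
  class(res) <- "criterion_result"
  res
}

#' @export
print.criterion_result <- function(x, ...) {
  cat(sprintf("%s vs %s: OR %.1f (95%% CI %.1f, %.1f), Fisher p = %s\n",
              x$criterion, x$target_group, x$or, x$ci_low, x$ci_high,
              format_p(x$fisher_p)))
  if (x$n_excluded > 0)
    cat(sprintf("  (%d children excluded: criterion not evaluable)\n",
                x$n_excluded))
  invisible(x)
}

#' Criteria performance report
#'
#' Evaluates every requested criterion for both inheritance target groups,
#' mirroring a forest-plot style table: one row per (criterion, group) with
#' the exact odds ratio, its confidence interval and Fisher p value.
#'
#' @inheritParams evaluate_criterion
#' @param criteria character vector of built-in criterion names; defaults to
#'   all of them.
#' @return data frame with columns \code{criterion}, \code{target_group},
#'   \code{a}, \code{b}, \code{c}, \code{d}, \code{or}, \code{ci_low},
#'   \code{ci_high}, \code{sample_or}, \code{fisher_p}, \code{n_excluded}.
#' @export
criteria_report <- function(cohort, diagnoses, criteria = criterion_names(),
                            confidence = 0.95) {
  rows <- list()
  for (grp in c("autosomal_dominant", "autosomal_recessive")) {
    for (cr in criteria) {
      r <- tryCatch(
        evaluate_criterion(cohort, diagnoses, cr, grp, confidence),
        error = function(e) NULL)
      if (is.null(r)) { # degenerate table (e.g. no cases in the target group)
        rows[[length(rows) + 1]] <- data.frame(
          criterion = cr, target_group = grp, a = NA, b = NA, c = NA, d = NA,
          or = NA, ci_low = NA, ci_high = NA, sample_or = NA, fisher_p = NA,
          n_excluded = NA, stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        criterion = cr, target_group = grp,
        a = r$table[1, 1], b = r$table[1, 2],
        c = r$table[2, 1], d = r$table[2, 2],
        or = r$or, ci_low = r$ci_low, ci_high = r$ci_high,
        sample_or = r$sample_or, fisher_p = r$fisher_p,
        n_excluded = r$n_excluded, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
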