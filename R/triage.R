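#' Apply the study eligibility window
#'
#' Children are eligible when diabetes onset fell between 6 months and 20
#' years of age, both bounds inclusive. Records with a missing age are
#' excluded with an explicit reason rather than dropped.
#'
#' @param cohort data frame with at least \code{child_id} and
#'   \code{age_at_diagnosis}.
#' @param min_age,max_age eligibility bounds in years (defaults 0.5 and 20).
#' @return list with \code{eligible} and \code{excluded} data frames; the
#'   excluded frame carries an \code{exclusion_reason} column.
#' @export
filter_eligible <- function(cohort, min_age = 0.5, max_age = 20) {
  age <- cohort$age_at_diagnosis
  reason <- rep(NA_character_, nrow(cohort))
  reason[is.na(age)] <- "missing_age"
  reason[!is.na(age) & age < min_age] <- "age_below_minimum"
  reason[!is.na(age) & age > max_age] <- "age_above_maximum"
  excl <- !is.na(reason)
  excluded <- cohort[excl, , drop = FALSE]
  if (nrow(excluded) > 0) excluded$exclusion_reason <- reason[excl]
  list(eligible = cohort[!excl, , drop = FALSE], excluded = excluded)
}

#' Identify definite type 1 diabetes
#'
#' Definite type 1 diabetes is defined as clinically diagnosed, insulin
#' treated and islet-autoantibody positive — all three required. Missing
#' antibody status is not positive. This subset supplies the within-cohort
#' score distribution compared against the external reference.
#'
#' @param cohort data frame with \code{clinically_diagnosed_t1d},
#'   \code{insulin_treated} and \code{antibody_status}.
#' @return logical vector.
#' @export
is_definite_t1d <- function(cohort) {
  isTRUE_v <- function(x) !is.na(x) & x
  isTRUE_v(cohort$clinically_diagnosed_t1d) &
    isTRUE_v(cohort$insulin_treated) &
    !is.na(cohort$antibody_status) & cohort$antibody_status == "positive"
}

#' Genetic-testing selection rule
#'
#' The published triage rule on (GRS category, antibody status): children
#' with a low genetic risk score are tested irrespective of antibody status;
#' children with a moderate score are tested only when antibody-negative;
#' children with a high score, and moderate children who are
#' antibody-positive or have missing antibody status, are not tested.
#'
#' @param category character vector of GRS categories
#'   ("low"/"moderate"/"high"); an \code{NA} category is an error — score or
#'   flag the child first.
#' @param antibody_status character vector ("positive"/"negative"/"missing").
#' @return data frame with \code{tested} (logical) and \code{reason}
#'   (one of low_grs, moderate_ab_negative, high_grs, moderate_ab_positive,
#'   moderate_ab_missing).
#' @examples
#' select_for_testing("low", "positive")      # tested, low_grs
#' select_for_testing("moderate", "missing")  # not tested
#' @export
select_for_testing <- function(category, antibody_status) {
  if (length(category) != length(antibody_status))
    stop_("category and antibody_status must have equal length")
  if (any(is.na(category)))
    stop_("undefined GRS category: children must be scored (or flagged) before triage")
  if (!all(category %in% c("low", "moderate", "high")))
    stop_("category must be low/moderate/high")
  ab <- ifelse(is.na(antibody_status), "missing", antibody_status)
  if (!all(ab %in% c("positive", "negative", "missing")))
    stop_("antibody_status must be positive/negative/missing")
  reason <- character(length(category))
  reason[category == "low"] <- "low_grs"
  reason[category == "high"] <- "high_grs"
  mod <- category == "moderate"
  reason[mod & ab == "negative"] <- "moderate_ab_negative"
  reason[mod & ab == "positive"] <- "moderate_ab_positive"
  reason[mod & ab == "missing"] <- "moderate_ab_missing"
  data.frame(tested = reason %in% c("low_grs", "moderate_ab_negative"),
             reason = reason, stringsAsFactors = FALSE)
}

#' Triage a scored cohort
#'
#' Applies [filter_eligible()] and then [select_for_testing()]; ineligible
#' children are retained in the output with reason \code{"ineligible"} for
#' auditability.
#'
#' @param cohort data frame with \code{child_id}, \code{age_at_diagnosis},
#'   \code{antibody_status} and \code{grs_category}.
#' @return data frame with \code{child_id}, \code{tested}, \code{reason}.
#' @export
triage_cohort <- function(cohort) {
  if (!"grs_category" %in% names(cohort))
    stop_("cohort must carry a grs_category column (run score_cohort first)")
  parts <- filter_eligible(cohort)
  el <- parts$eligible
  dec <- select_for_testing(el$grs_category, el$antibody_status)
  out <- data.frame(child_id = el$child_id, tested = dec$tested,
                    reason = dec$reason, stringsAsFactors = FALSE)
  if (nrow(parts$excluded) > 0) {
    out <- rbind(out, data.frame(child_id = parts$excluded$child_id,
                                 tested = FALSE, reason = "ineligible",
                                 stringsAsFactors = FALSE))
  }
  out[match(cohort$child_id, out$child_id), , drop = FALSE]
}

#' Summarise a triage partition
#'
#' Counts per decision reason plus tested / untested totals. Totals always
#' conserve the cohort size.
#'
#' @param decisions data frame from [triage_cohort()] or
#'   [select_for_testing()] with \code{tested} and \code{reason}.
#' @return named list of counts.
#' @export
partition_summary <- function(decisions) {
  reasons <- c("low_grs", "moderate_ab_negative", "high_grs",
               "moderate_ab_positive", "moderate_ab_missing", "ineligible")
  counts <- vapply(reasons, function(r) sum(decisions$reason == r), integer(1))
  c(as.list(counts),
    list(tested_total = sum(decisions$tested),
         untested_total = sum(!decisions$tested),
         total = nrow(decisions)))
}
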