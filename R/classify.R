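#' Classify confirmed monogenic diabetes cases by inheritance mode
#'
#' The zygosity-based rule: every monoallelic pathogenic variant is counted
#' as autosomal dominant, every biallelic pathogenic variant (homozygous or
#' compound heterozygous) as autosomal recessive, and mitochondrial variants
#' as "other". Classification depends only on zygosity, never on the gene
#' symbol; the panel is consulted only to reject calls in genes outside it.
#'
#' Non-pathogenic calls are rejected (dropped with a warning). A child with
#' both a monoallelic and a biallelic pathogenic call is classified by the
#' biallelic call, with a warning.
#'
#' @param calls data frame of variant calls (\code{child_id},
#'   \code{gene_symbol}, \code{zygosity}, \code{pathogenic}); see
#'   [read_variant_calls()].
#' @param panel gene panel data frame; see [default_gene_panel()].
#' @return data frame of diagnoses: \code{child_id}, \code{gene_symbol},
#'   \code{inheritance} (autosomal_dominant / autosomal_recessive / other),
#'   one row per child.
#' @examples
#' panel <- default_gene_panel()
#' calls <- data.frame(child_id = c("k1", "k2"),
#'                     gene_symbol = c("GCK", "WFS1"),
#'                     zygosity = c("monoallelic", "biallelic"),
#'                     pathogenic = TRUE)
#' classify_cases(calls, panel)
#' @export
classify_cases <- function(calls, panel) {
  stopifnot(is.data.frame(calls))
  if (nrow(calls) == 0)
    return(data.frame(child_id = character(0), gene_symbol = character(0),
                      inheritance = character(0), stringsAsFactors = FALSE))
  if (any(!calls$pathogenic)) {
    warning(sum(!calls$pathogenic),
            " non-pathogenic call(s) rejected from classification")
    calls <- calls[calls$pathogenic, , drop = FALSE]
  }
  absent <- setdiff(unique(calls$gene_symbol), panel$gene_symbol)
  if (length(absent) > 0)
    stop_("gene(s) absent from the panel: ", paste(absent, collapse = ", "))
  if (!all(calls$zygosity %in% c("monoallelic", "biallelic", "mitochondrial_variant")))
    stop_("zygosity must be monoallelic/biallelic/mitochondrial_variant")
  # biallelic takes precedence when a child has several pathogenic calls
  priority <- c(biallelic = 1, mitochondrial_variant = 2, monoallelic = 3)
  dup <- duplicated(calls$child_id) | duplicated(calls$child_id, fromLast = TRUE)
  if (any(dup)) {
    warning("child(ren) with multiple pathogenic calls classified by the ",
            "biallelic call: ",
            paste(unique(calls$child_id[dup]), collapse = ", "))
    calls <- calls[order(calls$child_id, priority[calls$zygosity]), ]
    calls <- calls[!duplicated(calls$child_id), , drop = FALSE]
  }
  inheritance <- c(monoallelic = "autosomal_dominant",
                   biallelic = "autosomal_recessive",
                   mitochondrial_variant = "other")[calls$zygosity]
  data.frame(child_id = calls$child_id, gene_symbol = calls$gene_symbol,
             inheritance = unname(inheritance), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Summarise causes of monogenic diabetes
#'
#' Counts and percentages per inheritance class, plus a per-gene table
#' suitable for a bar chart of causes.
#'
#' @param diagnoses data frame from [classify_cases()].
#' @return list with \code{by_inheritance} (inheritance, n, percent) and
#'   \code{by_gene} (gene_symbol, inheritance, n), both sorted by count.
#' @export
summarize_causes <- function(diagnoses) {
  if (nrow(diagnoses) == 0) {
    return(list(by_inheritance = data.frame(inheritance = character(0),
                                            n = integer(0), percent = numeric(0)),
                by_gene = data.frame(gene_symbol = character(0),
                                     inheritance = character(0), n = integer(0))))
  }
  total <- nrow(diagnoses)
  tab <- table(diagnoses$inheritance)
  by_inh <- data.frame(inheritance = names(tab), n = as.integer(tab),
                       percent = as_percent(as.integer(tab) / total),
                       stringsAsFactors = FALSE)
  by_inh <- by_inh[order(-by_inh$n), , drop = FALSE]
  gt <- aggregate(list(n = diagnoses$child_id),
                  by = list(gene_symbol = diagnoses$gene_symbol,
                            inheritance = diagnoses$inheritance),
                  FUN = length)
  gt <- gt[order(-gt$n, gt$gene_symbol), , drop = FALSE]
  rownames(by_inh) <- rownames(gt) <- NULL
  list(by_inheritance = by_inh, by_gene = gt)
}

#' Prevalence with exact binomial confidence interval
#'
#' Point estimate \code{n_cases / n_cohort} with a Clopper-Pearson interval.
#' When part of the cohort was never tested the estimate is a minimum
#' prevalence; set \code{minimum = TRUE} to label it as such.
#'
#' @param n_cases number of confirmed cases.
#' @param n_cohort cohort size (> 0).
#' @param confidence confidence level, default 0.95.
#' @param minimum logical; whether untested subgroups exist, making this a
#'   minimum prevalence.
#' @return list with \code{proportion}, \code{ci_low}, \code{ci_high},
#'   \code{n_cases}, \code{n_cohort}, \code{confidence}, \code{minimum}.
#' @examples
#' p <- prevalence(34, 1093)
#' round(100 * c(p$proportion, p$ci_low, p$ci_high), 1) # 3.1, 2.2, 4.3
#' @export
prevalence <- function(n_cases, n_cohort, confidence = 0.95, minimum = TRUE) {
  if (n_cohort <= 0) stop_("n_cohort must be positive")
  if (n_cases < 0 || n_cases > n_cohort)
    stop_("need 0 <= n_cases <= n_cohort")
  ci <- clopper_pearson(n_cases, n_cohort, confidence)
  list(proportion = n_cases / n_cohort,
       ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
       n_cases = n_cases, n_cohort = n_cohort,
       confidence = confidence, minimum = minimum)
}

#' Project prevalence with additional hypothetical cases
#'
#' Adds \code{k} hypothetical cases to the numerator only, quantifying how
#' much higher the prevalence could be had untested subgroups harboured
#' further cases (e.g. antibody-negative children with high genetic risk who
#' were never tested).
#'
#' @inheritParams prevalence
#' @param k number of hypothetical additional cases (non-negative integer).
#' @return list as in [prevalence()], with \code{minimum = FALSE} and an
#'   extra \code{k_added} element.
#' @examples
#' round(100 * project_prevalence(34, 1093, k = 2)$proportion, 1) # 3.3
#' @export
project_prevalence <- function(n_cases, n_cohort, k = 2, confidence = 0.95) {
  if (k < 0 || k != round(k)) stop_("k must be a non-negative integer")
  out <- prevalence(n_cases + k, n_cohort, confidence, minimum = FALSE)
  out$k_added <- k
  out
}
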