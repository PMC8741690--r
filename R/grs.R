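#' Compute the weighted type 1 diabetes genetic risk score
#'
#' For each child the score is the weighted risk-allele load normalised to
#' \code{[0, 1]}:
#' \deqn{score = \frac{\sum_i w_i d_i}{2 \sum_i w_i}}
#' where \eqn{d_i \in \{0, 1, 2\}} is the risk-allele dosage and \eqn{w_i}
#' the SNP's log odds-ratio weight. Sums run over the child's non-missing
#' SNPs only, with the denominator restricted to the same SNPs, so a missing
#' genotype renormalises rather than deflates the score. Children missing
#' more than \code{missing_ceiling} of the weight-table SNPs are flagged and
#' receive an undefined (\code{NA}) score, never a silent zero.
#'
#' @param dosages numeric matrix (children x SNPs) of risk-allele dosages in
#'   \{0, 1, 2\} with \code{NA} for missing; column names are SNP ids, row
#'   names child ids. SNP columns absent from \code{weights} are an error.
#' @param weights a weight table (see [read_weight_table()]).
#' @param missing_ceiling maximum tolerated fraction of missing SNPs per
#'   child (default 0.2).
#' @return data frame with columns \code{child_id}, \code{score},
#'   \code{n_missing}, \code{flagged}.
#' @examples
#' w <- default_weight_table()
#' d <- matrix(1, nrow = 2, ncol = nrow(w), dimnames = list(c("a", "b"), w$snp_id))
#' compute_grs(d, w)$score # both 0.5
#' @export
compute_grs <- function(dosages, weights, missing_ceiling = 0.2) {
  if (is.data.frame(dosages)) dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages)))
    stop_("dosage matrix must have SNP ids as column names")
  unknown <- setdiff(colnames(dosages), weights$snp_id)
  if (length(unknown) > 0)
    stop_("unknown SNP id(s) not present in the weight table: ",
          paste(unknown, collapse = ", "))
  if (any(!is.na(dosages) & !(dosages %in% c(0, 1, 2))))
    stop_("dosages must be 0, 1, 2 or NA")
  child_id <- rownames(dosages) %||% as.character(seq_len(nrow(dosages)))
  w <- weights$weight[match(colnames(dosages), weights$snp_id)]
  obs <- !is.na(dosages)
  d0 <- dosages
  d0[!obs] <- 0
  num <- as.numeric(d0 %*% w)
  den <- 2 * as.numeric(obs %*% w)
  n_snp_total <- nrow(weights)
  # SNPs absent from the matrix count as missing for every child
  n_missing <- (n_snp_total - ncol(dosages)) + rowSums(!obs)
  flagged <- n_missing / n_snp_total > missing_ceiling
  score <- ifelse(flagged | den == 0, NA_real_, num / den)
  data.frame(child_id = child_id, score = score,
             n_missing = as.integer(n_missing), flagged = flagged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Calibrate genetic-risk-score centile thresholds
#'
#' Derives the low/moderate and moderate/high classification cut-offs as
#' empirical centiles (default 5th and 50th) of a reference cohort of
#' gold-standard type 1 diabetes scores, using the linear-interpolation
#' (type 7) quantile convention. With no reference supplied, the published
#' threshold pair (0.234, 0.280) is returned unchanged.
#'
#' @param reference_scores numeric vector of at least 100 finite reference
#'   scores, or \code{NULL} for the published defaults.
#' @param centiles length-2 numeric vector of centiles, default \code{c(5, 50)}.
#' @return object of class \code{grs_reference}: list with sorted
#'   \code{scores}, \code{threshold_low}, \code{threshold_high}.
#' @export
calibrate_thresholds <- function(reference_scores = NULL, centiles = c(5, 50)) {
  if (length(centiles) != 2 || centiles[1] >= centiles[2])
    stop_("centiles must be an increasing pair")
  if (is.null(reference_scores)) {
    ref <- list(scores = numeric(0), threshold_low = 0.234,
                threshold_high = 0.280, centiles = centiles)
  } else {
    if (length(reference_scores) < 100)
      stop_("need at least 100 reference scores for a stable tail centile")
    if (any(!is.finite(reference_scores)))
      stop_("reference scores must all be finite")
    s <- sort(reference_scores)
    thr <- emp_quantile(s, centiles / 100)
    ref <- list(scores = s, threshold_low = thr[1], threshold_high = thr[2],
                centiles = centiles)
  }
  if (ref$threshold_low >= ref$threshold_high)
    stop_("degenerate reference: low threshold not below high threshold")
  class(ref) <- "grs_reference"
  ref
}

#' @export
print.grs_reference <- function(x, ...) {
  src <- if (length(x$scores) == 0) "published defaults" else
    sprintf("empirical centiles of %d reference scores", length(x$scores))
  cat(sprintf("GRS reference (%s): low < %.3f <= moderate <= %.3f < high\n",
              src, x$threshold_low, x$threshold_high))
  invisible(x)
}

#' Assign low / moderate / high genetic-risk categories
#'
#' Categories follow the closed moderate interval: \code{low} strictly below
#' the low threshold, \code{high} strictly above the high threshold, and
#' \code{moderate} for scores on or between the two thresholds (both
#' boundaries belong to moderate). Undefined scores (children over the
#' missingness ceiling) propagate as \code{NA}.
#'
#' @param score numeric vector of scores (may contain \code{NA}).
#' @param ref a \code{grs_reference} from [calibrate_thresholds()].
#' @return character vector in \{"low", "moderate", "high", NA\}.
#' @examples
#' ref <- calibrate_thresholds()
#' categorize_grs(c(0.233, 0.234, 0.280, 0.2801), ref)
#' @export
categorize_grs <- function(score, ref) {
  stopifnot(inherits(ref, "grs_reference"))
  out <- rep(NA_character_, length(score))
  out[!is.na(score) & score < ref$threshold_low] <- "low"
  out[!is.na(score) & score >= ref$threshold_low &
        score <= ref$threshold_high] <- "moderate"
  out[!is.na(score) & score > ref$threshold_high] <- "high"
  out
}

#' Centile of a score within the reference distribution
#'
#' Empirical centile: 100 times the fraction of reference scores less than
#' or equal to the score. \code{NA} when the reference carries no scores
#' (published-default thresholds).
#'
#' @param score numeric vector.
#' @param ref a \code{grs_reference}.
#' @return numeric vector in \code{[0, 100]}.
#' @export
grs_centile <- function(score, ref) {
  stopifnot(inherits(ref, "grs_reference"))
  if (length(ref$scores) == 0) return(rep(NA_real_, length(score)))
  vapply(score, function(s) {
    if (is.na(s)) NA_real_ else 100 * mean(ref$scores <= s)
  }, numeric(1))
}

#' Score a genotyped cohort and attach centiles and categories
#'
#' Convenience wrapper: [compute_grs()] then [grs_centile()] and
#' [categorize_grs()] against a reference.
#'
#' @inheritParams compute_grs
#' @param ref a \code{grs_reference}; defaults to the published thresholds.
#' @return data frame with columns \code{child_id}, \code{score},
#'   \code{n_missing}, \code{flagged}, \code{centile}, \code{category}.
#' @export
score_cohort <- function(dosages, weights, ref = calibrate_thresholds(),
                         missing_ceiling = 0.2) {
  res <- compute_grs(dosages, weights, missing_ceiling)
  res$centile <- grs_centile(res$score, ref)
  res$category <- categorize_grs(res$score, ref)
  res
}

#' Compare two score distributions
#'
#' Medians and interquartile ranges (type 7 quantiles, the same convention
#' as threshold calibration) plus Mann-Whitney and two-sample
#' Kolmogorov-Smirnov tests, as used to check that a clinic cohort's
#' definite type 1 diabetes scores match the external reference cohort.
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @return list with \code{median_x}, \code{iqr_x}, \code{median_y},
#'   \code{iqr_y} (each IQR a length-2 vector), \code{mw_U}, \code{mw_p},
#'   \code{ks_D}, \code{ks_p}.
#' @export
compare_grs_distributions <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop_("both samples need at least 2 observations")
  mw <- mann_whitney(x, y)
  ks <- ks_two_sample(x, y)
  list(median_x = median(x), iqr_x = emp_quantile(x, c(0.25, 0.75)),
       median_y = median(y), iqr_y = emp_quantile(y, c(0.25, 0.75)),
       mw_U = mw$U, mw_p = mw$p, ks_D = ks$D, ks_p = ks$p)
}
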