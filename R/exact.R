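# Exact and classical inference for 2x2 tables and small samples.
#
# Conventions used throughout:
#   * a 2x2 table has rows = criterion present/absent and
#     columns = case group / comparison group:
#         [ a  b ]
#         [ c  d ]
#   * conditioning on both margins, the (1,1) cell follows the (noncentral)
#     hypergeometric distribution with support max(0, k - n2) .. min(k, m1)
#     where m1 = a + b, n2 = c + d, k = a + c.

as_table2x2 <- function(tab) {
  if (is.matrix(tab)) {
    if (!all(dim(tab) == c(2, 2))) stop_("table must be 2x2")
    tab <- as.vector(t(tab)) # a, b, c, d
  }
  if (length(tab) != 4) stop_("supply a 2x2 matrix or counts a, b, c, d")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop_("cell counts must be non-negative integers")
  if (sum(tab) == 0) stop_("table total must be positive")
  as.numeric(tab)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact interval by beta-quantile inversion:
#' lower = \code{qbeta(alpha/2, x, n - x + 1)} (0 when x = 0),
#' upper = \code{qbeta(1 - alpha/2, x + 1, n - x)} (1 when x = n).
#'
#' @param x number of successes, \code{0 <= x <= n}.
#' @param n number of trials, \code{n >= 1}.
#' @param confidence confidence level in (0, 1), default 0.95.
#' @return named numeric vector \code{c(low, high)} on the proportion scale.
#' @examples
#' clopper_pearson(34, 1093) # 0.022 to 0.043
#' @export
clopper_pearson <- function(x, n, confidence = 0.95) {
  if (n < 1 || x < 0 || x > n || x != round(x) || n != round(n))
    stop_("need integers 0 <= x <= n with n >= 1")
  if (confidence <= 0 || confidence >= 1)
    stop_("confidence must be in (0, 1)")
  alpha <- 1 - confidence
  low <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(low = low, high = high)
}

#' Two-tailed Fisher's exact test
#'
#' Exact enumeration over the conditional (hypergeometric) support: the
#' two-sided p value is the total probability of all tables with the
#' observed margins whose probability does not exceed that of the observed
#' table (probability-mass method, relative tie tolerance 1e-7).
#'
#' @param tab 2x2 matrix of counts, or length-4 vector \code{c(a, b, c, d)}
#'   read row-wise.
#' @return the two-tailed p value.
#' @examples
#' fisher_exact(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)) # 1/3
#' @export
fisher_exact <- function(tab) {
  v <- as_table2x2(tab)
  a <- v[1]; b <- v[2]; c <- v[3]; d <- v[4]
  m1 <- a + b; n2 <- c + d; k <- a + c
  if (m1 == 0 || n2 == 0 || k == 0 || (b + d) == 0) {
    warning("zero margin: Fisher p = 1 by convention")
    return(1)
  }
  s <- max(0, k - n2):min(k, m1)
  pr <- dhyper(s, m1, n2, k)
  p_obs <- dhyper(a, m1, n2, k)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# normalised noncentral hypergeometric pmf over the conditional support,
# parameterised by log odds ratio
nchg_pmf <- function(m1, n2, k, log_or) {
  s <- max(0, k - n2):min(k, m1)
  lw <- lchoose(m1, s) + lchoose(n2, k - s) + s * log_or
  w <- exp(lw - max(lw))
  list(s = s, p = w / sum(w))
}

#' Exact odds ratio with confidence interval for a 2x2 table
#'
#' Point estimate: the conditional maximum-likelihood odds ratio under the
#' noncentral hypergeometric model (the estimate consistent with the exact
#' conditional test), found by solving \code{E[a | or] = a} on the log scale.
#' Confidence limits invert the one-sided exact conditional tests at
#' \code{(1 - confidence) / 2} each (Cornfield-style), by root-finding to
#' 1e-8 on the log-odds-ratio scale. The sample cross-product odds ratio
#' \code{(a d) / (b c)} is also reported for transparency.
#'
#' When the observed cell sits at the boundary of its conditional support
#' (one zero cell) the point estimate is 0 or infinity and the interval is
#' one-sided. Two zero cells in the same row or column leave the odds ratio
#' undefined and raise an error.
#'
#' @inheritParams fisher_exact
#' @param confidence confidence level, default 0.95.
#' @return list with \code{or} (conditional MLE), \code{ci_low},
#'   \code{ci_high}, \code{sample_or}.
#' @export
odds_ratio_exact <- function(tab, confidence = 0.95) {
  v <- as_table2x2(tab)
  a <- v[1]; b <- v[2]; c <- v[3]; d <- v[4]
  m1 <- a + b; n2 <- c + d; k <- a + c
  if (m1 == 0 || n2 == 0 || k == 0 || (b + d) == 0)
    stop_("odds ratio undefined: a table margin is zero")
  if (confidence <= 0 || confidence >= 1) stop_("confidence must be in (0, 1)")
  alpha <- 1 - confidence
  smin <- max(0, k - n2); smax <- min(k, m1)
  L <- 45 # log-OR search bound; e^45 is numerically +infinity here
  cond_mean <- function(log_or) {
    f <- nchg_pmf(m1, n2, k, log_or)
    sum(f$s * f$p)
  }
  or <- if (a <= smin) 0 else if (a >= smax) Inf else
    exp(uniroot(function(lo) cond_mean(lo) - a, c(-L, L), tol = 1e-10)$root)
  p_le <- function(log_or) { f <- nchg_pmf(m1, n2, k, log_or); sum(f$p[f$s <= a]) }
  p_ge <- function(log_or) { f <- nchg_pmf(m1, n2, k, log_or); sum(f$p[f$s >= a]) }
  ci_low <- if (a <= smin) 0 else
    exp(uniroot(function(lo) p_ge(lo) - alpha / 2, c(-L, L), tol = 1e-8)$root)
  ci_high <- if (a >= smax) Inf else
    exp(uniroot(function(lo) p_le(lo) - alpha / 2, c(-L, L), tol = 1e-8)$root)
  sample_or <- (a * d) / (b * c)
  list(or = or, ci_low = ci_low, ci_high = ci_high, sample_or = sample_or)
}

#' Two-sample test for equality of proportions
#'
#' Pooled-variance normal z test without continuity correction:
#' \deqn{z = (p_1 - p_2) / \sqrt{\bar p (1 - \bar p)(1/n_1 + 1/n_2)}}
#' with two-sided p value. A degenerate pooled proportion (0 or 1) gives
#' p = 1 with a warning.
#'
#' @param x1,n1 successes and trials in the first sample.
#' @param x2,n2 successes and trials in the second sample.
#' @return list with \code{z} and \code{p}.
#' @export
two_sample_proportion <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1 || x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2)
    stop_("need 0 <= x <= n with n >= 1 in both samples")
  pbar <- (x1 + x2) / (n1 + n2)
  if (pbar == 0 || pbar == 1) {
    warning("degenerate pooled proportion: p = 1")
    return(list(z = 0, p = 1))
  }
  z <- (x1 / n1 - x2 / n2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# exact null distribution of the rank sum of x within c(x, y):
# counts subsets by (size, doubled mid-rank sum) with a dynamic programme,
# so ties are handled exactly
rank_sum_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y); N <- nx + ny
  r2 <- as.integer(round(2 * rank(c(x, y))))
  w_obs <- sum(r2[seq_len(nx)])
  S <- sum(r2)
  cnt <- matrix(0, nrow = nx + 1, ncol = S + 1)
  cnt[1, 1] <- 1
  for (v in r2) {
    for (kk in seq(nx, 1)) {
      cnt[kk + 1, (v + 1):(S + 1)] <- cnt[kk + 1, (v + 1):(S + 1)] +
        cnt[kk, 1:(S + 1 - v)]
    }
  }
  prob <- cnt[nx + 1, ] / choose(N, nx)
  p_le <- sum(prob[seq_len(w_obs + 1)])
  p_ge <- sum(prob[(w_obs + 1):(S + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Mann-Whitney U test
#'
#' U statistic with mid-ranks for ties. The p value is exact — computed by
#' full enumeration of the conditional rank-sum distribution (a subset-sum
#' dynamic programme, so ties are exact too) — whenever
#' \code{length(x) * length(y) <= 400}; larger samples use the normal
#' approximation with tie correction and no continuity correction. The
#' two-sided exact p is twice the smaller tail, capped at 1.
#'
#' @param x,y non-empty numeric vectors.
#' @return list with \code{U}, \code{p} and \code{exact} (logical).
#' @examples
#' mann_whitney(1:3, 4:6) # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop_("both samples must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  U <- W - nx * (nx + 1) / 2
  if (nx * ny <= 400) {
    p <- rank_sum_exact_p(x, y)
    return(list(U = U, p = p, exact = TRUE))
  }
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- nx * ny / 12 * ((N + 1) - tie_term)
  if (sigma2 == 0) return(list(U = U, p = 1, exact = FALSE))
  z <- (U - nx * ny / 2) / sqrt(sigma2)
  list(U = U, p = 2 * pnorm(-abs(z)), exact = FALSE)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical distribution
#' functions. The p value is exact (conditional on the tie pattern) when
#' \code{length(x) * length(y) <= 400}, otherwise from the asymptotic
#' Kolmogorov distribution; both branches delegate the p value computation
#' to \code{stats::ks.test}.
#'
#' @param x,y non-empty numeric vectors.
#' @return list with \code{D}, \code{p} and \code{exact} (logical).
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop_("both samples must be non-empty")
  pts <- sort(unique(c(x, y)))
  ex <- vapply(pts, function(t) mean(x <= t), numeric(1))
  ey <- vapply(pts, function(t) mean(y <= t), numeric(1))
  D <- max(abs(ex - ey))
  exact <- length(x) * length(y) <= 400
  p <- suppressWarnings(ks.test(x, y, exact = exact)$p.value)
  list(D = D, p = p, exact = exact)
}
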