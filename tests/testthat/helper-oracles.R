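# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths of the implementation (choose() products instead of
# dhyper(), combn() enumeration instead of dynamic programming, grid
# bisection instead of uniroot).

# hypergeometric probabilities of every table with the observed margins,
# via explicit binomial coefficients
oracle_hyper_probs <- function(m1, n2, k) {
  s <- max(0, k - n2):min(k, m1)
  pr <- choose(m1, s) * choose(n2, k - s) / choose(m1 + n2, k)
  list(s = s, pr = pr)
}

# probability-mass two-sided Fisher p for cell a with margins (m1, n2, k)
oracle_fisher_p <- function(a, m1, n2, k) {
  h <- oracle_hyper_probs(m1, n2, k)
  p_obs <- h$pr[h$s == a]
  sum(h$pr[h$pr <= p_obs * (1 + 1e-7)])
}

# two-sided exact Mann-Whitney p by full combn() enumeration of rank sums
oracle_mw_p <- function(x, y) {
  nx <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  w_obs <- sum(r[seq_len(nx)])
  ws <- apply(combn(length(pool), nx), 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
}

ks_D_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# exact conditional KS p by full combn() enumeration of D
oracle_ks_p <- function(x, y) {
  nx <- length(x)
  pool <- c(x, y)
  d_obs <- ks_D_stat(x, y)
  ds <- apply(combn(length(pool), nx), 2,
              function(i) ks_D_stat(pool[i], pool[-i]))
  mean(ds >= d_obs - 1e-12)
}

# type 7 quantile by explicit sort-and-interpolate
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# noncentral hypergeometric upper/lower tail at odds ratio `or`, computed
# with explicit binomial coefficients
oracle_nchg_tail <- function(a, m1, n2, k, or, upper = TRUE) {
  s <- max(0, k - n2):min(k, m1)
  w <- choose(m1, s) * choose(n2, k - s) * or^s
  w <- w / sum(w)
  if (upper) sum(w[s >= a]) else sum(w[s <= a])
}

# exact conditional OR confidence limits by bisection on the odds-ratio
# scale to a relative tolerance of 1e-4
oracle_or_ci_grid <- function(a, b, c, d, conf = 0.95) {
  m1 <- a + b; n2 <- c + d; k <- a + c
  alpha <- 1 - conf
  bisect <- function(f, lo, hi) {
    for (i in 1:80) {
      mid <- sqrt(lo * hi)
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi / lo < 1 + 1e-6) break
    }
    sqrt(lo * hi)
  }
  smin <- max(0, k - n2); smax <- min(k, m1)
  low <- if (a <= smin) 0 else
    bisect(function(or) oracle_nchg_tail(a, m1, n2, k, or, upper = TRUE) - alpha / 2,
           1e-8, 1e8)
  high <- if (a >= smax) Inf else
    bisect(function(or) -(oracle_nchg_tail(a, m1, n2, k, or, upper = FALSE) - alpha / 2),
           1e-8, 1e8)
  c(low = low, high = high)
}

# minimal phenotype frame builder for triage / criteria tests
make_children <- function(n, ...) {
  base <- data.frame(
    child_id = sprintf("c%03d", seq_len(n)),
    age_at_diagnosis = 8,
    antibody_status = "negative",
    insulin_treated = TRUE,
    clinically_diagnosed_t1d = TRUE,
    parent_with_diabetes = FALSE,
    hba1c_mmol_mol = 75,
    mody_probability = 0.01,
    parental_consanguinity = FALSE,
    extra_pancreatic_features = "",
    grs_category = "moderate",
    stringsAsFactors = FALSE)
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  base
}
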