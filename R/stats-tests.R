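#' k-sample proportion test (Pearson chi-square, no continuity correction)
#'
#' Pearson chi-square of the k x 2 success/failure table against the
#' pooled proportion, with `df = k - 1`. No continuity correction is
#' applied for k-sample comparisons; the two-sample test with Yates
#' correction is [chisq_two_prop_yates()].
#'
#' @param x success counts (length k >= 2).
#' @param n totals (length k).
#' @return list with `statistic`, `df`, `p_value`, `proportions`,
#'   `pooled`.
#' @export
chisq_proportions_k <- function(x, n) {
  if (length(x) < 2L || length(x) != length(n)) {
    stop("x and n must have equal length >= 2")
  }
  if (any(x < 0) || any(x > n)) stop("need 0 <= x <= n")
  p <- sum(x) / sum(n)
  if (p <= 0 || p >= 1) stop("degenerate table: pooled proportion 0 or 1")
  e1 <- n * p
  e0 <- n * (1 - p)
  stat <- sum((x - e1)^2 / e1 + ((n - x) - e0)^2 / e0)
  df <- length(x) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       proportions = x / n, pooled = p)
}

#' Two-sample proportion test with Yates continuity correction
#'
#' For the 2x2 table with cells `a = x1`, `b = n1 - x1`, `c = x2`,
#' `d = n2 - x2` and total `N`, the statistic is
#' \deqn{N (\max(|ad - bc| - N/2, 0))^2 / (r_1 r_2 c_1 c_2)}
#' with the correction capped so the corrected difference is never
#' negative; `df = 1`.
#'
#' @param x1,n1 successes and total of group 1.
#' @param x2,n2 successes and total of group 2.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chisq_two_prop_yates <- function(x1, n1, x2, n2) {
  # numeric arithmetic throughout: the cross-product terms overflow
  # 32-bit integers already at moderate sample sizes
  a <- as.numeric(x1); b <- as.numeric(n1) - a
  c <- as.numeric(x2); d <- as.numeric(n2) - c
  if (min(a + b, c + d, a + c, b + d) <= 0) stop("zero margin in 2x2 table")
  N <- a + b + c + d
  num <- N * max(abs(a * d - b * c) - N / 2, 0)^2
  stat <- num / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Two-sided p value by summing, over all tables with the observed
#' margins, the hypergeometric probabilities no larger than that of the
#' observed table (with a small relative tolerance for ties).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  a <- table[1L, 1L]
  r1 <- sum(table[1L, ]); r2 <- sum(table[2L, ])
  c1 <- sum(table[, 1L])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == sum(table)) return(1)
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-07)])
}

#' Spearman rank correlation with midranks
#'
#' Pearson correlation of midranks; the p value uses the t approximation
#' with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `statistic` (t), `df`, `p_value`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, statistic = tstat, df = n - 2L,
       p_value = 2 * stats::pt(-abs(tstat), n - 2L))
}

#' Monte-Carlo chi-square test of a contingency table
#'
#' Pearson statistic on the observed table; the p value is estimated by
#' simulating tables with the observed margins (equivalently, random
#' permutation of category labels), with the add-one estimator
#' `(1 + #{simulated >= observed}) / (n_sim + 1)` so p is never zero.
#'
#' @param tab contingency matrix (2x2 or larger).
#' @param n_sim number of simulated tables.
#' @param seed integer seed; the p value is reproducible given the seed.
#' @return list with `statistic`, `p_value`, `n_sim`.
#' @export
mc_chisq <- function(tab, n_sim = 10000L, seed = 1L) {
  stopifnot(is.matrix(tab), all(tab >= 0))
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero margin in contingency table")
  }
  E <- outer(rs, cs) / sum(tab)
  pearson <- function(m) sum((m - E)^2 / E)
  stat <- pearson(tab)
  set.seed(as.integer(seed))
  sims <- stats::r2dtable(n_sim, rs, cs)
  ge <- sum(vapply(sims, pearson, numeric(1L)) >= stat - 1e-12)
  list(statistic = stat, p_value = (1 + ge) / (n_sim + 1), n_sim = n_sim)
}

#' Welch two-sample t test
#'
#' Welch statistic with Satterthwaite degrees of freedom; reported as
#' `mean(a) - mean(b)` in the numerator, so swapping the groups negates
#' `t`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb == 0) stop("zero variance in both groups")
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df),
       mean_a = mean(a), mean_b = mean(b))
}
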