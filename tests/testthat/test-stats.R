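test_that("k-sample proportion statistic matches the cell-sum oracle and
           base R", {
  res <- chisq_proportions_k(c(0, 0, 29, 18), rep(36, 4))
  expect_equal(round(res$statistic, 2), 77.42)
  expect_equal(res$df, 3L)
  expect_lt(res$p_value, 1e-04)
  # identical proportions: zero
  expect_equal(chisq_proportions_k(c(5, 5), c(10, 10))$statistic, 0)
  # the published four-species foreign-proportion inputs
  res2 <- chisq_proportions_k(c(2176, 2090, 3821, 5242),
                              c(20852, 22130, 29770, 37071))
  expect_equal(round(res2$statistic, 1), 360.2)
  # base-R cross-check without continuity correction
  ref <- stats::prop.test(c(2176, 2090, 3821, 5242),
                          c(20852, 22130, 29770, 37071), correct = FALSE)
  expect_equal(res2$statistic, unname(ref$statistic))
  expect_error(chisq_proportions_k(c(0, 0), c(5, 5)), "degenerate")
})

test_that("Yates-corrected 2x2 statistic reproduces the published values and
           agrees with base R on random tables", {
  expect_equal(round(chisq_two_prop_yates(0, 36, 29, 36)$statistic, 2), 45.27)
  expect_equal(round(chisq_two_prop_yates(0, 36, 18, 36)$statistic, 2), 21.41)
  expect_equal(round(chisq_two_prop_yates(29, 36, 18, 36)$statistic, 2), 6.13)
  expect_equal(chisq_two_prop_yates(7, 20, 7, 20)$statistic, 0)
  set.seed(20)
  for (i in 1:25) {
    n1 <- sample(10:60, 1L); n2 <- sample(10:60, 1L)
    x1 <- sample.int(n1 - 1L, 1L); x2 <- sample.int(n2 - 1L, 1L)
    mine <- chisq_two_prop_yates(x1, n1, x2, n2)
    ref <- suppressWarnings(
      stats::prop.test(c(x1, x2), c(n1, n2), correct = TRUE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-09)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-09)
  }
  expect_error(chisq_two_prop_yates(0, 36, 0, 36), "margin")
})

test_that("two- and k-sample statistics agree with a direct (O-E)^2/E oracle", {
  pearson_oracle <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
  }
  set.seed(77)
  for (i in 1:20) {
    k <- sample(2:5, 1L)
    n <- sample(20:80, k, replace = TRUE)
    x <- vapply(n, function(m) sample.int(m - 1L, 1L), integer(1L))
    tab <- cbind(x, n - x)
    expect_equal(chisq_proportions_k(x, n)$statistic, pearson_oracle(tab),
                 tolerance = 1e-09)
  }
})

test_that("Fisher's exact test equals full enumeration for small margins", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2L)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2L)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2L, byrow = TRUE)), 1)
  # enumeration oracle over all tables with the observed margins
  enum_oracle <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    a_range <- max(0, c1 - r2):min(r1, c1)
    p <- vapply(a_range, function(a) {
      choose(r1, a) * choose(r2, c1 - a) / choose(r1 + r2, c1)
    }, numeric(1L))
    sum(p[p <= p[a_range == tab[1, 1]] * (1 + 1e-07)])
  }
  set.seed(14)
  for (i in 1:30) {
    tab <- matrix(sample(0:12, 4L, replace = TRUE), 2L)
    if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) next
    expect_equal(fisher_exact_2x2(tab), enum_oracle(tab), tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-09)
  }
})

test_that("Spearman with midranks matches the rank formula and base R", {
  expect_equal(spearman_cor(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)
  set.seed(3)
  x <- stats::rnorm(40)
  y <- x + stats::rnorm(40)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  mine <- spearman_cor(x, y)
  expect_equal(mine$rho, unname(ref$estimate))
  # ties handled by midranks, matching cor(rank, rank)
  xt <- c(1, 1, 2, 3, 3, 4)
  yt <- c(2, 1, 2, 5, 4, 6)
  expect_equal(spearman_cor(xt, yt)$rho, stats::cor(rank(xt), rank(yt)))
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("Monte-Carlo chi-square is reproducible and converges to the
           asymptotic p", {
  tab <- matrix(c(3, 14, 94, 3420), 2L, byrow = TRUE)
  res <- mc_chisq(tab, n_sim = 2000L, seed = 5)
  expect_equal(round(res$statistic, 2), 14.2)   # oracle: direct (O-E)^2/E
  expect_equal(res$p_value, mc_chisq(tab, n_sim = 2000L, seed = 5)$p_value)
  expect_gt(res$p_value, 0)
  # homogeneous table
  expect_equal(mc_chisq(matrix(c(10, 10, 10, 10), 2L), seed = 1,
                        n_sim = 200L)$statistic, 0)
  expect_error(mc_chisq(matrix(c(0, 0, 5, 5), 2L, byrow = TRUE)), "margin")
  # large-count table: simulated p within Monte-Carlo error of chi-square p
  big <- matrix(c(60, 40, 45, 70), 2L, byrow = TRUE)
  stat <- mc_chisq(big, n_sim = 10L, seed = 1)$statistic
  p_asym <- stats::pchisq(stat, 1L, lower.tail = FALSE)
  res_big <- mc_chisq(big, n_sim = 1e05, seed = 9)
  se <- sqrt(p_asym * (1 - p_asym) / 1e05)
  expect_lt(abs(res_big$p_value - p_asym), 3 * se + 1e-04)
})

test_that("Welch t matches the closed form and is antisymmetric", {
  expect_equal(welch_t(c(4, 5, 6), c(4, 5, 6))$statistic, 0)
  expect_equal(round(welch_t(c(1, 2, 3), c(4, 5, 6))$statistic, 3), -3.674)
  a <- stats::rnorm(12, 5); b <- stats::rnorm(20, 6)
  mine <- welch_t(a, b)
  ref <- stats::t.test(a, b)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$df, unname(ref$parameter))
  expect_equal(mine$p_value, ref$p.value)
  expect_equal(welch_t(b, a)$statistic, -mine$statistic)
  expect_error(welch_t(c(1, 1), c(1, 1)), "variance")
})

test_that("GC content counts unambiguous bases only", {
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ANGC"), 2 / 3)
  expect_equal(gc_content(c("AT", "GC")), c(0, 1))
  expect_error(gc_content("NNN"), "unambiguous")
})

test_that("PGLS reduces to OLS at lambda 0 and on a star tree, and fits the
           published inputs", {
  resp <- c(mag = 0.104, soc = 0.095, sor = 0.128, tar = 0.141)
  pred <- c(mag = 0, soc = 0, sor = 0.806, tar = 0.5)
  tree <- reference_tree()
  # lambda = 0 equals OLS on the transformed scale
  p0 <- pgls_arcsine(resp, pred, tree, lambda = 0)
  ols <- stats::lm(asin(sqrt(resp)) ~ asin(sqrt(pred)))
  expect_equal(p0$slope, unname(stats::coef(ols)[2L]), tolerance = 1e-09)
  expect_equal(p0$statistic, unname(summary(ols)$coefficients[2L, 3L]),
               tolerance = 1e-09)
  # star tree: lambda irrelevant, equals OLS
  star <- parse_dated_newick("(mag:10,soc:10,sor:10,tar:10);")
  p_star <- pgls_arcsine(resp, pred, star, lambda = 1)
  expect_equal(p_star$slope, unname(stats::coef(ols)[2L]), tolerance = 1e-09)
  # published four points at lambda = 1: hand-verified GLS slope (+0.0382);
  # the within-pair contrast is negative but the between-clade contrast
  # dominates under the Brownian weighting
  p1 <- pgls_arcsine(resp, pred, tree, lambda = 1)
  expect_equal(p1$slope, 0.03816083, tolerance = 1e-06)
  expect_error(pgls_arcsine(c(mag = 1.2, soc = 0, sor = 0, tar = 0), pred,
                            tree), "\\[0, 1\\]")
})

test_that("PGLS with fixed lambda matches nlme::gls with a Pagel
           correlation", {
  skip_if_not_installed("nlme")
  set.seed(21)
  phy <- ape::rcoal(12)
  phy$edge.length <- phy$edge.length / max(ape::node.depth.edgelength(phy))
  tree <- dated_tree(phy, tol = 1e-6)
  x <- stats::runif(12, 0.1, 0.9)
  names(x) <- phy$tip.label
  y <- pmin(pmax(x + stats::rnorm(12, 0, 0.1), 0.01), 0.99)
  names(y) <- phy$tip.label
  for (lam in c(0.3, 0.8, 1)) {
    mine <- pgls_arcsine(y, x, tree, lambda = lam)
    d <- data.frame(ty = asin(sqrt(y)), tx = asin(sqrt(x)),
                    sp = phy$tip.label)
    ref <- nlme::gls(
      ty ~ tx, data = d,
      correlation = ape::corPagel(lam, phy, form = ~sp, fixed = TRUE))
    expect_equal(mine$slope, unname(stats::coef(ref)[2L]), tolerance = 1e-06)
    expect_equal(mine$statistic,
                 unname(summary(ref)$tTable[2L, "t-value"]),
                 tolerance = 1e-06)
  }
})

test_that("gc_trend recovers per-class deltas and the amelioration trend", {
  set.seed(6)
  classes <- c("unique", "sister", "genus", "shared_outgroup")
  n_per <- 40L
  cls <- rep(classes, each = n_per)
  sp <- rep("mag", length(cls))
  deltas_true <- c(unique = 0.12, sister = 0.08, genus = 0.04,
                   shared_outgroup = 0.01)
  gc <- 0.33 + deltas_true[cls] + stats::rnorm(length(cls), 0, 0.01)
  tr <- gc_trend(gc, sp, cls, background = c(mag = 0.33))
  expect_lt(tr$overall$rho, 0)
  expect_lt(tr$overall$p_value, 0.01)
  m <- unlist(tr$per_class["mag", ])
  expect_true(all(diff(m[classes]) < 0))
  expect_lt(max(abs(m - deltas_true[colnames(tr$per_class)])), 0.01)
})
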