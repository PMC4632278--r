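pm_row <- function(...) {
  v <- c(...)
  m <- matrix(v, 1L, 5L,
              dimnames = list("g", c(INGROUP_TAXA, OUTGROUP_TAXON)))
  m == 1L
}

test_that("parsimony-unambiguous gain and loss patterns are recognised", {
  ev <- reconstruct_events(pm_row(1, 0, 0, 0, 0))
  expect_equal(unname(ev$gains["mag"]), 1L)
  expect_equal(sum(ev$gains) + sum(ev$losses) + ev$ambiguous, 1L)

  ev <- reconstruct_events(pm_row(0, 0, 1, 1, 0))
  expect_equal(unname(ev$gains["stem_sortar"]), 1L)

  ev <- reconstruct_events(pm_row(1, 1, 1, 0, 1))
  expect_equal(unname(ev$losses["tar"]), 1L)

  ev <- reconstruct_events(pm_row(1, 1, 0, 0, 1))
  expect_equal(unname(ev$losses["stem_sortar"]), 1L)

  # single species + outgroup present: 2 gains vs 2 losses tie -> ambiguous
  ev <- reconstruct_events(pm_row(1, 0, 0, 0, 1))
  expect_equal(ev$ambiguous, 1L)
  # three species, outgroup absent: ambiguous
  ev <- reconstruct_events(pm_row(1, 1, 1, 0, 0))
  expect_equal(ev$ambiguous, 1L)
  # non-sister pair: ambiguous either way
  expect_equal(reconstruct_events(pm_row(1, 0, 1, 0, 0))$ambiguous, 1L)
  expect_equal(reconstruct_events(pm_row(1, 0, 1, 0, 1))$ambiguous, 1L)

  expect_error(reconstruct_events(pm_row(0, 0, 0, 0, 1)),
               "no ingroup presence")
})

test_that("event calls agree with an independent single-origin oracle on all
           31 patterns", {
  # Oracle: single-origin (Dollo) reconstruction computed from the tree
  # structure. The origin sits on the stem of the MRCA of the present
  # leaves; the minimum number of losses is the smallest set of complete
  # subtrees below the MRCA covering the absent leaves. A pattern is an
  # unambiguous single gain iff zero losses are needed and the origin stem
  # is one of the six tracked ingroup branches; an unambiguous single loss
  # iff exactly one pruned clade suffices, that clade's stem is tracked,
  # and the outgroup retains the gene (so the origin predates the ingroup
  # and the single-loss reading is not tied by a two-gain scenario).
  clades <- list(mag = "mag", soc = "soc", sor = "sor", tar = "tar",
                 stem_magsoc = c("mag", "soc"), stem_sortar = c("sor", "tar"),
                 ing = INGROUP_TAXA,
                 outgroup = OUTGROUP_TAXON,
                 root = c(INGROUP_TAXA, OUTGROUP_TAXON))
  min_prune <- function(absent) {
    # greedy from largest clades is exact on this nested hierarchy
    remaining <- absent
    k <- 0L
    for (cl in clades[order(-lengths(clades))]) {
      if (length(cl) <= length(remaining) && all(cl %in% remaining)) {
        remaining <- setdiff(remaining, cl)
        k <- k + 1L
      }
    }
    stopifnot(length(remaining) == 0L)
    k
  }
  dollo_oracle <- function(present) {
    absent <- setdiff(c(INGROUP_TAXA, OUTGROUP_TAXON), present)
    mrca <- names(clades)[order(lengths(clades))][
      which(vapply(clades[order(lengths(clades))],
                   function(cl) all(present %in% cl), logical(1L)))[1L]]
    below <- intersect(clades[[mrca]], absent)
    n_loss <- min_prune(below)
    tracked <- c("mag", "soc", "sor", "tar", "stem_magsoc", "stem_sortar")
    if (n_loss == 0L && mrca %in% tracked &&
        !(OUTGROUP_TAXON %in% present)) {
      return(list(call = "gain", branch = mrca))
    }
    if (n_loss == 1L && OUTGROUP_TAXON %in% present) {
      lost_clade <- names(clades)[vapply(clades, setequal, logical(1L),
                                         y = below)]
      if (length(lost_clade) == 1L && lost_clade %in% tracked) {
        return(list(call = "loss", branch = lost_clade))
      }
    }
    list(call = "ambiguous", branch = NA_character_)
  }
  for (mask in 1:(2^5 - 1L)) {
    leaf <- as.logical(bitwAnd(mask, 2^(0:4)))
    names(leaf) <- c(INGROUP_TAXA, OUTGROUP_TAXON)
    if (sum(leaf[INGROUP_TAXA]) == 0L) next
    pm <- matrix(leaf, 1L, 5L, dimnames = list("g", names(leaf)))
    ev <- reconstruct_events(pm)
    oracle <- dollo_oracle(names(leaf)[leaf])
    lbl <- paste(as.integer(leaf), collapse = "")
    if (oracle$call == "gain") {
      expect_equal(unname(ev$gains[oracle$branch]), 1L, label = lbl)
      expect_equal(sum(ev$gains) + sum(ev$losses), 1L, label = lbl)
    } else if (oracle$call == "loss") {
      expect_equal(unname(ev$losses[oracle$branch]), 1L, label = lbl)
      expect_equal(sum(ev$gains) + sum(ev$losses), 1L, label = lbl)
    } else {
      expect_equal(ev$ambiguous, 1L, label = lbl)
    }
  }
})

test_that("branch durations derive from the printed node ages", {
  d <- branch_durations(reference_tree())
  expect_equal(unname(d), c(6.9, 6.9, 14.2, 14.2, 22.1, 14.8))
  expect_equal(sum(d), 79.1)
  expect_error(branch_durations(
    parse_dated_newick("((mag:14.2,soc:14.2):0.0001,(sor:14.2,tar:14.2):0.0001);")),
    NA)  # tiny but positive stems are fine
  expect_error(reference_tree(root_age = 14.2, sortar_age = 14.2),
               "exceed")
})

test_that("HPD is the shortest window, checked against a full scan", {
  expect_equal(hpd_interval(rep(3.5, 10)), c(3.5, 3.5))
  expect_equal(hpd_interval(1:100, 0.95), c(1, 95))
  scan_oracle <- function(x, mass) {
    x <- sort(x)
    m <- ceiling(mass * length(x))
    widths <- vapply(seq_len(length(x) - m + 1L),
                     function(i) x[i + m - 1L] - x[i], numeric(1L))
    i <- which.min(widths)
    c(x[i], x[i + m - 1L])
  }
  set.seed(31)
  for (rep in 1:25) {
    x <- switch(1 + rep %% 3,
                stats::rnorm(200), stats::rexp(150), stats::rlnorm(120))
    expect_equal(hpd_interval(x, 0.95), scan_oracle(x, 0.95))
    expect_equal(hpd_interval(x, 0.5), scan_oracle(x, 0.5))
  }
  # uniform sample: interval width approaches the mass
  set.seed(8)
  u <- stats::runif(20000)
  w <- diff(hpd_interval(u, 0.95))
  expect_lt(abs(w - 0.95), 0.02)
  expect_error(hpd_interval(numeric(0)), "empty")
})

test_that("rate point estimates and HPDs behave as Poisson sampling", {
  tree <- reference_tree()
  ev <- event_counts(gains = c(mag = 46, soc = 90, sor = 201, tar = 211,
                               stem_magsoc = 53, stem_sortar = 247))
  r <- estimate_rates(ev, tree, seed = 1, n_draws = 4000L)
  pooled <- r[r$branch == "pooled" & r$type == "gain", ]
  expect_equal(pooled$rate, 848 / 79.1, tolerance = 1e-12)
  expect_true(pooled$hpd_low <= pooled$rate && pooled$rate <= pooled$hpd_high)
  # zero events: degenerate interval at zero
  r0 <- estimate_rates(event_counts(), tree, seed = 1, n_draws = 500L)
  expect_true(all(r0$rate == 0 & r0$hpd_low == 0 & r0$hpd_high == 0))
  # one branch with many events: normal approximation to the Poisson
  ev1 <- event_counts(gains = c(mag = 100))
  t1 <- reference_tree(root_age = 29, sortar_age = 14.2, magsoc_age = 10)
  r1 <- estimate_rates(ev1, t1, seed = 2, n_draws = 20000L)
  g1 <- r1[r1$branch == "mag" & r1$type == "gain", ]
  expect_equal(g1$hpd_low, (100 - 1.96 * 10) / 10, tolerance = 0.06)
  expect_equal(g1$hpd_high, (100 + 1.96 * 10) / 10, tolerance = 0.06)
})

test_that("rates scale inversely with a uniform duration rescaling", {
  ev <- event_counts(gains = c(mag = 12, sor = 30, stem_sortar = 7),
                     losses = c(tar = 4))
  r1 <- estimate_rates(ev, reference_tree(), seed = 3, n_draws = 200L)
  r2 <- estimate_rates(ev, reference_tree(2 * 29, 2 * 14.2, 2 * 6.9),
                       seed = 3, n_draws = 200L)
  expect_equal(r1$rate, 2 * r2$rate)
})

test_that("date uncertainty can be emulated from printed age intervals", {
  set.seed(12)
  trees <- simulate_tree_posterior(50)
  expect_true(isTRUE(attr(trees, "emulated_posterior")))
  roots <- vapply(trees, function(t) t$root_age, numeric(1L))
  expect_true(all(roots >= 23.6 & roots <= 35.7))
  ms <- vapply(trees, function(t) mrca_age(t, c("mag", "soc")), numeric(1L))
  st <- vapply(trees, function(t) mrca_age(t, c("sor", "tar")), numeric(1L))
  expect_true(all(ms < st & st < roots))
  ev <- event_counts(gains = c(mag = 46, soc = 90, sor = 201, tar = 211,
                               stem_magsoc = 53, stem_sortar = 247))
  r <- estimate_rates(ev, trees, seed = 4, n_draws = 4000L)
  pooled <- r[r$branch == "pooled" & r$type == "gain", ]
  # wider interval than with fixed dates, still centred near the point rate
  expect_true(pooled$hpd_low < pooled$rate && pooled$rate < pooled$hpd_high)
})
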