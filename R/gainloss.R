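#' Parsimony-unambiguous gains and losses on the reference topology
#'
#' On the rooted topology `((mag,soc),(sor,tar))` with an outgroup, a
#' presence pattern implies an unambiguous single gain iff the gene is
#' present only in one ingroup species (terminal gain) or exactly in both
#' members of one sister pair (stem gain), with the outgroup absent in
#' both cases. The inverse patterns imply unambiguous single losses:
#' absent from exactly one ingroup species (terminal loss) or exactly one
#' sister pair (stem loss), with the outgroup present. Any other pattern —
#' including single-species presence with the outgroup present, a
#' two-events-versus-two-events parsimony tie — is counted as ambiguous
#' and excluded from rate estimation.
#'
#' @param presence logical matrix (groups x `mag,soc,sor,tar,outgroup`).
#' @param sister_pairs sister-pair configuration.
#' @return list with `gains` and `losses` (named integer vectors over
#'   `mag`, `soc`, `sor`, `tar`, `stem_magsoc`, `stem_sortar`),
#'   `ambiguous` (count), `n` (rows), and `pattern` (per-row label).
#' @export
reconstruct_events <- function(presence, sister_pairs = SISTER_PAIRS) {
  taxa <- INGROUP_TAXA
  stopifnot(all(c(taxa, OUTGROUP_TAXON) %in% colnames(presence)))
  ing <- presence[, taxa, drop = FALSE]
  outg <- presence[, OUTGROUP_TAXON]
  if (any(rowSums(ing) == 0L)) {
    stop("presence row with no ingroup presence: ",
         paste(utils::head(rownames(presence)[rowSums(ing) == 0L], 5L),
               collapse = ", "))
  }
  branches <- c(taxa, paste0("stem_", names(sister_pairs)))
  gains <- losses <- stats::setNames(integer(length(branches)), branches)
  pattern <- rep("ambiguous", nrow(presence))
  nsp <- rowSums(ing)
  for (i in seq_len(nrow(presence))) {
    row <- ing[i, ]
    if (!outg[i]) {
      if (nsp[i] == 1L) {
        b <- taxa[which(row)]
        gains[b] <- gains[b] + 1L
        pattern[i] <- paste0("gain_", b)
        next
      }
      if (nsp[i] == 2L) {
        for (nm in names(sister_pairs)) {
          if (all(row[sister_pairs[[nm]]]) && nsp[i] == 2L) {
            b <- paste0("stem_", nm)
            gains[b] <- gains[b] + 1L
            pattern[i] <- paste0("gain_", b)
            break
          }
        }
        next
      }
    } else {
      if (nsp[i] == 3L) {
        b <- taxa[which(!row)]
        losses[b] <- losses[b] + 1L
        pattern[i] <- paste0("loss_", b)
        next
      }
      if (nsp[i] == 2L) {
        for (nm in names(sister_pairs)) {
          if (all(!row[sister_pairs[[nm]]]) &&
              all(row[setdiff(taxa, sister_pairs[[nm]])])) {
            b <- paste0("stem_", nm)
            losses[b] <- losses[b] + 1L
            pattern[i] <- paste0("loss_", b)
            break
          }
        }
        next
      }
    }
  }
  ambiguous <- sum(pattern == "ambiguous")
  list(gains = gains, losses = losses, ambiguous = ambiguous,
       n = nrow(presence), pattern = pattern)
}

#' Event counts container from explicit per-branch counts
#'
#' @param gains,losses named numeric vectors over the six ingroup branches
#'   (`mag`, `soc`, `sor`, `tar`, `stem_magsoc`, `stem_sortar`); missing
#'   names are zero.
#' @return list in the layout of [reconstruct_events()].
#' @export
event_counts <- function(gains = NULL, losses = NULL) {
  branches <- c(INGROUP_TAXA, paste0("stem_", names(SISTER_PAIRS)))
  g <- l <- stats::setNames(numeric(length(branches)), branches)
  if (!is.null(gains)) g[names(gains)] <- gains
  if (!is.null(losses)) l[names(losses)] <- losses
  if (any(g < 0) || any(l < 0)) stop("event counts must be >= 0")
  list(gains = g, losses = l, ambiguous = NA_integer_,
       n = NA_integer_, pattern = NULL)
}

#' Shortest interval containing a given probability mass
#'
#' The highest-density interval of a sample: the shortest contiguous
#' window over the sorted values containing `ceiling(mass * n)` points.
#'
#' @param samples numeric vector (length >= 1).
#' @param mass coverage, default 0.95.
#' @return numeric `c(low, high)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  if (length(samples) == 0L) stop("empty sample")
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1L], x[n]))
  spans <- x[(m):n] - x[seq_len(n - m + 1L)]
  i <- which.min(spans)
  c(x[i], x[i + m - 1L])
}

#' Sample dated trees from printed node-age intervals
#'
#' Emulates date uncertainty when no posterior tree sample is available:
#' node ages are drawn uniformly and independently within their 95\%
#' interval bounds, re-drawing any set that violates the ultrametric
#' ordering (root older than both pair crowns). This is an explicit
#' stand-in for a posterior sample and is labelled as such on the result.
#'
#' @param n number of trees.
#' @param age_hpd list with elements `root`, `sortar`, `magsoc`, each
#'   `c(low, high)` in My.
#' @return list of [dated_tree()] objects with attribute
#'   `"emulated_posterior" = TRUE`.
#' @export
simulate_tree_posterior <- function(n,
                                    age_hpd = default_config()$tree$age_hpd) {
  trees <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      root <- stats::runif(1L, age_hpd$root[1L], age_hpd$root[2L])
      sortar <- stats::runif(1L, age_hpd$sortar[1L], age_hpd$sortar[2L])
      magsoc <- stats::runif(1L, age_hpd$magsoc[1L], age_hpd$magsoc[2L])
      if (root > sortar && root > magsoc && sortar > magsoc) break
    }
    trees[[i]] <- reference_tree(root, sortar, magsoc)
  }
  attr(trees, "emulated_posterior") <- TRUE
  trees
}

#' Poisson rate estimates with HPD intervals for gains and losses
#'
#' Point estimates divide observed event counts by branch durations on the
#' maximum-credibility tree (the first tree, or the single tree supplied).
#' Uncertainty combines event sampling and date uncertainty: for each
#' draw, a tree is picked uniformly from `trees`, per-branch event counts
#' are resampled as `Poisson(observed)`, and rates are formed as
#' `k / duration`; clade (stem plus two terminals) and pooled rates use
#' summed counts over summed durations. The 95\% interval is the shortest
#' window containing 95\% of draws ([hpd_interval()]).
#'
#' @param events event counts from [reconstruct_events()] or
#'   [event_counts()].
#' @param trees a [dated_tree()] or list of them (posterior sample).
#' @param seed integer seed; all draws are reproducible.
#' @param n_draws Monte-Carlo draws.
#' @param mass HPD coverage.
#' @return `data.frame` with one row per (branch-or-aggregate, event type):
#'   `branch`, `type`, `events`, `duration`, `rate` (point estimate),
#'   `mean`, `hpd_low`, `hpd_high`, `n_draws`.
#' @export
estimate_rates <- function(events, trees, seed, n_draws = 10000L,
                           mass = 0.95) {
  if (inherits(trees, "dated_tree")) trees <- list(trees)
  if (length(trees) == 0L) stop("at least one tree is required")
  set.seed(as.integer(seed))
  durs <- lapply(trees, branch_durations)
  branches <- names(durs[[1L]])
  point_dur <- durs[[1L]]
  aggregates <- list(
    clade_magsoc = c("mag", "soc", "stem_magsoc"),
    clade_sortar = c("sor", "tar", "stem_sortar"),
    pooled = branches
  )
  tree_idx <- sample.int(length(trees), n_draws, replace = TRUE)
  dur_mat <- do.call(rbind, durs)            # trees x branches
  draw_dur <- dur_mat[tree_idx, , drop = FALSE]
  out <- list()
  for (type in c("gain", "loss")) {
    obs <- if (type == "gain") events$gains else events$losses
    obs <- obs[branches]
    k <- matrix(stats::rpois(n_draws * length(branches),
                             lambda = rep(obs, each = n_draws)),
                nrow = n_draws)
    colnames(k) <- branches
    rate_draws <- k / draw_dur
    units <- c(as.list(stats::setNames(branches, branches)), aggregates)
    for (nm in names(units)) {
      b <- units[[nm]]
      if (length(b) == 1L) {
        dr <- rate_draws[, b]
        pt <- obs[b] / point_dur[b]
        ev <- obs[b]; du <- point_dur[b]
      } else {
        dr <- rowSums(k[, b, drop = FALSE]) /
          rowSums(draw_dur[, b, drop = FALSE])
        pt <- sum(obs[b]) / sum(point_dur[b])
        ev <- sum(obs[b]); du <- sum(point_dur[b])
      }
      hpd <- hpd_interval(dr, mass)
      out[[length(out) + 1L]] <- data.frame(
        branch = nm, type = type, events = unname(ev), duration = unname(du),
        rate = unname(pt), mean = mean(dr),
        hpd_low = hpd[1L], hpd_high = hpd[2L],
        n_draws = n_draws, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
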