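TOPOLOGY_TEMPLATES <- c(
  "(((%1,%2),%3),%4);",
  "(%1,((%2,%3),%4));",
  "((%1,(%2,%3)),%4);",
  "(((%1,%3),%2),%4);",
  "((%1,%3),(%2,%4));",
  "(((%1,%2),%4),%3);",
  "(%1,((%2,%4),%3));",
  "((%1,(%2,%4)),%3);",
  "(((%1,%4),%3),%2);",
  "((%1,%4),(%2,%3));",
  "(((%1,%4),%2),%3);",
  "(%1,(%2,(%3,%4)));",
  "((%1,(%3,%4)),%2);",
  "(((%1,%3),%4),%2);",
  "((%1,%2),(%3,%4));"
)

#' Enumerate the 15 rooted topologies on four ingroup taxa
#'
#' Returns all 15 distinct rooted binary topologies for four labelled
#' leaves, in the reference numbering of the study (topology 15 is the
#' species topology `((mag,soc),(sor,tar))`, topology 1 is
#' `(((mag,soc),sor),tar)`).
#'
#' @param ingroup exactly four taxon labels, in the reference order.
#' @return character vector of 15 Newick strings.
#' @export
enumerate_topologies <- function(ingroup = INGROUP_TAXA) {
  if (length(ingroup) != 4L) stop("exactly 4 ingroup labels required")
  vapply(TOPOLOGY_TEMPLATES, function(tpl) {
    for (i in 1:4) tpl <- gsub(paste0("%", i), ingroup[i], tpl, fixed = TRUE)
    tpl
  }, character(1L), USE.NAMES = FALSE)
}

#' Canonical Newick form of a rooted tree
#'
#' Children at every node are sorted by the smallest leaf label they
#' contain, giving a deterministic string representation independent of
#' input rotation.
#'
#' @param phy a rooted `phylo` object (no branch lengths needed).
#' @return canonical Newick string (no branch lengths).
#' @export
canonical_newick <- function(phy) {
  n <- length(phy$tip.label)
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  rec <- function(node) {
    if (node <= n) {
      lab <- phy$tip.label[node]
      return(list(str = lab, min = lab))
    }
    ch <- lapply(kids[[as.character(node)]], rec)
    ch <- ch[order(vapply(ch, `[[`, character(1L), "min"))]
    list(str = paste0("(", paste(vapply(ch, `[[`, character(1L), "str"),
                                 collapse = ","), ")"),
         min = ch[[1L]]$min)
  }
  paste0(rec(n + 1L)$str, ";")
}

#' Classify a gene tree against the 15 reference topologies
#'
#' The tree is rooted on the outgroup taxon (if present), the outgroup is
#' dropped, and the ingroup topology is matched by canonical form against
#' [enumerate_topologies()]. Trees whose ingroup part is not fully
#' resolved (polytomies, e.g. from identical sequences) are
#' unclassifiable and return `NA`.
#'
#' @param tree a `phylo` object or Newick string over the four ingroup
#'   taxa, optionally plus the outgroup.
#' @param ingroup four ingroup labels in reference order.
#' @param outgroup outgroup label used for rooting.
#' @return topology index 1-15, or `NA_integer_` if unclassifiable.
#' @export
classify_topology <- function(tree, ingroup = INGROUP_TAXA,
                              outgroup = OUTGROUP_TAXON) {
  phy <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  if (is.null(phy)) stop("could not parse tree")
  if (outgroup %in% phy$tip.label) {
    if (!ape::is.rooted(phy) || length(phy$tip.label) > 2L) {
      phy <- tryCatch(ape::root(phy, outgroup = outgroup,
                                resolve.root = TRUE),
                      error = function(e) phy)
    }
    phy <- ape::drop.tip(phy, outgroup)
  }
  if (!setequal(phy$tip.label, ingroup)) {
    stop("tree tips {", paste(sort(phy$tip.label), collapse = ","),
         "} do not match the ingroup {", paste(ingroup, collapse = ","), "}")
  }
  if (!ape::is.binary(phy)) return(NA_integer_)
  canon <- canonical_newick(phy)
  refs <- vapply(enumerate_topologies(ingroup), function(s) {
    canonical_newick(ape::read.tree(text = s))
  }, character(1L))
  idx <- match(canon, refs)
  if (is.na(idx)) NA_integer_ else as.integer(idx)
}

#' Neighbor-joining gene tree from an aligned sequence set
#'
#' A desk-scale stand-in for maximum-likelihood gene-tree inference:
#' Jukes-Cantor distances (alignment columns containing a gap or ambiguity
#' in any taxon are excluded) followed by neighbor joining, rooted on the
#' outgroup.
#'
#' @param alignment named character vector of equal-length sequences over
#'   the five taxa (four ingroup plus outgroup).
#' @param outgroup label used for rooting.
#' @return rooted `phylo` object.
#' @export
build_nj_tree <- function(alignment, outgroup = OUTGROUP_TAXON) {
  if (length(alignment) < 3L) stop("at least 3 sequences required")
  if (length(unique(nchar(alignment))) != 1L) {
    stop("alignment sequences must have equal length")
  }
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(mat) <- names(alignment)
  dna <- ape::as.DNAbin(mat)
  d <- ape::dist.dna(dna, model = "JC69", pairwise.deletion = FALSE)
  if (any(!is.finite(as.matrix(d)[lower.tri(as.matrix(d))]))) {
    dm <- as.matrix(d)
    bad <- which(!is.finite(dm) & lower.tri(dm), arr.ind = TRUE)
    pairs <- apply(bad, 1L, function(ij) {
      paste(rownames(dm)[ij[1L]], colnames(dm)[ij[2L]], sep = "-")
    })
    stop("Jukes-Cantor distance undefined (p >= 0.75) for pair(s): ",
         paste(pairs, collapse = ", "))
  }
  phy <- ape::nj(d)
  if (outgroup %in% phy$tip.label) {
    phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  }
  # zero-length internal branches carry no signal: collapse to polytomies
  # so uninformative alignments come out unclassifiable rather than as an
  # arbitrary resolution
  ape::di2multi(phy, tol = 1e-10)
}

#' Tally gene-tree topologies for native and foreign ortholog sets
#'
#' @param native_trees,foreign_trees lists (or vectors) of trees accepted
#'   by [classify_topology()].
#' @param ingroup,outgroup taxon configuration.
#' @return `data.frame` with `topology` (1-15), `newick`, `native_n`,
#'   `native_pct`, `foreign_n`, `foreign_pct`; unclassifiable counts are
#'   attached as attribute `"unclassified"`.
#' @export
topology_tally <- function(native_trees, foreign_trees,
                           ingroup = INGROUP_TAXA,
                           outgroup = OUTGROUP_TAXON) {
  cls <- function(trees) {
    vapply(trees, classify_topology, integer(1L),
           ingroup = ingroup, outgroup = outgroup)
  }
  nat <- cls(native_trees)
  fo <- cls(foreign_trees)
  tab <- function(x) tabulate(x[!is.na(x)], nbins = 15L)
  nat_n <- tab(nat); fo_n <- tab(fo)
  out <- data.frame(
    topology = 1:15,
    newick = enumerate_topologies(ingroup),
    native_n = nat_n,
    native_pct = if (sum(nat_n) > 0) 100 * nat_n / sum(nat_n) else NA_real_,
    foreign_n = fo_n,
    foreign_pct = if (sum(fo_n) > 0) 100 * fo_n / sum(fo_n) else NA_real_,
    stringsAsFactors = FALSE
  )
  attr(out, "unclassified") <- c(native = sum(is.na(nat)),
                                 foreign = sum(is.na(fo)))
  out
}

#' Congruence of foreign versus native gene trees
#'
#' Tests whether the proportion of gene trees matching a focal topology
#' differs between the native and foreign ortholog sets, via the
#' Yates-corrected 2x2 proportion test.
#'
#' @param tally a [topology_tally()] `data.frame`, or a list with
#'   `native_n` and `foreign_n` count vectors.
#' @param focal_topology index of the focal topology (default 15, the
#'   species topology).
#' @return list with `statistic`, `df`, `p_value` and the underlying 2x2
#'   counts.
#' @export
congruence_test <- function(tally, focal_topology = 15L) {
  nat <- tally$native_n
  fo <- tally$foreign_n
  if (sum(nat) == 0L || sum(fo) == 0L) stop("both tree sets must be non-empty")
  res <- chisq_two_prop_yates(nat[focal_topology], sum(nat),
                              fo[focal_topology], sum(fo))
  res$counts <- matrix(c(nat[focal_topology], sum(nat) - nat[focal_topology],
                         fo[focal_topology], sum(fo) - fo[focal_topology]),
                       2L, byrow = TRUE,
                       dimnames = list(c("native", "foreign"),
                                       c("focal", "other")))
  res
}
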