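#' Ingroup taxa and sister pairs of the reference phylogeny
#'
#' The study system is four congeneric bdelloid rotifer species forming two
#' sister pairs, plus a family-level outgroup: `mag` and `soc` (permanently
#' aquatic) versus `sor` and `tar` (desiccating habitats).
#'
#' @export
INGROUP_TAXA <- c("mag", "soc", "sor", "tar")

#' @rdname INGROUP_TAXA
#' @export
SISTER_PAIRS <- list(magsoc = c("mag", "soc"), sortar = c("sor", "tar"))

#' @rdname INGROUP_TAXA
#' @export
OUTGROUP_TAXON <- "outgroup"

#' Construct a dated tree object
#'
#' A `dated_tree` wraps an ultrametric `phylo` object with node ages in
#' million years (root age minus node depth). Branch durations are the age
#' differences along edges.
#'
#' @param phy an ultrametric `phylo` object with branch lengths in My.
#' @param tol ultrametricity tolerance on leaf depths (My).
#' @return an object of class `dated_tree` with elements `phylo`, `tip_ages`
#'   (all zero), `root_age` and `node_ages` (ages of internal nodes, indexed
#'   as in `phy`).
#' @export
dated_tree <- function(phy, tol = 1e-6) {
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  depths <- ape::node.depth.edgelength(phy)
  ntip <- length(phy$tip.label)
  leaf_depths <- depths[seq_len(ntip)]
  if (diff(range(leaf_depths)) > tol) {
    stop("tree is not ultrametric within tolerance ", tol, "; leaf depths: ",
         paste(sprintf("%s=%g", phy$tip.label, leaf_depths), collapse = ", "))
  }
  root_age <- max(depths)
  ages <- root_age - depths
  if (any(phy$edge.length <= 0)) {
    stop("all branch durations must be > 0; found ",
         sum(phy$edge.length <= 0), " non-positive edges")
  }
  structure(
    list(phylo = phy, root_age = root_age, ages = ages),
    class = "dated_tree"
  )
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("Dated tree:", length(x$phylo$tip.label), "tips, root age",
      format(x$root_age), "My\n")
  cat("  tips:", paste(x$phylo$tip.label, collapse = ", "), "\n")
  invisible(x)
}

#' Read a dated Newick tree
#'
#' Parses a Newick string or file with branch lengths in million years,
#' checks ultrametricity, and (optionally) validates the tip set.
#'
#' @param path path to a Newick file, or a Newick string (detected by a
#'   terminal `;`).
#' @param taxa optional character vector: the exact tip set expected.
#' @param tol ultrametricity tolerance (My).
#' @return a [dated_tree()] object.
#' @export
parse_dated_newick <- function(path, taxa = NULL, tol = 1e-6) {
  if (grepl(";\\s*$", path)) {
    phy <- ape::read.tree(text = path)
  } else {
    if (!file.exists(path)) stop("tree file not found: ", path)
    phy <- ape::read.tree(path)
  }
  if (is.null(phy)) stop("could not parse Newick input")
  if (!is.null(taxa) && !setequal(phy$tip.label, taxa)) {
    stop("tree tips {", paste(sort(phy$tip.label), collapse = ","),
         "} do not match expected taxa {", paste(sort(taxa), collapse = ","), "}")
  }
  dated_tree(phy, tol = tol)
}

#' Age of the most recent common ancestor of a tip set
#'
#' @param tree a [dated_tree()].
#' @param tips character vector of tip labels (length >= 1).
#' @return age in My.
#' @export
mrca_age <- function(tree, tips) {
  phy <- tree$phylo
  idx <- match(tips, phy$tip.label)
  if (anyNA(idx)) stop("unknown tips: ", paste(tips[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(tree$ages[idx])
  node <- ape::getMRCA(phy, tips)
  tree$ages[node]
}

#' Reference dated phylogeny of the study species
#'
#' Topology `((mag,soc),(sor,tar))` with crown ages 29 My (genus), 14.2 My
#' (`sor`/`tar`) and 6.9 My (`mag`/`soc`); when `outgroup = TRUE` the
#' family-level outgroup attaches at `outgroup_age` (default 60 My, the
#' family divergence).
#'
#' @param root_age,sortar_age,magsoc_age node ages in My.
#' @param outgroup attach the outgroup taxon?
#' @param outgroup_age ingroup/outgroup split age in My.
#' @return a [dated_tree()].
#' @export
reference_tree <- function(root_age = 29, sortar_age = 14.2, magsoc_age = 6.9,
                           outgroup = FALSE, outgroup_age = 60) {
  if (!(root_age > sortar_age && root_age > magsoc_age)) {
    stop("root age must exceed both pair ages")
  }
  ingroup <- sprintf("((mag:%.12g,soc:%.12g):%.12g,(sor:%.12g,tar:%.12g):%.12g)",
                     magsoc_age, magsoc_age, root_age - magsoc_age,
                     sortar_age, sortar_age, root_age - sortar_age)
  nwk <- if (outgroup) {
    if (outgroup_age <= root_age) stop("outgroup age must exceed ingroup root age")
    sprintf("(%s:%.12g,%s:%.12g);", ingroup, outgroup_age - root_age,
            OUTGROUP_TAXON, outgroup_age)
  } else {
    paste0(ingroup, ";")
  }
  parse_dated_newick(nwk)
}

#' Ingroup branch durations of a dated tree
#'
#' Returns the six branch durations of the reference ingroup topology:
#' four terminal branches (each equal to its sister-pair crown age) and the
#' two stem branches (ingroup root age minus pair age).
#'
#' @param tree a [dated_tree()] containing at least the four ingroup tips
#'   with topology `((mag,soc),(sor,tar))`.
#' @return named numeric vector over `mag`, `soc`, `sor`, `tar`,
#'   `stem_magsoc`, `stem_sortar` (My).
#' @export
branch_durations <- function(tree) {
  magsoc <- mrca_age(tree, SISTER_PAIRS$magsoc)
  sortar <- mrca_age(tree, SISTER_PAIRS$sortar)
  root <- mrca_age(tree, INGROUP_TAXA)
  d <- c(mag = magsoc, soc = magsoc, sor = sortar, tar = sortar,
         stem_magsoc = root - magsoc, stem_sortar = root - sortar)
  if (any(d <= 0)) {
    stop("non-positive branch duration: ",
         paste(names(d)[d <= 0], collapse = ", "))
  }
  d
}

#' Write a dated tree to Newick
#'
#' @param tree a [dated_tree()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dated_newick <- function(tree, path) {
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}
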