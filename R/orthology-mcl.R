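#' Markov clustering (MCL) of a weighted similarity graph
#'
#' Implements the Markov Cluster algorithm on an undirected weighted graph.
#' Self-loops are added carrying each node's maximum incident weight
#' (isolated nodes get weight 1), the adjacency matrix is column-normalised
#' into a stochastic flow matrix, and expansion (matrix squaring) alternates
#' with inflation (entry-wise power `inflation`, then column
#' renormalisation). Entries below `prune` are dropped after each
#' inflation. Iteration stops when the flow matrix changes by less than
#' `convergence` (max absolute entry difference) or after `max_iter`
#' rounds; in the latter case the current matrix is interpreted anyway and
#' flagged. Clusters are the attractor systems of the limit matrix:
#' connected components of its non-zero structure, so overlapping
#' attractors are merged and every node lands in exactly one cluster.
#'
#' @param edges `data.frame` with columns `node1`, `node2`, `weight`
#'   (undirected; duplicate edges keep the maximum weight). Isolated nodes
#'   can be supplied via `nodes`.
#' @param inflation inflation parameter (granularity); larger values give
#'   finer clusters.
#' @param nodes optional character vector of all node names (to include
#'   isolated nodes).
#' @param prune drop flow-matrix entries below this value.
#' @param convergence stop when successive flow matrices differ by less.
#' @param max_iter iteration cap.
#' @return list with `membership` (named integer vector: cluster index per
#'   node), `n_clusters`, `converged`, `iterations`.
#' @export
mcl_cluster <- function(edges, inflation = 20, nodes = NULL, prune = 1e-08,
                        convergence = 1e-06, max_iter = 200L) {
  if (inflation <= 1) stop("inflation must be > 1")
  all_nodes <- unique(c(nodes, edges$node1, edges$node2))
  n <- length(all_nodes)
  if (n == 0L) {
    return(list(membership = integer(0), n_clusters = 0L,
                converged = TRUE, iterations = 0L))
  }
  if (nrow(edges) > 0L && any(edges$weight < 0)) stop("negative edge weight")
  i <- c(match(edges$node1, all_nodes), match(edges$node2, all_nodes))
  j <- c(match(edges$node2, all_nodes), match(edges$node1, all_nodes))
  w <- c(edges$weight, edges$weight)
  # duplicate (i, j) entries keep the maximum weight
  key <- paste(i, j)
  keep <- !duplicated(key)
  agg <- tapply(w, key, max)
  M <- Matrix::sparseMatrix(i = i[keep], j = j[keep],
                            x = as.numeric(agg[key[keep]]),
                            dims = c(n, n),
                            dimnames = list(all_nodes, all_nodes))
  loop <- apply_colmax(M)
  loop[loop == 0] <- 1
  M[cbind(seq_len(n), seq_len(n))] <- loop
  col_normalize <- function(m) m %*% Matrix::Diagonal(x = 1 / Matrix::colSums(m))
  M <- col_normalize(M)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    prev <- M
    M <- M %*% M                     # expansion
    M@x <- M@x^inflation             # inflation (entry-wise on support)
    M <- col_normalize(M)            # renormalise before pruning so
    M <- Matrix::drop0(M * (M >= prune))  # absolute-scale pruning holds
    cs <- Matrix::colSums(M)
    dead <- which(cs == 0)           # fully pruned column: restart at self
    if (length(dead) > 0L) {
      M[cbind(dead, dead)] <- 1
      cs[dead] <- 1
    }
    M <- M %*% Matrix::Diagonal(x = 1 / cs)
    if (max(abs(M - prev)) < convergence) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter,
            " iterations; interpreting current flow matrix")
  }
  support <- (M > 0) | Matrix::t(M > 0)
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  names(membership) <- all_nodes
  list(membership = membership, n_clusters = comp$no,
       converged = converged, iterations = it)
}

apply_colmax <- function(M) {
  M <- methods::as(M, "CsparseMatrix")
  out <- numeric(ncol(M))
  dp <- diff(M@p)
  if (length(M@x) > 0L) {
    ci <- rep.int(seq_len(ncol(M)), dp)
    mx <- tapply(M@x, ci, max)
    out[as.integer(names(mx))] <- mx
  }
  out
}

#' Similarity edges for MCL from pooled BLAST hits
#'
#' The standard BLAST-to-MCL transform: edge weight
#' `min(-log10(evalue), cap)` for hits at e-value <= `evalue_max`
#' (e-value 0 maps to the cap). Self-hits are dropped; reciprocal hits
#' keep the maximum weight. With `weight = "bitscore"` the bitscore is
#' used instead.
#'
#' @param hits pooled all-vs-all hit `data.frame`; query and subject ids
#'   must be globally unique across species.
#' @param evalue_max inclusion threshold.
#' @param cap weight cap for the log-e-value transform.
#' @param weight `"log_evalue"` (default) or `"bitscore"`.
#' @return edge `data.frame` (`node1`, `node2`, `weight`).
#' @export
mcl_edges_from_hits <- function(hits, evalue_max = 1e-10, cap = 200,
                                weight = c("log_evalue", "bitscore")) {
  weight <- match.arg(weight)
  h <- hits[hits$evalue <= evalue_max & hits$query_id != hits$subject_id, ,
            drop = FALSE]
  w <- if (weight == "log_evalue") {
    pmin(-log10(pmax(h$evalue, 10^(-cap))), cap)
  } else {
    h$bitscore
  }
  data.frame(node1 = h$query_id, node2 = h$subject_id, weight = w,
             stringsAsFactors = FALSE)
}

#' Ortholog groups by Markov clustering of pooled transcripts
#'
#' Pools transcripts across all taxa (ingroup plus, by default, the
#' outgroup), clusters the all-vs-all similarity graph with
#' [mcl_cluster()], and returns groups whose outgroup flag reflects
#' outgroup transcripts in the cluster. Clusters with no ingroup member
#' are dropped.
#'
#' @param hits pooled all-vs-all hit `data.frame`.
#' @param transcripts transcript `data.frame` with `id` and `species`
#'   covering every node (ids globally unique).
#' @param config configuration list; `orthology$mcl` supplies parameters.
#' @return an [ortho_groups()] object (`method = "mcl"`) with a
#'   `converged` attribute.
#' @export
mcl_ortho_groups <- function(hits, transcripts, config = default_config()) {
  cf <- config$orthology$mcl
  og_taxon <- config$taxa$outgroup
  if (!isTRUE(cf$include_outgroup)) {
    keep <- transcripts$species != og_taxon
    transcripts <- transcripts[keep, , drop = FALSE]
    hits <- hits[hits$query_id %in% transcripts$id &
                   hits$subject_id %in% transcripts$id, , drop = FALSE]
  }
  edges <- mcl_edges_from_hits(hits, evalue_max = cf$evalue_max,
                               cap = cf$weight_cap)
  res <- mcl_cluster(edges, inflation = cf$inflation, nodes = transcripts$id,
                     prune = cf$prune, convergence = cf$convergence,
                     max_iter = cf$max_iter)
  sp <- transcripts$species[match(names(res$membership), transcripts$id)]
  if (anyNA(sp)) {
    stop("hits reference transcripts absent from the transcript table: ",
         paste(utils::head(names(res$membership)[is.na(sp)]), collapse = ", "))
  }
  members <- data.frame(
    cluster = res$membership,
    species = sp,
    transcript_id = names(res$membership),
    stringsAsFactors = FALSE
  )
  has_ingroup <- tapply(members$species != og_taxon, members$cluster, any)
  keep_cl <- as.integer(names(has_ingroup)[has_ingroup])
  members <- members[members$cluster %in% keep_cl, , drop = FALSE]
  cl_ids <- sort(unique(members$cluster))
  members$group_id <- sprintf("mcl_%05d", match(members$cluster, cl_ids))
  outg <- tapply(members$species == og_taxon, members$group_id, any)
  ingroup_members <- members[members$species != og_taxon,
                             c("group_id", "species", "transcript_id")]
  og <- ortho_groups(ingroup_members, "mcl",
                     outgroup_present = vapply(outg, isTRUE, logical(1L)))
  attr(og, "converged") <- res$converged
  og
}
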