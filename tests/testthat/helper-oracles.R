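# Independent oracles used by the tests. These deliberately do not share
# code with the package implementation they check.

# --- reference MCL -----------------------------------------------------------
# Straightforward dense implementation of the Markov Cluster algorithm,
# written independently of hgtpipe::mcl_cluster (dense matrices, explicit
# loops, no pruning). Returns a membership vector.
mcl_reference <- function(edges, inflation, nodes = NULL, max_iter = 300L) {
  nm <- unique(c(nodes, edges$node1, edges$node2))
  n <- length(nm)
  A <- matrix(0, n, n, dimnames = list(nm, nm))
  for (k in seq_len(nrow(edges))) {
    a <- edges$node1[k]; b <- edges$node2[k]
    A[a, b] <- max(A[a, b], edges$weight[k])
    A[b, a] <- max(A[b, a], edges$weight[k])
  }
  for (j in seq_len(n)) {
    mx <- max(A[, j])
    A[j, j] <- if (mx > 0) mx else 1
  }
  for (j in seq_len(n)) A[, j] <- A[, j] / sum(A[, j])
  for (it in seq_len(max_iter)) {
    old <- A
    A <- A %*% A
    A <- A^inflation
    for (j in seq_len(n)) A[, j] <- A[, j] / sum(A[, j])
    A[A < 1e-12] <- 0
    for (j in seq_len(n)) A[, j] <- A[, j] / sum(A[, j])
    if (max(abs(A - old)) < 1e-06) break
  }
  reach <- (A > 0) | t(A > 0)
  membership <- rep(NA_integer_, n)
  names(membership) <- nm
  cl <- 0L
  for (j in seq_len(n)) {
    if (!is.na(membership[j])) next
    cl <- cl + 1L
    frontier <- j
    while (length(frontier) > 0L) {
      membership[frontier] <- cl
      nxt <- unique(unlist(lapply(frontier, function(v) which(reach[v, ]))))
      frontier <- setdiff(nxt, which(!is.na(membership)))
    }
  }
  membership
}

# canonical signature of a partition, for comparing clusterings
partition_signature <- function(membership) {
  parts <- lapply(split(names(membership), membership), sort)
  parts <- parts[order(vapply(parts, `[`, character(1L), 1L))]
  unname(parts)
}

# --- brute-force rooted-topology enumeration --------------------------------
# All rooted binary trees over a label set, as canonical nested-set strings,
# built by recursive bipartition (independent of the package's canonical
# form code).
brute_rooted_trees <- function(labels) {
  if (length(labels) == 1L) return(labels)
  out <- character(0)
  n <- length(labels)
  # nonempty proper subsets containing the first label (avoids double count)
  others <- labels[-1L]
  for (m in 0:(2^(n - 1L) - 2L)) {
    pick <- as.logical(bitwAnd(m, 2^(seq_len(n - 1L) - 1L)))
    left <- c(labels[1L], others[pick])
    right <- others[!pick]
    for (l in brute_rooted_trees(left)) {
      for (r in brute_rooted_trees(right)) {
        pair <- sort(c(l, r))
        out <- c(out, paste0("(", pair[1L], ",", pair[2L], ")"))
      }
    }
  }
  unique(out)
}

# sort children inside an existing newick-ish nested string (for comparing
# against brute_rooted_trees output)
canon_nested <- function(s) {
  s <- sub(";$", "", s)
  parse_node <- function(str) {
    if (!startsWith(str, "(")) return(str)
    inner <- substr(str, 2L, nchar(str) - 1L)
    depth <- 0L
    cut <- integer(0)
    for (i in seq_len(nchar(inner))) {
      ch <- substr(inner, i, i)
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") depth <- depth - 1L
      if (ch == "," && depth == 0L) cut <- c(cut, i)
    }
    starts <- c(1L, cut + 1L)
    ends <- c(cut - 1L, nchar(inner))
    kids <- sort(vapply(seq_along(starts), function(k) {
      parse_node(substr(inner, starts[k], ends[k]))
    }, character(1L)))
    paste0("(", paste(kids, collapse = ","), ")")
  }
  parse_node(s)
}

# --- analytic detectability expectation -------------------------------------
# Expected counts of parsimony-unambiguous GAIN patterns under the forward
# gain/loss (per-gene hazard) model on a dated tree: enumerates, for every
# gene origin (root or uniform gain on a branch), the leaf presence-pattern
# distribution via exponential survival down the tree, and sums the
# expected mass on unique-to-one-species and exactly-one-sister-pair
# patterns (outgroup absent).
expected_unambiguous_gains <- function(tree, gain_rate, loss_rate,
                                       n_ancestral) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  elen <- phy$edge.length
  edge_of_child <- match(seq_len(max(phy$edge)), phy$edge[, 2L])
  # pattern distribution over leaf subsets given the gene is present at node
  patt_at <- function(node) {
    if (node <= ntip) {
      return(list(sets = list(phy$tip.label[node]), probs = 1))
    }
    child_mix <- lapply(kids[[as.character(node)]], function(ch) {
      t <- elen[edge_of_child[ch]]
      s <- exp(-loss_rate * t)
      sub <- patt_at(ch)
      list(sets = c(sub$sets, list(character(0))),
           probs = c(s * sub$probs, 1 - s))
    })
    sets <- list(character(0))
    probs <- 1
    for (cm in child_mix) {
      new_sets <- list()
      new_probs <- numeric(0)
      for (i in seq_along(sets)) {
        for (j in seq_along(cm$sets)) {
          new_sets[[length(new_sets) + 1L]] <- c(sets[[i]], cm$sets[[j]])
          new_probs <- c(new_probs, probs[i] * cm$probs[j])
        }
      }
      key <- vapply(new_sets, function(s) paste(sort(s), collapse = "+"),
                    character(1L))
      agg <- tapply(new_probs, key, sum)
      sets <- lapply(names(agg), function(k) {
        if (k == "") character(0) else strsplit(k, "\\+")[[1L]]
      })
      probs <- as.numeric(agg)
    }
    list(sets = sets, probs = probs)
  }
  is_unambiguous_gain <- function(set) {
    ing <- intersect(set, INGROUP_TAXA)
    if (OUTGROUP_TAXON %in% set) return(FALSE)
    if (length(setdiff(set, c(INGROUP_TAXA, OUTGROUP_TAXON))) > 0L)
      return(FALSE)
    if (length(ing) == 1L) return(TRUE)
    if (length(ing) == 2L) {
      return(any(vapply(SISTER_PAIRS, function(p) setequal(ing, p),
                        logical(1L))))
    }
    FALSE
  }
  mass_from <- function(dist) {
    sum(dist$probs[vapply(dist$sets, is_unambiguous_gain, logical(1L))])
  }
  root <- ntip + 1L
  total <- n_ancestral * mass_from(patt_at(root))
  for (k in seq_len(nrow(phy$edge))) {
    child <- phy$edge[k, 2L]
    t <- elen[k]
    reach <- gain_rate * (1 - exp(-loss_rate * t)) / loss_rate
    total <- total + reach * mass_from(patt_at(child))
  }
  total
}

# --- misc fixture builders ---------------------------------------------------
write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

random_weighted_graph <- function(n_nodes, p_edge = 0.15, w_range = c(1, 60)) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2L))
  keep <- stats::runif(nrow(pairs)) < p_edge
  data.frame(node1 = pairs[keep, 1L], node2 = pairs[keep, 2L],
             weight = stats::runif(sum(keep), w_range[1L], w_range[2L]),
             stringsAsFactors = FALSE)
}
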