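#' Ortholog group container
#'
#' Ortholog groups are held as a two-table S3 object: `members` (long
#' format: `group_id`, `species`, `transcript_id`) and `groups` (one row
#' per group: `group_id`, `method`, `n_members`, `outgroup_present`,
#' `foreign`, `distribution`). `foreign` and `distribution` start `NA` and
#' are filled by [designate_foreign_groups()] and
#' [classify_distribution()].
#'
#' @param members long membership `data.frame`.
#' @param method `"rbh"` or `"mcl"`.
#' @param outgroup_present optional named logical vector by group id.
#' @return an `ortho_groups` object.
#' @export
ortho_groups <- function(members, method, outgroup_present = NULL) {
  stopifnot(all(c("group_id", "species", "transcript_id") %in% names(members)))
  ids <- unique(members$group_id)
  if (length(ids) > 0L && any(tapply(members$transcript_id, members$group_id,
                                     length) < 1L)) {
    stop("empty ortholog group")
  }
  og <- rep(FALSE, length(ids))
  names(og) <- ids
  if (!is.null(outgroup_present)) og[names(outgroup_present)] <- outgroup_present
  groups <- data.frame(
    group_id = ids,
    method = rep_len(method, length(ids)),
    n_members = as.integer(table(factor(members$group_id, levels = ids))),
    outgroup_present = unname(og),
    foreign = rep_len(NA, length(ids)),
    distribution = rep_len(NA_character_, length(ids)),
    stringsAsFactors = FALSE
  )
  structure(list(members = members, groups = groups, method = method),
            class = "ortho_groups")
}

#' @export
print.ortho_groups <- function(x, ...) {
  cat("Ortholog groups (", x$method, "): ", nrow(x$groups), " groups, ",
      nrow(x$members), " member transcripts\n", sep = "")
  if (!all(is.na(x$groups$foreign))) {
    cat("  foreign groups:", sum(x$groups$foreign, na.rm = TRUE), "\n")
  }
  invisible(x)
}

best_hits_per_query <- function(hits, evalue_max) {
  h <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (nrow(h) == 0L) return(h)
  h <- h[order(h$query_id, -h$bitscore, h$evalue, h$subject_id), , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Ortholog groups from consistent reciprocal best hits
#'
#' For each unordered species pair, transcripts `x` (species `a`) and `y`
#' (species `b`) form a reciprocal best hit (RBH) iff `y` is `x`'s best hit
#' in `b` and `x` is `y`'s best hit in `a`, both at e-value <=
#' `evalue_max`. Best means maximum bitscore, tie-broken by minimum
#' e-value then lexicographic subject id. RBH pairs form a graph whose
#' connected components are candidate groups; a component is retained only
#' if each member species contributes exactly one transcript and every
#' pair of member species is linked by an RBH edge (pairwise consistency).
#'
#' @param pair_hits named list of hit tables for ordered species pairs;
#'   names `"a__b"` mean queries from species `a` against the database of
#'   species `b`. All ordered pairs over `species` must be present.
#' @param species character vector of ingroup species labels.
#' @param evalue_max RBH e-value cutoff.
#' @return an [ortho_groups()] object (`method = "rbh"`) with an extra
#'   `dropped` element: a `data.frame` of rejected components and reasons
#'   (`duplicate_species` or `missing_edge`).
#' @export
reciprocal_best_hits <- function(pair_hits, species = INGROUP_TAXA,
                                 evalue_max = 1e-10) {
  pairs <- expand.grid(a = species, b = species, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  want <- paste0(pairs$a, "__", pairs$b)
  missing <- setdiff(want, names(pair_hits))
  if (length(missing) > 0L) {
    stop("missing pairwise hit table(s): ", paste(missing, collapse = ", "))
  }
  best <- lapply(pair_hits[want], best_hits_per_query, evalue_max = evalue_max)
  names(best) <- want

  edges <- list()
  combs <- utils::combn(species, 2L)
  for (k in seq_len(ncol(combs))) {
    a <- combs[1L, k]; b <- combs[2L, k]
    ab <- best[[paste0(a, "__", b)]]
    ba <- best[[paste0(b, "__", a)]]
    if (nrow(ab) == 0L || nrow(ba) == 0L) next
    back <- ba$subject_id[match(ab$subject_id, ba$query_id)]
    mutual <- !is.na(back) & back == ab$query_id
    if (any(mutual)) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = paste0(a, "|", ab$query_id[mutual]),
        to = paste0(b, "|", ab$subject_id[mutual]),
        species_pair = paste0(a, "-", b),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(edges) == 0L) {
    og <- ortho_groups(data.frame(group_id = character(0),
                                  species = character(0),
                                  transcript_id = character(0),
                                  stringsAsFactors = FALSE), "rbh")
    og$dropped <- data.frame(component = integer(0), reason = character(0),
                             n_nodes = integer(0), stringsAsFactors = FALSE)
    return(og)
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE)
  comp <- igraph::components(g)
  node <- names(comp$membership)
  node_sp <- sub("\\|.*", "", node)
  node_tx <- sub("^[^|]*\\|", "", node)

  members <- list()
  dropped <- list()
  gid <- 0L
  edge_key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  for (ci in seq_len(comp$no)) {
    in_c <- comp$membership == ci
    sps <- node_sp[in_c]
    txs <- node_tx[in_c]
    if (anyDuplicated(sps)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        component = ci, reason = "duplicate_species", n_nodes = sum(in_c),
        stringsAsFactors = FALSE)
      next
    }
    nn <- node[in_c]
    need <- utils::combn(sort(nn), 2L)
    have_all <- all(paste(need[1L, ], need[2L, ]) %in% edge_key)
    if (!have_all) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        component = ci, reason = "missing_edge", n_nodes = sum(in_c),
        stringsAsFactors = FALSE)
      next
    }
    gid <- gid + 1L
    ord <- order(sps)
    members[[gid]] <- data.frame(
      group_id = sprintf("rbh_%05d", gid),
      species = sps[ord], transcript_id = txs[ord],
      stringsAsFactors = FALSE)
  }
  members <- if (length(members) > 0L) do.call(rbind, members) else
    data.frame(group_id = character(0), species = character(0),
               transcript_id = character(0), stringsAsFactors = FALSE)
  og <- ortho_groups(members, "rbh")
  og$dropped <- if (length(dropped) > 0L) do.call(rbind, dropped) else
    data.frame(component = integer(0), reason = character(0),
               n_nodes = integer(0), stringsAsFactors = FALSE)
  og
}

#' Flag ortholog groups with an outgroup homolog
#'
#' A group is outgroup-present iff any member transcript hits the outgroup
#' transcriptome at e-value <= `evalue_max`.
#'
#' @param groups an [ortho_groups()] object.
#' @param outgroup_hits hit `data.frame` of member transcripts vs the
#'   outgroup transcriptome.
#' @param evalue_max homology threshold.
#' @return `groups` with `outgroup_present` updated.
#' @export
attach_outgroup <- function(groups, outgroup_hits, evalue_max = 1e-10) {
  hit_ids <- unique(outgroup_hits$query_id[outgroup_hits$evalue <= evalue_max])
  by_group <- tapply(groups$members$transcript_id %in% hit_ids,
                     groups$members$group_id, any)
  idx <- match(groups$groups$group_id, names(by_group))
  present <- as.logical(by_group)[idx]
  present[is.na(present)] <- FALSE
  groups$groups$outgroup_present <- groups$groups$outgroup_present | present
  groups
}
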