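#' Designate foreign ortholog groups by majority rule
#'
#' A group is foreign iff strictly more than half of its ingroup member
#' transcripts are individually foreign; a group exactly at half is native
#' (strict reading of the majority rule). Outgroup transcripts carry no
#' h_U call and do not vote. Every ingroup member must have a call.
#'
#' @param groups an [ortho_groups()] object.
#' @param calls calls `data.frame` covering all member transcripts.
#' @return `groups` with the `foreign` column filled.
#' @export
designate_foreign_groups <- function(groups, calls) {
  m <- groups$members
  st <- calls$status[match(m$transcript_id, calls$transcript_id)]
  if (anyNA(st)) {
    stop("member transcript(s) without an HGT call: ",
         paste(utils::head(m$transcript_id[is.na(st)], 5L), collapse = ", "))
  }
  n_foreign <- tapply(st == "foreign", m$group_id, sum)
  n_total <- tapply(st, m$group_id, length)
  foreign <- as.numeric(n_foreign) > as.numeric(n_total) / 2
  groups$groups$foreign <-
    foreign[match(groups$groups$group_id, names(n_foreign))]
  groups
}

#' Phylogenetic distribution class of an ortholog group
#'
#' Classes, in increasing phylogenetic breadth:
#' `unique` (single ingroup species), `sister` (exactly both members of
#' one sister pair), `genus` (ingroup span covers both sister pairs),
#' `shared_outgroup` (outgroup homolog present, which dominates the other
#' rules). The returned label carries the span for the narrow classes,
#' e.g. `unique(mag)` or `sister(sortar)`.
#'
#' @param species_span character vector of ingroup species containing the
#'   group.
#' @param outgroup_present logical.
#' @param sister_pairs named list of two character pairs.
#' @return distribution label.
#' @export
classify_distribution <- function(species_span, outgroup_present,
                                  sister_pairs = SISTER_PAIRS) {
  span <- unique(species_span)
  if (length(span) == 0L) stop("empty ingroup span")
  if (isTRUE(outgroup_present)) return("shared_outgroup")
  in_pair <- vapply(sister_pairs, function(p) any(span %in% p), logical(1L))
  if (all(in_pair)) return("genus")
  for (nm in names(sister_pairs)) {
    if (setequal(span, sister_pairs[[nm]])) return(paste0("sister(", nm, ")"))
  }
  if (length(span) == 1L) return(paste0("unique(", span, ")"))
  # within one pair but not exactly the pair cannot occur with 2 species
  stop("unclassifiable span: ", paste(span, collapse = ","))
}

#' @rdname classify_distribution
#' @param groups an [ortho_groups()] object.
#' @return for `classify_distributions()`: `groups` with the
#'   `distribution` column filled.
#' @export
classify_distributions <- function(groups, sister_pairs = SISTER_PAIRS) {
  spans <- split(groups$members$species, groups$members$group_id)
  g <- groups$groups
  g$distribution <- vapply(seq_len(nrow(g)), function(i) {
    classify_distribution(spans[[g$group_id[i]]], g$outgroup_present[i],
                          sister_pairs)
  }, character(1L))
  groups$groups <- g
  groups
}

#' Base class of a distribution label
#'
#' Collapses `unique(mag)` to `unique` and `sister(sortar)` to `sister`.
#'
#' @param distribution character vector of distribution labels.
#' @return factor-like character vector over
#'   `unique`/`sister`/`genus`/`shared_outgroup`.
#' @export
distribution_class <- function(distribution) {
  sub("\\(.*\\)$", "", distribution)
}

#' Presence/absence matrix of ortholog groups
#'
#' One row per group, columns the ingroup taxa plus the outgroup; the
#' outgroup cell is the group's `outgroup_present` flag.
#'
#' @param groups an [ortho_groups()] object.
#' @param foreign_only keep only groups designated foreign.
#' @param taxa ingroup taxon order for the columns.
#' @return logical matrix.
#' @export
presence_matrix <- function(groups, foreign_only = FALSE,
                            taxa = INGROUP_TAXA) {
  g <- groups$groups
  if (foreign_only) {
    if (all(is.na(g$foreign))) stop("run designate_foreign_groups() first")
    g <- g[which(g$foreign), , drop = FALSE]
  }
  m <- groups$members[groups$members$group_id %in% g$group_id, , drop = FALSE]
  pm <- matrix(FALSE, nrow(g), length(taxa) + 1L,
               dimnames = list(g$group_id, c(taxa, OUTGROUP_TAXON)))
  if (nrow(m) > 0L) {
    pm[cbind(match(m$group_id, g$group_id), match(m$species, taxa))] <- TRUE
  }
  pm[, OUTGROUP_TAXON] <- g$outgroup_present
  pm
}

#' Per-species distribution-class counts (study-table layout)
#'
#' For each species, counts the ortholog groups containing that species in
#' each distribution class. Sister-pair groups are counted in both member
#' species' rows, genus and outgroup-shared groups in every member
#' species' row, mirroring the per-species rows of the study's
#' distribution table.
#'
#' @param groups a classified [ortho_groups()] object.
#' @param foreign_only restrict to foreign groups.
#' @param taxa species row order.
#' @return integer matrix species x class
#'   (`unique`, `sister`, `genus`, `shared_outgroup`), plus a `total`
#'   column.
#' @export
count_distributions <- function(groups, foreign_only = TRUE,
                                taxa = INGROUP_TAXA) {
  g <- groups$groups
  if (foreign_only) g <- g[which(g$foreign), , drop = FALSE]
  if (any(is.na(g$distribution))) stop("run classify_distributions() first")
  classes <- c("unique", "sister", "genus", "shared_outgroup")
  m <- groups$members[groups$members$group_id %in% g$group_id, , drop = FALSE]
  cls <- distribution_class(g$distribution[match(m$group_id, g$group_id)])
  tab <- table(factor(m$species, levels = taxa), factor(cls, levels = classes))
  out <- cbind(unclass(tab), total = rowSums(tab))
  storage.mode(out) <- "integer"
  out
}
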