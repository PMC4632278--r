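#' Genome presence of ortholog groups
#'
#' A group is present in the validation genome iff any member transcript
#' hits a genome scaffold at e-value <= `evalue_max`. Recovery fractions
#' (proportion of groups found in the genome) are reported per
#' distribution class; for classes split by span (e.g. `unique(mag)` vs
#' `unique(soc)`), the full label is kept so cross-species recovery can be
#' read off directly.
#'
#' @param groups a classified [ortho_groups()] object.
#' @param genome_hits hit `data.frame` of member transcripts vs genome
#'   scaffolds (`partition = "genome"`).
#' @param evalue_max presence threshold.
#' @param foreign_only restrict to foreign groups.
#' @return list with `present` (named logical per group) and `recovery`
#'   (`data.frame`: `distribution`, `n_groups`, `n_present`, `fraction`).
#' @export
genome_presence <- function(groups, genome_hits, evalue_max = 1e-05,
                            foreign_only = TRUE) {
  g <- groups$groups
  if (foreign_only) g <- g[which(g$foreign), , drop = FALSE]
  hit_ids <- unique(genome_hits$query_id[genome_hits$evalue <= evalue_max])
  m <- groups$members[groups$members$group_id %in% g$group_id, , drop = FALSE]
  by_group <- tapply(m$transcript_id %in% hit_ids, m$group_id, any)
  present <- as.logical(by_group)[match(g$group_id, names(by_group))]
  present[is.na(present)] <- FALSE
  names(present) <- g$group_id
  rec <- do.call(rbind, lapply(split(present, g$distribution), function(p) {
    data.frame(n_groups = length(p), n_present = sum(p),
               fraction = mean(p), stringsAsFactors = FALSE)
  }))
  recovery <- data.frame(distribution = rownames(rec), rec,
                         row.names = NULL, stringsAsFactors = FALSE)
  list(present = present, recovery = recovery)
}

#' Estimate transcriptome false-negative rates
#'
#' The false-negative probability \eqn{f_s} for species `s` is the
#' fraction of genes classified absent from `s`'s transcriptome that the
#' validation genome shows to be truly present — i.e. the cross-species
#' genome recovery rate. With a single validation genome, a pooled `f`
#' (the mean of the observed cross-species recovery rates) is applied to
#' all species unless per-species rates are supplied.
#'
#' @param recovery numeric vector of cross-species recovery fractions
#'   (each in `[0, 1)`), e.g. the fractions of genes unique to the other
#'   species found in the validation genome.
#' @param species optional species labels; when given, a per-species rate
#'   vector is returned alongside the pooled value.
#' @param taxa all taxa the model must cover (the pooled rate fills gaps).
#' @return an `fn_model` list: `f` (named per-taxon rates), `pooled`,
#'   `provenance` (the input fractions).
#' @export
estimate_fn_rates <- function(recovery, species = NULL,
                              taxa = c(INGROUP_TAXA, OUTGROUP_TAXON)) {
  if (any(recovery < 0 | recovery >= 1)) {
    stop("recovery fractions must lie in [0, 1)")
  }
  pooled <- mean(recovery)
  f <- rep(pooled, length(taxa))
  names(f) <- taxa
  if (!is.null(species)) {
    stopifnot(length(species) == length(recovery))
    f[species] <- recovery
  }
  structure(list(f = f, pooled = pooled, provenance = recovery),
            class = "fn_model")
}

#' @export
print.fn_model <- function(x, ...) {
  cat("Transcriptome false-negative model: pooled f =",
      format(x$pooled, digits = 4), "\n")
  invisible(x)
}

pattern_probs <- function(absent, f) {
  # enumerate truly-present subsets of the observed-absent taxa
  k <- length(absent)
  if (k == 0L) {
    return(list(subsets = list(character(0)), probs = 1))
  }
  subsets <- list()
  probs <- numeric(0)
  for (mask in 0:(2^k - 1L)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
    p <- prod(ifelse(inset, f[absent], 1 - f[absent]))
    subsets[[length(subsets) + 1L]] <- absent[inset]
    probs <- c(probs, p)
  }
  list(subsets = subsets, probs = probs)
}

#' Correct distribution-class counts for transcriptome false negatives
#'
#' Expected-value reclassification: a gene observed present in a taxon set
#' `A` is truly present in each observed-absent taxon `b` independently
#' with probability \eqn{f_b} (the false-negative model). For every
#' observed presence pattern the expectation is taken over all true
#' patterns, each reclassified by the distribution rules, and per-species
#' class counts are accumulated — so mass moves only from narrower to
#' broader classes (unique to sister/genus/shared, sister to
#' genus/shared), corrected unique counts never exceed observed ones, and
#' species gain expected membership in genes they were scored absent for.
#'
#' @param presence logical presence matrix (groups x taxa including
#'   `outgroup`), typically [presence_matrix()] of the foreign groups.
#' @param model an [estimate_fn_rates()] model.
#' @param sister_pairs sister-pair configuration.
#' @param taxa ingroup taxa.
#' @return list with `observed` and `corrected` per-species class-count
#'   matrices (corrected counts are expectations, not integers).
#' @export
correct_category_counts <- function(presence, model,
                                    sister_pairs = SISTER_PAIRS,
                                    taxa = INGROUP_TAXA) {
  classes <- c("unique", "sister", "genus", "shared_outgroup")
  all_taxa <- c(taxa, OUTGROUP_TAXON)
  stopifnot(all(all_taxa %in% colnames(presence)))
  if (any(rowSums(presence[, taxa, drop = FALSE]) == 0L)) {
    stop("presence matrix row with no ingroup presence")
  }
  observed <- matrix(0, length(taxa), length(classes),
                     dimnames = list(taxa, classes))
  corrected <- observed
  pat_key <- apply(presence[, all_taxa, drop = FALSE], 1L,
                   function(r) paste(as.integer(r), collapse = ""))
  for (key in unique(pat_key)) {
    n <- sum(pat_key == key)
    pat <- as.integer(strsplit(key, "")[[1L]]) == 1L
    names(pat) <- all_taxa
    span <- taxa[pat[taxa]]
    cls <- distribution_class(
      classify_distribution(span, pat[OUTGROUP_TAXON], sister_pairs))
    observed[span, cls] <- observed[span, cls] + n
    absent <- all_taxa[!pat]
    pp <- pattern_probs(absent, model$f)
    for (s in seq_along(pp$subsets)) {
      true_span <- sort(c(span, intersect(pp$subsets[[s]], taxa)))
      true_out <- pat[OUTGROUP_TAXON] || OUTGROUP_TAXON %in% pp$subsets[[s]]
      true_cls <- distribution_class(
        classify_distribution(true_span, true_out, sister_pairs))
      corrected[true_span, true_cls] <-
        corrected[true_span, true_cls] + n * pp$probs[s]
    }
  }
  if (any(corrected < -1e-9)) stop("internal error: negative corrected count")
  observed <- cbind(observed, total = rowSums(observed))
  corrected <- cbind(corrected, total = rowSums(corrected))
  list(observed = observed, corrected = corrected, model = model)
}
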