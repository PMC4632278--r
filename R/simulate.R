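branch_label <- function(phy, child, sister_pairs = SISTER_PAIRS) {
  ntip <- length(phy$tip.label)
  if (child <= ntip) return(phy$tip.label[child])
  tips <- phy$tip.label[unlist(phangorn_descendants(phy, child))]
  for (nm in names(sister_pairs)) {
    if (setequal(tips, sister_pairs[[nm]])) return(paste0("stem_", nm))
  }
  if (setequal(tips, INGROUP_TAXA)) return("stem_ingroup")
  paste0("node_", child)
}

# tip indices below an internal node (plain edge-list walk)
phangorn_descendants <- function(phy, node) {
  ntip <- length(phy$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0L) {
    nd <- stack[1L]
    stack <- stack[-1L]
    ch <- phy$edge[phy$edge[, 1L] == nd, 2L]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  out
}

#' Simulate gene content evolving on a dated tree
#'
#' Forward simulation of the gain/loss process whose rates the pipeline
#' estimates. `n_ancestral` genes are present at the root; along each
#' branch of duration `t`, each present gene is lost with probability
#' `1 - exp(-loss_rate * t)` (at least one Poisson loss event), and
#' `Poisson(gain_rate * t)` new genes arise at uniform times, each
#' surviving the remainder of the branch with probability
#' `exp(-loss_rate * (t - u))`. Leaf presence is recorded; genes absent
#' from every ingroup leaf are dropped from the matrix (they are
#' unobservable in this design) but remain in the event log.
#'
#' @param tree a [dated_tree()], typically [reference_tree()] with
#'   `outgroup = TRUE`.
#' @param gain_rate,loss_rate events per lineage per My (>= 0).
#' @param n_ancestral genes present at the root.
#' @param seed integer seed; output is bit-reproducible given
#'   (seed, parameters).
#' @return list with `presence` (logical matrix, taxa columns; an
#'   `outgroup` column of `FALSE` is added if the tree lacks the outgroup
#'   tip), `events` (`data.frame`: `branch`, `duration`, `gains`,
#'   `losses`), and `n_genes` (total genes ever created).
#' @export
simulate_gene_content <- function(tree, gain_rate, loss_rate, n_ancestral,
                                  seed) {
  if (gain_rate < 0 || loss_rate < 0) stop("rates must be >= 0")
  set.seed(as.integer(seed))
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  n_genes <- as.integer(n_ancestral)
  present <- vector("list", max(phy$edge))
  present[[root]] <- seq_len(n_ancestral)
  # cladewise order visits every parent before its children
  phc <- ape::reorder.phylo(phy, "cladewise")
  edges <- phc$edge
  elen <- phc$edge.length
  ev <- list()
  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1L]
    child <- edges[k, 2L]
    t <- elen[k]
    genes <- present[[parent]]
    p_survive <- exp(-loss_rate * t)
    survived <- genes[stats::runif(length(genes)) < p_survive]
    n_lost <- length(genes) - length(survived)
    n_gain <- stats::rpois(1L, gain_rate * t)
    new_ids <- integer(0)
    if (n_gain > 0L) {
      u <- stats::runif(n_gain, 0, t)
      keep <- stats::runif(n_gain) < exp(-loss_rate * (t - u))
      new_ids <- n_genes + which(keep)
      n_genes <- n_genes + n_gain  # ids reserved even for gains lost in-branch
    }
    present[[child]] <- c(survived, new_ids)
    ev[[k]] <- data.frame(branch = branch_label(phy, child), duration = t,
                          gains = n_gain, losses = n_lost,
                          stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, ev)
  taxa <- phy$tip.label
  all_ids <- sort(unique(unlist(present[seq_len(ntip)])))
  if (is.null(all_ids)) all_ids <- integer(0)
  rn <- if (length(all_ids) > 0L) paste0("g", all_ids) else character(0)
  pm <- matrix(FALSE, length(all_ids), length(taxa),
               dimnames = list(rn, taxa))
  for (i in seq_len(ntip)) {
    pm[match(present[[i]], all_ids), taxa[i]] <- TRUE
  }
  if (!(OUTGROUP_TAXON %in% taxa)) {
    pm <- cbind(pm, matrix(FALSE, nrow(pm), 1L,
                           dimnames = list(NULL, OUTGROUP_TAXON)))
  }
  ing <- intersect(INGROUP_TAXA, colnames(pm))
  pm <- pm[rowSums(pm[, ing, drop = FALSE]) > 0L, , drop = FALSE]
  list(presence = pm, events = events, n_genes = n_genes)
}

#' Simulate transcript sequences with GC amelioration
#'
#' One transcript per (group, species) presence cell. Foreign transcripts
#' target GC `donor_gc + amelioration[class] * (background_gc - donor_gc)`
#' — amelioration 0 leaves a gene at its donor composition, 1 makes it
#' indistinguishable from the host background — and native transcripts
#' target the species background. Bases are drawn independently, G/C with
#' the target probability, so realised GC is binomial around the target.
#'
#' @param presence logical matrix (groups x taxa).
#' @param foreign named logical: is each group foreign?
#' @param distribution named character: distribution class per group.
#' @param background_gc named per-species background GC (fractions).
#' @param donor_gc donor GC fraction for unameliorated foreign genes.
#' @param amelioration named weights in `[0, 1]`, non-decreasing over
#'   `unique`, `sister`, `genus`, `shared_outgroup`.
#' @param length_bp transcript length.
#' @param seed integer seed.
#' @return transcript `data.frame` (as [read_transcript_fasta()]) with
#'   extra columns `group_id`, `foreign`, `class`, `gc_target`.
#' @export
simulate_transcripts <- function(presence, foreign, distribution,
                                 background_gc, donor_gc = 0.45,
                                 amelioration = c(unique = 0, sister = 0.3,
                                                  genus = 0.6,
                                                  shared_outgroup = 0.9),
                                 length_bp = 500L, seed = 1L) {
  set.seed(as.integer(seed))
  if (is.unsorted(amelioration[c("unique", "sister", "genus",
                                 "shared_outgroup")])) {
    stop("amelioration weights must be non-decreasing with breadth")
  }
  taxa <- intersect(colnames(presence), names(background_gc))
  rows <- list()
  for (sp in taxa) {
    gids <- rownames(presence)[presence[, sp]]
    if (length(gids) == 0L) next
    cls <- distribution_class(distribution[gids])
    is_f <- foreign[gids]
    target <- ifelse(is_f,
                     donor_gc + amelioration[cls] * (background_gc[sp] - donor_gc),
                     background_gc[sp])
    if (any(target <= 0 | target >= 1)) stop("GC target outside (0, 1)")
    seqs <- vapply(target, function(p) {
      gc <- stats::runif(length_bp) < p
      strong <- sample(c("G", "C"), length_bp, replace = TRUE)
      weak <- sample(c("A", "T"), length_bp, replace = TRUE)
      paste(ifelse(gc, strong, weak), collapse = "")
    }, character(1L))
    rows[[sp]] <- data.frame(
      id = paste0(sp, "|", gids), species = sp, sequence = seqs,
      length_bp = length_bp, fpkm = 10, isopct = 100,
      group_id = gids, foreign = unname(is_f), class = unname(cls),
      gc_target = unname(target), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate partitioned BLAST hit tables with target h_U structure
#'
#' For each transcript a best metazoan bitscore is drawn, and the best
#' non-metazoan bitscore is placed so that \eqn{h_U} is Gaussian around
#' the class mean (`foreign_mean` for foreign transcripts, `native_mean`
#' otherwise), truncated at zero. E-values follow the fixed monotone map
#' `e = K * 2^(-bitscore)`, so ordering by bitscore and by e-value agree.
#' The foreign hit is assigned to a random donor partition.
#'
#' @param transcript_ids character vector.
#' @param foreign logical vector: intended class per transcript.
#' @param foreign_mean,native_mean,sd h_U distribution parameters.
#' @param base_bitscore mean of the metazoan best bitscore.
#' @param evalue_k constant `K` of the bitscore-to-e-value map.
#' @param seed integer seed.
#' @return hit `data.frame` across the six protein partitions.
#' @export
simulate_blast_tables <- function(transcript_ids, foreign,
                                  foreign_mean = 60, native_mean = -40,
                                  sd = 15, base_bitscore = 150,
                                  evalue_k = 1, seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(transcript_ids)
  if (n == 0L) return(empty_hits())
  met <- pmax(stats::rnorm(n, base_bitscore, 20), 60)
  hu <- stats::rnorm(n, ifelse(foreign, foreign_mean, native_mean), sd)
  non <- pmax(met + hu, 0)
  donor <- sample(NONMETAZOAN_PARTITIONS, n, replace = TRUE)
  ev <- function(bits) pmin(evalue_k * 2^(-bits), 1)
  met_hits <- hit_table(transcript_ids, paste0("met_", seq_len(n)),
                        "metazoa", met, ev(met))
  keep <- non > 0
  non_hits <- hit_table(transcript_ids[keep],
                        paste0("non_", seq_len(n))[keep],
                        donor[keep], non[keep], ev(non[keep]))
  rbind(met_hits, non_hits)
}

#' Simulate binomial desiccation-survival data
#'
#' @param p per-species survival probabilities (named vector).
#' @param n individuals tested per species.
#' @param seed integer seed.
#' @return `data.frame` with `species`, `n_tested`, `n_survived`.
#' @export
simulate_survival <- function(p, n = 36L, seed = 1L) {
  if (any(p < 0 | p > 1)) stop("survival probabilities must lie in [0, 1]")
  set.seed(as.integer(seed))
  data.frame(
    species = if (is.null(names(p))) paste0("sp", seq_along(p)) else names(p),
    n_tested = n,
    n_survived = stats::rbinom(length(p), n, p),
    stringsAsFactors = FALSE
  )
}
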