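#' Generate a complete synthetic study on disk
#'
#' Builds a self-consistent set of pipeline inputs: foreign gene content
#' simulated on the dated tree ([simulate_gene_content()]), a native core
#' shared by all taxa, transcript sequences with GC amelioration,
#' partitioned protein hit tables realising the intended h_U classes,
#' pairwise and pooled similarity tables that encode the true ortholog
#' groups, contamination and outgroup-homology tables, genome-scaffold
#' hits for the validation species (with transcriptome false negatives
#' masked at rate `fn_rate`), and binomial survival data. All files are
#' plain text in the formats the readers consume; the ground truth is
#' written alongside as `truth.yaml`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed controlling every random draw.
#' @param n_ancestral ancestral foreign genes at the tree root.
#' @param n_native native core ortholog groups (present in all taxa).
#' @param gain_rate foreign-gene gain rate (events per lineage per My).
#' @param loss_rate per-gene loss hazard (per My). Unlike the gain rate,
#'   this is a per-gene rate; the default 0.02/My lets a substantial
#'   fraction of ancestral acquisitions survive to the tips while still
#'   producing species-specific recent gains, emulating the observed mix
#'   of ancestral and recent foreign genes.
#' @param fn_rate probability that a truly present gene is missing from a
#'   species' transcriptome.
#' @param contam_rate fraction of foreign transcripts given a close
#'   nucleotide-database hit.
#' @param background_gc per-species background GC fractions.
#' @param donor_gc donor GC for unameliorated foreign genes.
#' @param survival_p per-species desiccation survival probabilities.
#' @param config pipeline configuration.
#' @return `out_dir`, invisibly. Side effect: files written.
#' @export
simulate_study <- function(out_dir, seed = 1L, n_ancestral = 150L,
                           n_native = 400L, gain_rate = 12.8,
                           loss_rate = 0.02, fn_rate = 0.08,
                           contam_rate = 0.02,
                           background_gc = c(mag = 0.330, soc = 0.330,
                                             sor = 0.307, tar = 0.321),
                           donor_gc = 0.45,
                           survival_p = c(mag = 0, soc = 0, sor = 0.806,
                                          tar = 0.5),
                           config = default_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  tcf <- config$tree
  tree <- reference_tree(tcf$root_age, tcf$sortar_age, tcf$magsoc_age,
                         outgroup = TRUE, outgroup_age = tcf$outgroup_age)
  write_dated_newick(reference_tree(tcf$root_age, tcf$sortar_age,
                                    tcf$magsoc_age),
                     file.path(out_dir, "tree.nwk"))

  content <- simulate_gene_content(tree, gain_rate, loss_rate, n_ancestral,
                                   seed = seed + 1L)
  foreign_pm <- content$presence
  native_pm <- matrix(TRUE, n_native, ncol(foreign_pm),
                      dimnames = list(paste0("n", seq_len(n_native)),
                                      colnames(foreign_pm)))
  truth_pm <- rbind(foreign_pm, native_pm)
  foreign_flag <- stats::setNames(
    c(rep(TRUE, nrow(foreign_pm)), rep(FALSE, n_native)), rownames(truth_pm))

  # transcriptome false negatives: mask ingroup cells of the expressed matrix
  expressed <- truth_pm
  mask <- matrix(stats::runif(length(expressed)) < fn_rate,
                 nrow(expressed), ncol(expressed),
                 dimnames = dimnames(expressed))
  mask[, OUTGROUP_TAXON] <- FALSE
  expressed[mask] <- FALSE
  expressed <- expressed[rowSums(expressed[, INGROUP_TAXA]) > 0L, ,
                         drop = FALSE]

  dist_lab <- vapply(rownames(expressed), function(g) {
    classify_distribution(INGROUP_TAXA[expressed[g, INGROUP_TAXA]],
                          expressed[g, OUTGROUP_TAXON])
  }, character(1L))

  transcripts <- simulate_transcripts(
    expressed[, INGROUP_TAXA, drop = FALSE],
    foreign_flag[rownames(expressed)], dist_lab, background_gc,
    donor_gc = donor_gc, seed = seed + 2L)
  for (sp in INGROUP_TAXA) {
    write_transcript_fasta(transcripts[transcripts$species == sp, ],
                           file.path(out_dir, paste0(sp, ".fasta")))
  }

  hits <- simulate_blast_tables(transcripts$id, transcripts$foreign,
                                seed = seed + 3L)
  for (part in unique(hits$partition)) {
    write_blast_tab(hits[hits$partition == part, ],
                    file.path(out_dir, paste0("hits_", part, ".tsv")))
  }

  # pairwise similarity implied by shared group membership
  pair_dir <- file.path(out_dir, "pairwise")
  dir.create(pair_dir, showWarnings = FALSE)
  for (a in INGROUP_TAXA) for (b in INGROUP_TAXA) {
    if (a == b) next
    both <- rownames(expressed)[expressed[, a] & expressed[, b]]
    tab <- if (length(both) > 0L) {
      hit_table(paste0(a, "|", both), paste0(b, "|", both), "nt",
                bitscore = 500, evalue = 1e-60)
    } else empty_hits("nt")
    write_blast_tab(tab, file.path(pair_dir, paste0(a, "__", b, ".tsv")))
  }

  # pooled all-vs-all graph (ingroup + outgroup transcripts)
  og_rows <- rownames(expressed)[expressed[, OUTGROUP_TAXON]]
  node_tab <- rbind(
    transcripts[, c("id", "species", "group_id")],
    if (length(og_rows) > 0L) data.frame(
      id = paste0(OUTGROUP_TAXON, "|", og_rows), species = OUTGROUP_TAXON,
      group_id = og_rows, stringsAsFactors = FALSE) else NULL
  )
  all_hits <- do.call(rbind, lapply(split(node_tab$id, node_tab$group_id),
                                    function(ids) {
    if (length(ids) < 2L) return(NULL)
    pr <- t(utils::combn(ids, 2L))
    hit_table(pr[, 1L], pr[, 2L], "nt", bitscore = 500, evalue = 1e-60)
  }))
  if (is.null(all_hits)) all_hits <- empty_hits("nt")
  write_blast_tab(all_hits, file.path(out_dir, "hits_all.tsv"))
  utils::write.table(node_tab, file.path(out_dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # outgroup homology of member transcripts
  og_groups <- rownames(expressed)[expressed[, OUTGROUP_TAXON]]
  og_members <- transcripts$id[transcripts$group_id %in% og_groups]
  og_hits <- if (length(og_members) > 0L) {
    hit_table(og_members, paste0(OUTGROUP_TAXON, "|",
                                 sub("^[^|]*\\|", "", og_members)),
              "outgroup", bitscore = 400, evalue = 1e-40)
  } else empty_hits("outgroup")
  write_blast_tab(og_hits, file.path(out_dir, "hits_outgroup.tsv"))

  # contamination candidates among foreign transcripts
  f_ids <- transcripts$id[transcripts$foreign]
  n_cand <- round(contam_rate * length(f_ids))
  cand <- if (n_cand > 0L) sample(f_ids, n_cand) else character(0)
  nt_hits <- if (length(cand) > 0L) {
    hit_table(cand, paste0("ntdb_", seq_along(cand)), "nt",
              bitscore = 300, evalue = 1e-08)
  } else empty_hits("nt")
  write_blast_tab(nt_hits, file.path(out_dir, "hits_nt.tsv"))

  # genome scaffolds of the validation species reflect TRUE presence
  val_sp <- "mag"
  in_genome <- rownames(truth_pm)[truth_pm[, val_sp]]
  gen_members <- transcripts$id[transcripts$group_id %in% in_genome]
  genome_hits <- if (length(gen_members) > 0L) {
    hit_table(gen_members, paste0("scaffold_",
                                  sub("^[^|]*\\|", "", gen_members)),
              "genome", bitscore = 400, evalue = 1e-30)
  } else empty_hits("genome")
  write_blast_tab(genome_hits, file.path(out_dir, "hits_genome.tsv"))

  surv <- simulate_survival(survival_p, seed = seed + 4L)
  utils::write.table(surv, file.path(out_dir, "survival.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  truth <- list(
    seed = as.integer(seed), gain_rate = gain_rate, loss_rate = loss_rate,
    fn_rate = fn_rate, n_foreign_groups = nrow(foreign_pm),
    n_native_groups = n_native,
    foreign_fraction = mean(transcripts$foreign),
    true_gains = content$events$gains[
      match(c(INGROUP_TAXA, "stem_magsoc", "stem_sortar"),
            content$events$branch)]
  )
  yaml::write_yaml(truth, file.path(out_dir, "truth.yaml"))
  write_config(config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Load a study directory written by [simulate_study()]
#'
#' @param dir study directory.
#' @return list of in-memory pipeline inputs.
#' @export
load_study <- function(dir) {
  cfg <- read_config(file.path(dir, "config.yaml"))
  transcripts <- do.call(rbind, lapply(INGROUP_TAXA, function(sp) {
    read_transcript_fasta(file.path(dir, paste0(sp, ".fasta")), species = sp)
  }))
  prot <- do.call(rbind, lapply(
    c("metazoa", NONMETAZOAN_PARTITIONS), function(part) {
      f <- file.path(dir, paste0("hits_", part, ".tsv"))
      if (file.exists(f)) parse_blast_tab(f, part) else NULL
    }))
  pair_files <- list.files(file.path(dir, "pairwise"), full.names = TRUE)
  pair_hits <- lapply(pair_files, parse_blast_tab, partition = "nt")
  names(pair_hits) <- sub("\\.tsv$", "", basename(pair_files))
  nodes <- utils::read.delim(file.path(dir, "nodes.tsv"),
                             stringsAsFactors = FALSE)
  list(
    config = cfg,
    transcripts = transcripts,
    protein_hits = prot,
    pair_hits = pair_hits,
    all_hits = parse_blast_tab(file.path(dir, "hits_all.tsv"), "nt"),
    all_nodes = nodes,
    nt_hits = parse_blast_tab(file.path(dir, "hits_nt.tsv"), "nt"),
    outgroup_hits = parse_blast_tab(file.path(dir, "hits_outgroup.tsv"),
                                    "outgroup"),
    genome_hits = parse_blast_tab(file.path(dir, "hits_genome.tsv"),
                                  "genome"),
    tree = parse_dated_newick(file.path(dir, "tree.nwk")),
    survival = utils::read.delim(file.path(dir, "survival.tsv"),
                                 stringsAsFactors = FALSE)
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — HGT calling, contamination screening,
#' orthology (both methods), genome validation and false-negative
#' correction, gain/loss rate estimation, and the comparative statistics —
#' writing one TSV per stage plus a machine-readable JSON manifest of
#' thresholds, seeds and per-stage row counts. A stage failure stops the
#' run with the stage name in the error.
#'
#' @param study input list from [load_study()] (or assembled in memory in
#'   the same layout).
#' @param out_dir output directory.
#' @param seed integer seed for the rate Monte-Carlo.
#' @return list of in-memory stage results, invisibly; side effect:
#'   files in `out_dir`.
#' @export
run_pipeline <- function(study, out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- study$config %||% default_config()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list(seed = as.integer(seed), config = cfg, stages = list())
  note <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }

  calls <- stage("hgt_index", {
    do.call(rbind, lapply(split(study$transcripts, study$transcripts$species),
                          function(tr) {
      hits <- study$protein_hits[study$protein_hits$query_id %in% tr$id, ]
      call_hgt(tr, hits, cfg)
    }))
  })
  rownames(calls) <- NULL
  utils::write.table(calls, file.path(out_dir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("hgt_index", n_transcripts = nrow(calls),
       n_foreign = sum(calls$status == "foreign"))

  contam <- stage("contamination", {
    flag_contaminants(calls, study$nt_hits, study$outgroup_hits,
                      cfg$contamination$nt_evalue_max,
                      cfg$contamination$rescue_evalue_max)
  })
  calls <- contam$calls
  utils::write.table(calls, file.path(out_dir, "calls_clean.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("contamination", n_candidates = nrow(contam$report),
       n_removed = sum(contam$report$decision == "removed"),
       n_transcripts = nrow(calls))

  orth <- stage("orthology", {
    rbh <- reciprocal_best_hits(study$pair_hits,
                                species = cfg$taxa$ingroup,
                                evalue_max = cfg$orthology$rbh_evalue_max)
    rbh <- attach_outgroup(rbh, study$outgroup_hits,
                           cfg$orthology$outgroup_evalue_max)
    rbh <- classify_distributions(designate_foreign_groups(rbh, calls))
    mcl <- mcl_ortho_groups(study$all_hits, study$all_nodes, cfg)
    mcl <- classify_distributions(designate_foreign_groups(mcl, calls))
    list(rbh = rbh, mcl = mcl)
  })
  for (m in names(orth)) {
    g <- merge(orth[[m]]$groups,
               stats::aggregate(transcript_id ~ group_id,
                                orth[[m]]$members, paste, collapse = ";"),
               by = "group_id")
    utils::write.table(g, file.path(out_dir, paste0("orthologs_", m, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  note("orthology", n_rbh = nrow(orth$rbh$groups),
       n_mcl = nrow(orth$mcl$groups),
       n_foreign_mcl = sum(orth$mcl$groups$foreign))

  groups <- orth$mcl
  valid <- stage("genome_validation", {
    gp <- genome_presence(groups, study$genome_hits, cfg$genome$evalue_max)
    cross <- gp$recovery[grepl("^unique\\((?!mag)", gp$recovery$distribution,
                               perl = TRUE), , drop = FALSE]
    model <- if (nrow(cross) > 0L && all(cross$fraction < 1)) {
      estimate_fn_rates(cross$fraction)
    } else {
      estimate_fn_rates(0)
    }
    pm <- presence_matrix(groups, foreign_only = TRUE)
    corr <- correct_category_counts(pm, model)
    list(presence = gp, model = model, counts = corr)
  })
  utils::write.table(
    data.frame(species = rownames(valid$counts$observed),
               valid$counts$observed, check.names = FALSE),
    file.path(out_dir, "counts_observed.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(species = rownames(valid$counts$corrected),
               valid$counts$corrected, check.names = FALSE),
    file.path(out_dir, "counts_corrected.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  note("genome_validation", pooled_fn = valid$model$pooled)

  rates <- stage("gainloss", {
    pm <- presence_matrix(groups, foreign_only = TRUE)
    write_presence_matrix(pm, file.path(out_dir, "presence.tsv"))
    events <- reconstruct_events(pm)
    estimate_rates(events, study$tree, seed = seed,
                   n_draws = cfg$rates$n_draws)
  })
  utils::write.table(rates, file.path(out_dir, "rates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("gainloss", pooled_gain = rates$rate[rates$branch == "pooled" &
                                              rates$type == "gain"])

  stats_out <- stage("stats", {
    out <- list()
    if (!is.null(study$survival)) {
      s <- study$survival
      out$survival_kprop <- chisq_proportions_k(s$n_survived, s$n_tested)
      hgt_prop <- tapply(calls$status == "foreign",
                         calls$species,
                         function(z) mean(z[TRUE]))
      retained <- tapply(calls$status %in% c("foreign", "native"),
                         calls$species, sum)
      foreign_n <- tapply(calls$status == "foreign", calls$species, sum)
      prop <- foreign_n[s$species] / retained[s$species]
      out$pgls <- pgls_arcsine(
        stats::setNames(prop, s$species),
        stats::setNames(s$n_survived / s$n_tested, s$species),
        study$tree, lambda = 1)
    }
    g <- groups$groups
    f_groups <- g$group_id[which(g$foreign)]
    tr <- study$transcripts
    gid <- groups$members$group_id[match(tr$id, groups$members$transcript_id)]
    keep <- !is.na(gid) & gid %in% f_groups
    if (any(keep)) {
      bg <- tapply(gc_content(tr$sequence), tr$species, mean)
      out$gc <- gc_trend(gc_content(tr$sequence[keep]),
                         tr$species[keep],
                         g$distribution[match(gid[keep], g$group_id)],
                         bg)
    }
    out
  })
  report <- list(
    survival_chisq = stats_out$survival_kprop$statistic %||% NA,
    pgls_slope = stats_out$pgls$slope %||% NA,
    gc_overall_rho = stats_out$gc$overall$rho %||% NA
  )
  note("stats", report = report)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(calls = calls, orthology = orth, validation = valid,
                 rates = rates, stats = stats_out, manifest = manifest))
}
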