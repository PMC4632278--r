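pair_tables <- function(edges, species) {
  # edges: data.frame(qsp, q, ssp, s, bits) describing directed best-hit rows
  out <- list()
  for (a in species) for (b in species) {
    if (a == b) next
    key <- paste0(a, "__", b)
    sel <- edges$qsp == a & edges$ssp == b
    out[[key]] <- if (any(sel)) {
      hit_table(edges$q[sel], edges$s[sel], "nt", edges$bits[sel],
                2^(-edges$bits[sel]))
    } else empty_hits("nt")
  }
  out
}

test_that("consistent reciprocal-best-hit cliques are retained", {
  sp <- c("A", "B", "C")
  ed <- data.frame(
    qsp = c("A", "B", "B", "C", "A", "C"),
    q = c("a1", "b1", "b1", "c1", "a1", "c1"),
    ssp = c("B", "A", "C", "B", "C", "A"),
    s = c("b1", "a1", "c1", "b1", "c1", "a1"),
    bits = 200, stringsAsFactors = FALSE
  )
  og <- reciprocal_best_hits(pair_tables(ed, sp), species = sp)
  expect_equal(nrow(og$groups), 1L)
  expect_setequal(og$members$transcript_id, c("a1", "b1", "c1"))
  expect_equal(nrow(og$dropped), 0L)
})

test_that("one-sided best hits form no RBH edge", {
  sp <- c("A", "B")
  ed <- data.frame(
    qsp = c("A", "B"), q = c("a1", "b1"),
    ssp = c("B", "A"), s = c("b1", "a2"),   # b1's best is a2, not a1
    bits = 200, stringsAsFactors = FALSE
  )
  og <- reciprocal_best_hits(pair_tables(ed, sp), species = sp)
  expect_equal(nrow(og$groups), 0L)
})

test_that("components missing a cross edge are dropped as inconsistent", {
  sp <- c("A", "B", "C")
  # a1-b1 and b1-c1 are RBHs, but a1's best in C is c2 (and c2's best is a1,
  # though c2 is outside the component's chain through b1)
  ed <- data.frame(
    qsp = c("A", "B", "B", "C", "A", "C"),
    q = c("a1", "b1", "b1", "c1", "a1", "c2"),
    ssp = c("B", "A", "C", "B", "C", "A"),
    s = c("b1", "a1", "c1", "b1", "c2", "a1"),
    bits = 200, stringsAsFactors = FALSE
  )
  og <- reciprocal_best_hits(pair_tables(ed, sp), species = sp)
  # the component contains a1, b1, c1, c2 -> two C transcripts
  expect_equal(nrow(og$groups), 0L)
  expect_gte(nrow(og$dropped), 1L)
  expect_true(all(og$dropped$reason %in%
                    c("duplicate_species", "missing_edge")))
})

test_that("RBH output is invariant to hit-table row order", {
  sp <- c("A", "B", "C")
  # two clean three-species groups
  mk <- function(i) data.frame(
    qsp = c("A", "B", "B", "C", "A", "C"),
    q = paste0(c("a", "b", "b", "c", "a", "c"), i),
    ssp = c("B", "A", "C", "B", "C", "A"),
    s = paste0(c("b", "a", "c", "b", "c", "a"), i),
    bits = 200 + i, stringsAsFactors = FALSE)
  ed <- rbind(mk(1), mk(2))
  tabs <- pair_tables(ed, sp)
  og1 <- reciprocal_best_hits(tabs, species = sp)
  tabs_shuffled <- lapply(tabs, function(t) t[rev(seq_len(nrow(t))), ])
  og2 <- reciprocal_best_hits(tabs_shuffled, species = sp)
  key <- function(og) {
    m <- og$members[order(og$members$transcript_id), ]
    unname(split(m$transcript_id, m$group_id)[
      order(vapply(split(m$transcript_id, m$group_id), min, character(1L)))])
  }
  expect_equal(key(og1), key(og2))
})

test_that("outgroup attachment respects the e-value boundary", {
  members <- data.frame(group_id = c("g1", "g1", "g2"),
                        species = c("mag", "soc", "sor"),
                        transcript_id = c("m1", "s1", "r1"),
                        stringsAsFactors = FALSE)
  og <- ortho_groups(members, "rbh")
  hits <- rbind(hit_table("m1", "Ar1", "outgroup", 100, 1e-12),
                hit_table("r1", "Ar2", "outgroup", 50, 1e-09))
  og <- attach_outgroup(og, hits)
  expect_true(og$groups$outgroup_present[og$groups$group_id == "g1"])
  expect_false(og$groups$outgroup_present[og$groups$group_id == "g2"])
  og2 <- attach_outgroup(ortho_groups(members, "rbh"), empty_hits("outgroup"))
  expect_false(any(og2$groups$outgroup_present))
})

clique_edges <- function(ids, w) {
  pr <- t(utils::combn(ids, 2L))
  data.frame(node1 = pr[, 1L], node2 = pr[, 2L], weight = w,
             stringsAsFactors = FALSE)
}

test_that("MCL separates disjoint cliques and keeps isolated singletons", {
  e <- rbind(clique_edges(paste0("a", 1:3), 40),
             clique_edges(paste0("b", 1:3), 40))
  res <- mcl_cluster(e, inflation = 20)
  expect_equal(res$n_clusters, 2L)
  sig <- partition_signature(res$membership)
  expect_equal(sig, list(paste0("a", 1:3), paste0("b", 1:3)))

  res2 <- mcl_cluster(e[0, ], nodes = "lonely", inflation = 20)
  expect_equal(res2$n_clusters, 1L)
  expect_equal(names(res2$membership), "lonely")
})

test_that("weakly bridged cliques split at high inflation, agreeing with the
           reference implementation", {
  e <- rbind(clique_edges(paste0("a", 1:4), 50),
             clique_edges(paste0("b", 1:4), 50),
             data.frame(node1 = "a1", node2 = "b1", weight = 1))
  res <- mcl_cluster(e, inflation = 20)
  expect_equal(res$n_clusters, 2L)
  ref <- mcl_reference(e, inflation = 20)
  expect_equal(partition_signature(res$membership),
               partition_signature(ref))
})

test_that("MCL clusters partition the node set across inflation extremes", {
  e <- rbind(clique_edges(paste0("a", 1:4), 50),
             clique_edges(paste0("b", 1:4), 50),
             data.frame(node1 = "a1", node2 = "b1", weight = 25),
             data.frame(node1 = "a2", node2 = "hanger", weight = 2))
  for (infl in c(1.2, 5, 20, 60)) {
    res <- suppressWarnings(mcl_cluster(e, inflation = infl))
    expect_equal(sort(names(res$membership)),
                 sort(unique(c(e$node1, e$node2))))
    expect_false(any(is.na(res$membership)))  # full coverage, no overlap
  }
  # near-1 inflation on a connected graph: a single cluster
  low <- suppressWarnings(mcl_cluster(e, inflation = 1.05))
  expect_equal(low$n_clusters, 1L)
  # granularity grows with inflation and matches the reference
  # implementation at both extremes
  for (infl in c(2, 60)) {
    mine <- suppressWarnings(mcl_cluster(e, inflation = infl))
    ref <- mcl_reference(e, inflation = infl)
    expect_equal(partition_signature(mine$membership),
                 partition_signature(ref), label = paste("inflation", infl))
  }
  n_lo <- suppressWarnings(mcl_cluster(e, inflation = 2))$n_clusters
  n_hi <- suppressWarnings(mcl_cluster(e, inflation = 60))$n_clusters
  expect_lte(n_lo, n_hi)
})

test_that("foreign designation is a strict majority over ingroup members", {
  members <- data.frame(
    group_id = rep(c("g1", "g2", "g3"), c(4L, 4L, 1L)),
    species = c(INGROUP_TAXA, INGROUP_TAXA, "mag"),
    transcript_id = paste0("t", 1:9), stringsAsFactors = FALSE
  )
  status <- c("foreign", "foreign", "foreign", "native",   # 3/4
              "foreign", "foreign", "native", "native",    # 2/4 exactly half
              "foreign")                                   # 1/1
  calls <- data.frame(transcript_id = paste0("t", 1:9), status = status,
                      stringsAsFactors = FALSE)
  og <- designate_foreign_groups(ortho_groups(members, "rbh"), calls)
  expect_equal(og$groups$foreign[match(c("g1", "g2", "g3"),
                                       og$groups$group_id)],
               c(TRUE, FALSE, TRUE))
  expect_error(
    designate_foreign_groups(ortho_groups(members, "rbh"), calls[-1L, ]),
    "without an HGT call"
  )
})

test_that("distribution classes follow the span and outgroup rules", {
  expect_equal(classify_distribution(c("sor", "tar"), FALSE), "sister(sortar)")
  expect_equal(classify_distribution("mag", TRUE), "shared_outgroup")
  expect_equal(classify_distribution(c("mag", "sor"), FALSE), "genus")
  expect_equal(classify_distribution(c("mag", "soc", "sor"), FALSE), "genus")
  expect_equal(classify_distribution("tar", FALSE), "unique(tar)")
  expect_equal(classify_distribution(c("mag", "soc"), FALSE), "sister(magsoc)")
  expect_error(classify_distribution(character(0), FALSE), "empty")
})

test_that("per-species class counts sum to the species' foreign-group total", {
  set.seed(7)
  n <- 60L
  pm <- matrix(stats::runif(n * 5) < 0.5, n, 5,
               dimnames = list(sprintf("g%02d", 1:n),
                               c(INGROUP_TAXA, OUTGROUP_TAXON)))
  pm <- pm[rowSums(pm[, INGROUP_TAXA]) > 0L, ]
  members <- do.call(rbind, lapply(rownames(pm), function(g) {
    sp <- INGROUP_TAXA[pm[g, INGROUP_TAXA]]
    data.frame(group_id = g, species = sp,
               transcript_id = paste0(sp, "|", g), stringsAsFactors = FALSE)
  }))
  og <- ortho_groups(members, "mcl",
                     outgroup_present = pm[, OUTGROUP_TAXON])
  og$groups$foreign <- TRUE
  og <- classify_distributions(og)
  counts <- count_distributions(og)
  for (sp in INGROUP_TAXA) {
    expect_equal(counts[sp, "total"],
                 sum(counts[sp, c("unique", "sister", "genus",
                                  "shared_outgroup")]))
    expect_equal(counts[sp, "total"], sum(pm[, sp]))
  }
})

test_that("pooled MCL orthology recovers constructed groups with outgroup
           flags", {
  # three groups: one spanning all taxa + outgroup, one sister pair, one
  # unique; similarity edges exist only within groups
  nodes <- data.frame(
    id = c(paste0(c("mag", "soc", "sor", "tar", "outgroup"), "|g1"),
           paste0(c("sor", "tar"), "|g2"), "mag|g3"),
    species = c("mag", "soc", "sor", "tar", "outgroup", "sor", "tar", "mag"),
    stringsAsFactors = FALSE
  )
  grp <- sub("^.*\\|", "", nodes$id)
  hits <- do.call(rbind, lapply(unique(grp), function(g) {
    ids <- nodes$id[grp == g]
    if (length(ids) < 2L) return(NULL)
    pr <- t(utils::combn(ids, 2L))
    hit_table(pr[, 1L], pr[, 2L], "nt", 300, 1e-60)
  }))
  og <- mcl_ortho_groups(hits, nodes)
  expect_equal(nrow(og$groups), 3L)
  og <- classify_distributions(og)
  d <- sort(og$groups$distribution)
  expect_equal(d, sort(c("shared_outgroup", "sister(sortar)", "unique(mag)")))
})
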