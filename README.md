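# hgtpipe

Detection, phylogenetic distribution and gain/loss rate estimation of
horizontally transferred genes in animal transcriptomes.

Bdelloid rotifers carry far more genes of non-metazoan origin than is
typical for animals, plausibly acquired during desiccation–rehydration
cycles that break and repair chromosomes. Comparing four congeneric
species (two permanently aquatic, two from desiccating habitats,
abbreviated `mag`, `soc`, `sor`, `tar`) plus a family-level outgroup
makes it possible to ask whether horizontal gene transfer (HGT) is
ancient or ongoing, and whether desiccating lineages acquire foreign
genes faster. `hgtpipe` implements that full inference chain for anyone
analysing transcriptome BLAST results against partitioned protein
databases:

1. **Detection.** Per transcript, the HGT index
   *h<sub>U</sub>* = (best non-metazoan bitscore) − (best metazoan
   bitscore), over six database partitions; *h<sub>U</sub>* ≥ 30 calls a
   transcript foreign and assigns a donor kingdom
   (`call_hgt()`, `compute_hu()`, `sensitivity_sweep()`).
2. **Contamination screening** with rescue by outgroup homology
   (`flag_contaminants()`).
3. **Orthology** by consistent reciprocal best hits and by a from-scratch
   Markov clustering (MCL) of the pooled similarity graph
   (`reciprocal_best_hits()`, `mcl_cluster()`), foreign groups by
   majority rule, and distribution classes
   unique / sister / genus / shared-with-outgroup
   (`classify_distributions()`).
4. **False-negative correction** of distribution counts from
   genome-presence BLAST results (`estimate_fn_rates()`,
   `correct_category_counts()`).
5. **Gain/loss rates.** Parsimony-unambiguous gains and losses on the
   dated tree `((mag,soc),(sor,tar))` (crown ages 29 / 14.2 / 6.9 My),
   Poisson rates per branch with 95% highest-density intervals
   (`reconstruct_events()`, `estimate_rates()`, `hpd_interval()`).
6. **Comparative statistics**: proportion tests (k-sample and
   Yates-corrected 2×2), Fisher exact, Spearman, Monte-Carlo chi-square,
   Welch t, PGLS with Pagel's λ on arcsine-square-root proportions, gene
   tree topology classification over the 15 rooted four-taxon shapes,
   and GC-amelioration trends.

A synthetic-data module (`simulate_study()` and friends) generates
complete, internally consistent studies — gene content evolved on the
dated tree, transcripts with GC amelioration, bitscore tables realising
chosen *h<sub>U</sub>* distributions, contamination, genome validation
with masked false negatives, survival assays — so the entire pipeline is
testable offline.

## Worked example

```r
library(hgtpipe)

study_dir <- tempfile("rotifer_demo")
simulate_study(study_dir, seed = 42, n_ancestral = 60L, n_native = 120L)
study <- load_study(study_dir)
res <- run_pipeline(study, tempfile("results"), seed = 42)

table(res$calls$status)
#> contaminant     foreign      native
#>          35        1776         475
```

2,286 simulated transcripts were scored: 1,776 called foreign
(*h<sub>U</sub>* ≥ 30), 35 of those flagged and removed as contaminants
(close nucleotide-database match, no outgroup rescue), the rest native.

```r
counts <- count_distributions(classify_distributions(res$orthology$mcl))
counts
#>     unique sister genus shared_outgroup total
#> mag    138    190   120               8   456
#> soc    103    190   119               7   419
#> sor    221    119    96               7   443
#> tar    205    119   115               7   446
```

Per species, the foreign Markov-cluster groups split by phylogenetic
breadth — genes unique to that species, shared with its sister only,
spread across the genus, or shared with the outgroup. Rows sum to each
species' foreign-group total.

```r
subset(res$rates, branch %in% c("pooled", "clade_magsoc", "clade_sortar") &
                  type == "gain")
#>         branch type events duration     rate     mean  hpd_low hpd_high
#> 7 clade_magsoc gain    431     35.9 12.00557 12.01376 10.86351 13.11978
#> 8 clade_sortar gain    545     43.2 12.61574 12.61013 11.55093 13.63426
#> 9       pooled gain    976     79.1 12.33881 12.33947 11.59292 13.10999
```

976 parsimony-unambiguous gains over 79.1 My of ingroup branch time give
a pooled rate of 12.3 gains per lineage per My with a 95% HPD of
11.6–13.1 — recovering the generating gain rate of 12.8 up to
detectability (genes gained and lost again on the same branch are
invisible).

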