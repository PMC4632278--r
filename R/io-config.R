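#' Default pipeline configuration
#'
#' All thresholds used anywhere in the pipeline, with the values of the
#' reference analysis as defaults. The configuration is a nested list and
#' can be round-tripped through YAML with [read_config()]/[write_config()].
#'
#' * `hgt`: expression/length retention filters, the e-value cutoff for
#'   scoring hits and the \eqn{h_U} threshold for designating a transcript
#'   foreign; `missing_bitscore` is the bitscore substituted for a side
#'   (metazoan or non-metazoan) with no retained hit.
#' * `contamination`: nucleotide-database flagging and outgroup rescue
#'   cutoffs.
#' * `orthology`: reciprocal-best-hit and Markov-clustering parameters.
#' * `genome`: presence threshold against genome scaffolds.
#' * `rates`: Monte-Carlo draws for rate intervals.
#'
#' @return a nested named list.
#' @export
default_config <- function() {
  list(
    taxa = list(
      ingroup = INGROUP_TAXA,
      sister_pairs = lapply(SISTER_PAIRS, identity),
      outgroup = OUTGROUP_TAXON
    ),
    hgt = list(
      fpkm_min = 1, isopct_min = 1, len_min = 200L,
      evalue_max = 1e-05, hu_min = 30, missing_bitscore = 0
    ),
    contamination = list(
      nt_evalue_max = 1e-05, rescue_evalue_max = 1e-10
    ),
    orthology = list(
      rbh_evalue_max = 1e-10,
      outgroup_evalue_max = 1e-10,
      mcl = list(
        inflation = 20, evalue_max = 1e-10, weight_cap = 200,
        prune = 1e-08, convergence = 1e-06, max_iter = 200L,
        include_outgroup = TRUE
      ),
      foreign_majority = 0.5
    ),
    genome = list(evalue_max = 1e-05),
    rates = list(n_draws = 10000L),
    tree = list(
      root_age = 29, sortar_age = 14.2, magsoc_age = 6.9, outgroup_age = 60,
      age_hpd = list(root = c(23.6, 35.7), sortar = c(11.4, 17.3),
                     magsoc = c(5.6, 8.5))
    )
  )
}

#' Read / write pipeline configuration
#'
#' Reads a YAML configuration file, filling unspecified entries from
#' [default_config()].
#'
#' @param path YAML file path.
#' @return the merged configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_config
#' @param config a configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read / write a presence/absence matrix
#'
#' The on-disk format is TSV with header
#' `ortholog_id<TAB>mag<TAB>soc<TAB>sor<TAB>tar<TAB>outgroup` and 0/1 cells.
#' In memory the matrix is logical with ortholog ids as row names.
#'
#' @param path TSV file path.
#' @return logical matrix, taxa as columns.
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "ortholog_id") {
    stop("presence matrix must have first column 'ortholog_id'")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("presence matrix cells must be 0/1")
  rownames(m) <- df$ortholog_id
  m == 1L
}

#' @rdname read_presence_matrix
#' @param presence logical (or 0/1) matrix with ortholog-id row names.
#' @export
write_presence_matrix <- function(presence, path) {
  df <- data.frame(ortholog_id = rownames(presence),
                   `+`(presence, 0L), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
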