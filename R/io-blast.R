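#' Hit-table partitions recognised by the pipeline
#'
#' Six protein partitions are used for the HGT index (one metazoan, five
#' non-metazoan); `nt`, `outgroup` and `genome` tag the nucleotide-database,
#' outgroup-transcriptome and genome-scaffold searches.
#'
#' @export
HIT_PARTITIONS <- c("metazoa", "eubacteria", "archaea", "fungi", "plants",
                    "other_eukaryotes", "nt", "outgroup", "genome")

#' Non-metazoan protein partitions contributing to the HGT index
#' @export
NONMETAZOAN_PARTITIONS <- c("eubacteria", "archaea", "fungi", "plants",
                            "other_eukaryotes")

BLAST6_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
                 "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a 12-column tabular BLAST file
#'
#' Parses the standard `outfmt 6` layout (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`) and tags every
#' row with a partition label. Rows are preserved in file order; alignment
#' coordinates are kept 1-based inclusive as BLAST writes them.
#'
#' @param path path to a tab-separated hit file with at least 12 columns.
#' @param partition one of [HIT_PARTITIONS].
#' @return a `data.frame` of hits with a `partition` column.
#' @export
parse_blast_tab <- function(path, partition) {
  partition <- match.arg(partition, HIT_PARTITIONS)
  if (!file.exists(path)) stop("BLAST table not found: ", path)
  if (file.size(path) == 0L) return(empty_hits(partition))
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (nrow(raw) == 0L) return(empty_hits(partition))
  if (ncol(raw) < 12L) {
    stop("BLAST table ", path, " has ", ncol(raw), " columns; >= 12 required")
  }
  raw <- raw[, 1:12]
  names(raw) <- BLAST6_COLS
  hits <- as_hit_table(raw, partition, source = path)
  hits
}

empty_hits <- function(partition = character(0)) {
  data.frame(
    query_id = character(0), subject_id = character(0),
    pct_identity = numeric(0), aln_length = integer(0),
    mismatch = integer(0), gapopen = integer(0),
    qstart = integer(0), qend = integer(0),
    sstart = integer(0), send = integer(0),
    evalue = numeric(0), bitscore = numeric(0),
    partition = character(0), stringsAsFactors = FALSE
  )
}

as_hit_table <- function(raw, partition, source = "<data>") {
  num <- function(col, what, integer = FALSE) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad) > 0L) {
      stop("non-numeric ", what, " in ", source, " at row ", bad[1L],
           ": '", raw[[col]][bad[1L]], "'")
    }
    if (integer) as.integer(round(v)) else v
  }
  out <- data.frame(
    query_id = raw$query_id,
    subject_id = raw$subject_id,
    pct_identity = num("pct_identity", "percent identity"),
    aln_length = num("aln_length", "alignment length", integer = TRUE),
    mismatch = num("mismatch", "mismatch count", integer = TRUE),
    gapopen = num("gapopen", "gap-open count", integer = TRUE),
    qstart = num("qstart", "query start", integer = TRUE),
    qend = num("qend", "query end", integer = TRUE),
    sstart = num("sstart", "subject start", integer = TRUE),
    send = num("send", "subject end", integer = TRUE),
    evalue = num("evalue", "e-value"),
    bitscore = num("bitscore", "bitscore"),
    partition = partition,
    stringsAsFactors = FALSE
  )
  if (any(out$evalue < 0, na.rm = TRUE)) {
    stop("negative e-value in ", source)
  }
  if (any(out$bitscore < 0, na.rm = TRUE)) {
    stop("negative bitscore in ", source)
  }
  out
}

#' Build a hit table from vectors
#'
#' Convenience constructor used by the simulators and tests; only the fields
#' the pipeline consumes are required, the remaining tabular BLAST columns
#' are filled with placeholder alignment coordinates.
#'
#' @param query_id,subject_id character vectors.
#' @param partition partition label, recycled.
#' @param bitscore,evalue numeric vectors.
#' @param pct_identity,aln_length optional numeric vectors.
#' @return a hit `data.frame` in the same layout as [parse_blast_tab()].
#' @export
hit_table <- function(query_id, subject_id, partition, bitscore, evalue,
                      pct_identity = 90, aln_length = 100L) {
  n <- length(query_id)
  if (any(bitscore < 0)) stop("negative bitscore")
  if (any(evalue < 0)) stop("negative e-value")
  data.frame(
    query_id = query_id, subject_id = subject_id,
    pct_identity = rep_len(pct_identity, n),
    aln_length = rep_len(as.integer(aln_length), n),
    mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = rep_len(as.integer(aln_length), n),
    sstart = 1L, send = rep_len(as.integer(aln_length), n),
    evalue = evalue, bitscore = bitscore,
    partition = rep_len(partition, n),
    stringsAsFactors = FALSE
  )
}

#' Write a hit table as 12-column tabular BLAST
#'
#' @param hits a hit `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  utils::write.table(hits[, BLAST6_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
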