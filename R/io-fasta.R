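#' Read a transcript FASTA file
#'
#' Reads a (possibly multi-line) FASTA file into a transcript table. The
#' first whitespace-delimited token of each header is the transcript id;
#' remaining `key=value` tokens are parsed as metadata, from which `FPKM`
#' and `IsoPct` (case-insensitive) populate the expression columns used by
#' the retention filters.
#'
#' Sequences are uppercased and ambiguity codes other than `N` are replaced
#' by `N`; no positional analysis is done downstream, so only base
#' composition matters.
#'
#' @param path path to a FASTA file.
#' @param species species label attached to every record.
#' @return a `data.frame` with columns `id`, `species`, `sequence`,
#'   `length_bp`, `fpkm`, `isopct`. Missing expression metadata yields `NA`.
#' @export
read_transcript_fasta <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    return(empty_transcripts())
  }
  first <- nonempty[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: sequence line before first header at line ", first)
  }
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate transcript ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  meta <- parse_header_metadata(headers)
  sequence <- toupper(as.character(seqs))
  sequence <- gsub("[^ACGTN]", "N", sequence)
  data.frame(
    id = ids,
    species = rep(species, length(ids)),
    sequence = unname(sequence),
    length_bp = nchar(sequence),
    fpkm = meta$fpkm,
    isopct = meta$isopct,
    stringsAsFactors = FALSE
  )
}

empty_transcripts <- function() {
  data.frame(
    id = character(0), species = character(0), sequence = character(0),
    length_bp = integer(0), fpkm = numeric(0), isopct = numeric(0),
    stringsAsFactors = FALSE
  )
}

parse_header_metadata <- function(headers) {
  grab <- function(h, key) {
    m <- regmatches(h, regexpr(paste0("(?i)\\b", key, "=[-0-9.eE+]+"), h, perl = TRUE))
    if (length(m) == 0L) NA_real_ else as.numeric(sub(".*=", "", m))
  }
  list(
    fpkm = vapply(headers, grab, numeric(1L), key = "FPKM", USE.NAMES = FALSE),
    isopct = vapply(headers, grab, numeric(1L), key = "IsoPct", USE.NAMES = FALSE)
  )
}

#' Write a transcript table to FASTA
#'
#' Headers carry the id followed by `FPKM=` and `IsoPct=` tokens when those
#' columns are non-missing, so a write/read round trip preserves ids,
#' sequences and expression metadata.
#'
#' @param transcripts a transcript `data.frame` as returned by
#'   [read_transcript_fasta()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(transcripts, path) {
  hdr <- transcripts$id
  extra <- character(nrow(transcripts))
  has_fpkm <- !is.na(transcripts$fpkm)
  extra[has_fpkm] <- paste0(" FPKM=", format(transcripts$fpkm[has_fpkm], trim = TRUE))
  has_iso <- !is.na(transcripts$isopct)
  extra[has_iso] <- paste0(extra[has_iso], " IsoPct=",
                           format(transcripts$isopct[has_iso], trim = TRUE))
  x <- Biostrings::BStringSet(transcripts$sequence)
  names(x) <- paste0(hdr, extra)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' GC fraction of a nucleotide sequence
#'
#' Computed over unambiguous bases only: `(G + C) / (A + C + G + T)`.
#' `N` and other ambiguity codes are excluded from both numerator and
#' denominator.
#'
#' @param seq character vector of nucleotide sequences.
#' @return numeric vector of GC fractions in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  vapply(seq, function(s) {
    s <- toupper(s)
    bases <- strsplit(s, "")[[1L]]
    gc <- sum(bases %in% c("G", "C"))
    at <- sum(bases %in% c("A", "T"))
    if (gc + at == 0L) {
      stop("GC content undefined: sequence has no unambiguous bases")
    }
    gc / (gc + at)
  }, numeric(1L), USE.NAMES = FALSE)
}
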