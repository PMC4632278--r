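#' Apply transcript retention filters
#'
#' Transcripts are retained for HGT detection if expression passes both
#' thresholds (`fpkm >= fpkm_min` and `isopct >= isopct_min`) and the
#' transcript is strictly longer than `len_min` bp. Exclusion reasons are
#' assigned by the first failing rule, in the fixed order expression then
#' length, so tallies are reproducible. Missing (`NA`) expression metadata
#' passes the expression filter.
#'
#' @param transcripts transcript `data.frame` (see [read_transcript_fasta()]).
#' @param fpkm_min,isopct_min,len_min retention thresholds.
#' @return list with `retained` (transcript `data.frame`), `excluded`
#'   (`data.frame` of `id`, `reason`), and `tally` (named counts by reason).
#' @export
filter_transcripts <- function(transcripts, fpkm_min = 1, isopct_min = 1,
                               len_min = 200L) {
  low_expr <- (!is.na(transcripts$fpkm) & transcripts$fpkm < fpkm_min) |
    (!is.na(transcripts$isopct) & transcripts$isopct < isopct_min)
  short <- !low_expr & transcripts$length_bp <= len_min
  reason <- rep(NA_character_, nrow(transcripts))
  reason[low_expr] <- "excluded_low_expression"
  reason[short] <- "excluded_short"
  keep <- is.na(reason)
  list(
    retained = transcripts[keep, , drop = FALSE],
    excluded = data.frame(id = transcripts$id[!keep],
                          reason = reason[!keep],
                          stringsAsFactors = FALSE),
    tally = c(excluded_low_expression = sum(low_expr),
              excluded_short = sum(short),
              retained = sum(keep))
  )
}

#' Compute the HGT index h_U per transcript
#'
#' For each query transcript, hits with e-value above `evalue_max` are
#' discarded; the best (maximum) retained bitscore is taken on the metazoan
#' side and across the five non-metazoan protein partitions, and
#' \eqn{h_U =} best non-metazoan bitscore \eqn{-} best metazoan bitscore.
#' Transcripts with no retained hit in any partition are
#' `excluded_no_hit`. A side with no retained hit contributes
#' `missing_bitscore` (default 0), so \eqn{h_U} then equals the other
#' side's bitscore; this convention is flagged in the `missing_side`
#' column. Status is `foreign` iff \eqn{h_U \ge} `hu_min` (the boundary
#' value itself is foreign), else `native`.
#'
#' @param hits hit `data.frame` over the six protein partitions.
#' @param transcript_ids ids to score; defaults to all query ids present in
#'   `hits`. Ids without hits are reported `excluded_no_hit`.
#' @param evalue_max e-value cutoff for retaining a hit.
#' @param hu_min foreign threshold on \eqn{h_U}.
#' @param missing_bitscore bitscore substituted for an absent side.
#' @return calls `data.frame`: `transcript_id`, `best_metazoan_bitscore`,
#'   `best_nonmetazoan_bitscore`, `h_u`, `status`, `donor_kingdom`,
#'   `missing_side`.
#' @export
compute_hu <- function(hits, transcript_ids = NULL, evalue_max = 1e-05,
                       hu_min = 30, missing_bitscore = 0) {
  if (any(hits$bitscore < 0, na.rm = TRUE)) stop("negative bitscore in hits")
  prot <- hits[hits$partition %in% c("metazoa", NONMETAZOAN_PARTITIONS), ,
               drop = FALSE]
  kept <- prot[prot$evalue <= evalue_max, , drop = FALSE]
  if (is.null(transcript_ids)) transcript_ids <- unique(prot$query_id)
  n <- length(transcript_ids)
  best_side <- function(side_rows) {
    b <- rep(NA_real_, n)
    if (nrow(side_rows) > 0L) {
      agg <- tapply(side_rows$bitscore, side_rows$query_id, max)
      idx <- match(names(agg), transcript_ids)
      ok <- !is.na(idx)
      b[idx[ok]] <- as.numeric(agg)[ok]
    }
    b
  }
  best_met <- best_side(kept[kept$partition == "metazoa", , drop = FALSE])
  best_non <- best_side(kept[kept$partition %in% NONMETAZOAN_PARTITIONS, ,
                             drop = FALSE])
  no_hit <- is.na(best_met) & is.na(best_non)
  missing_side <- ifelse(no_hit, "both",
                         ifelse(is.na(best_met), "metazoan",
                                ifelse(is.na(best_non), "nonmetazoan", "none")))
  met <- ifelse(is.na(best_met), missing_bitscore, best_met)
  non <- ifelse(is.na(best_non), missing_bitscore, best_non)
  h_u <- ifelse(no_hit, NA_real_, non - met)
  status <- ifelse(no_hit, "excluded_no_hit",
                   ifelse(h_u >= hu_min, "foreign", "native"))
  calls <- data.frame(
    transcript_id = transcript_ids,
    best_metazoan_bitscore = ifelse(no_hit, NA_real_, met),
    best_nonmetazoan_bitscore = ifelse(no_hit, NA_real_, non),
    h_u = h_u,
    status = status,
    donor_kingdom = "none",
    missing_side = missing_side,
    stringsAsFactors = FALSE
  )
  foreign <- calls$transcript_id[calls$status == "foreign"]
  if (length(foreign) > 0L) {
    calls$donor_kingdom[calls$status == "foreign"] <-
      donor_kingdoms(foreign, kept)
  }
  calls
}

#' Assign the donor kingdom of a foreign transcript
#'
#' The kingdom of the non-metazoan partition holding the retained hit with
#' the minimum e-value; ties are broken by higher bitscore, then by
#' lexicographic partition name, so output is deterministic. The
#' `other_eukaryotes` partition is reported as `protists`.
#'
#' @param call a single-row calls `data.frame` with `status == "foreign"`.
#' @param hits retained hit `data.frame` (already e-value filtered).
#' @return donor kingdom label.
#' @export
assign_donor_kingdom <- function(call, hits) {
  if (call$status != "foreign") stop("donor kingdom is defined only for foreign calls")
  donor_kingdoms(call$transcript_id, hits)
}

donor_kingdoms <- function(ids, kept_hits) {
  h <- kept_hits[kept_hits$partition %in% NONMETAZOAN_PARTITIONS &
                   kept_hits$query_id %in% ids, , drop = FALSE]
  ord <- order(h$query_id, h$evalue, -h$bitscore, h$partition)
  h <- h[ord, , drop = FALSE]
  best <- h[!duplicated(h$query_id), , drop = FALSE]
  king <- best$partition[match(ids, best$query_id)]
  king[king == "other_eukaryotes"] <- "protists"
  king[is.na(king)] <- "none"
  king
}

#' Full HGT calling for one species
#'
#' Applies the retention filters, scores retained transcripts with
#' [compute_hu()], and returns one row per input transcript with filter
#' exclusions folded into `status`.
#'
#' @param transcripts transcript `data.frame` for one species.
#' @param hits protein-partition hit `data.frame` for the same transcripts.
#' @param config configuration list (see [default_config()]); the `hgt`
#'   entry supplies all thresholds.
#' @return calls `data.frame` with `transcript_id`, `species`, `length_bp`,
#'   bitscore columns, `h_u`, `status`, `donor_kingdom`.
#' @export
call_hgt <- function(transcripts, hits, config = default_config()) {
  cf <- config$hgt
  flt <- filter_transcripts(transcripts, cf$fpkm_min, cf$isopct_min, cf$len_min)
  calls <- compute_hu(hits, transcript_ids = flt$retained$id,
                      evalue_max = cf$evalue_max, hu_min = cf$hu_min,
                      missing_bitscore = cf$missing_bitscore)
  if (nrow(flt$excluded) > 0L) {
    exc <- data.frame(
      transcript_id = flt$excluded$id,
      best_metazoan_bitscore = NA_real_,
      best_nonmetazoan_bitscore = NA_real_,
      h_u = NA_real_, status = flt$excluded$reason,
      donor_kingdom = "none", missing_side = NA_character_,
      stringsAsFactors = FALSE
    )
    calls <- rbind(calls, exc)
  }
  calls <- calls[match(transcripts$id, calls$transcript_id), , drop = FALSE]
  calls$species <- transcripts$species
  calls$length_bp <- transcripts$length_bp
  rownames(calls) <- NULL
  calls[, c("transcript_id", "species", "length_bp",
            "best_metazoan_bitscore", "best_nonmetazoan_bitscore",
            "h_u", "status", "donor_kingdom", "missing_side")]
}

#' Sensitivity sweep over detection thresholds
#'
#' Re-applies the full filtering and h_U classification over a grid of
#' e-value, minimum-length and h_U thresholds, reporting the foreign
#' proportion per species and parameter combination. The degenerate grid
#' `{1e-05} x {200} x {30}` reproduces the default analysis.
#'
#' @param transcripts transcript `data.frame`, possibly multiple species.
#' @param hits protein-partition hit `data.frame` for all transcripts.
#' @param evalue_grid,length_grid,hu_grid numeric vectors of thresholds.
#' @param config base configuration; expression filters are taken from it.
#' @return `data.frame` with one row per (species, evalue_max, len_min,
#'   hu_min): `n_retained`, `n_foreign`, `proportion`.
#' @export
sensitivity_sweep <- function(transcripts, hits, evalue_grid = 1e-05,
                              length_grid = 200L, hu_grid = 30,
                              config = default_config()) {
  grid <- expand.grid(evalue_max = evalue_grid, len_min = length_grid,
                      hu_min = hu_grid, KEEP.OUT.ATTRS = FALSE)
  out <- list()
  for (sp in unique(transcripts$species)) {
    tr <- transcripts[transcripts$species == sp, , drop = FALSE]
    for (i in seq_len(nrow(grid))) {
      cf <- config
      cf$hgt$evalue_max <- grid$evalue_max[i]
      cf$hgt$len_min <- grid$len_min[i]
      cf$hgt$hu_min <- grid$hu_min[i]
      calls <- call_hgt(tr, hits, cf)
      n_ret <- sum(calls$status %in% c("foreign", "native"))
      n_for <- sum(calls$status == "foreign")
      out[[length(out) + 1L]] <- data.frame(
        species = sp, evalue_max = grid$evalue_max[i],
        len_min = grid$len_min[i], hu_min = grid$hu_min[i],
        n_retained = n_ret, n_foreign = n_for,
        proportion = if (n_ret > 0L) n_for / n_ret else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(species = character(0), evalue_max = numeric(0),
                      len_min = numeric(0), hu_min = numeric(0),
                      n_retained = integer(0), n_foreign = integer(0),
                      proportion = numeric(0)))
  }
  do.call(rbind, out)
}
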