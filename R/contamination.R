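#' Flag putative contaminant transcripts among foreign calls
#'
#' Only foreign calls are screened. A foreign transcript with any
#' nucleotide-database (`nt`) hit at e-value <= `nt_evalue_max` becomes a
#' contamination candidate; a candidate with any hit against the outgroup
#' transcriptome at e-value <= `rescue_evalue_max` is rescued (a sequence
#' shared with the distant outgroup cannot plausibly be a recent
#' contaminant), otherwise its status becomes `contaminant` and it is
#' excluded from all downstream counts. Native and excluded transcripts are
#' never touched, and with an empty `nt` table the call set is unchanged.
#'
#' @param calls calls `data.frame` from [call_hgt()] (any species mix).
#' @param nt_hits hit `data.frame` from BLASTN against the nucleotide
#'   database (`partition = "nt"`).
#' @param outgroup_hits hit `data.frame` against the outgroup transcriptome
#'   (`partition = "outgroup"`).
#' @param nt_evalue_max flagging threshold.
#' @param rescue_evalue_max rescue threshold.
#' @return list with `calls` (updated statuses) and `report`: one row per
#'   candidate with `transcript_id`, `best_nt_subject`, `best_nt_evalue`,
#'   `best_rescue_evalue`, `decision` (`rescued`/`removed`).
#' @export
flag_contaminants <- function(calls, nt_hits, outgroup_hits,
                              nt_evalue_max = 1e-05,
                              rescue_evalue_max = 1e-10) {
  foreign_ids <- calls$transcript_id[calls$status == "foreign"]
  unknown <- setdiff(unique(nt_hits$query_id), calls$transcript_id)
  if (length(unknown) > 0L) {
    warning("nt hits reference ", length(unknown),
            " transcript(s) absent from the call set; ignored")
  }
  nt <- nt_hits[nt_hits$query_id %in% foreign_ids &
                  nt_hits$evalue <= nt_evalue_max, , drop = FALSE]
  candidates <- unique(nt$query_id)
  if (length(candidates) == 0L) {
    return(list(calls = calls, report = data.frame(
      transcript_id = character(0), best_nt_subject = character(0),
      best_nt_evalue = numeric(0), best_rescue_evalue = numeric(0),
      decision = character(0), stringsAsFactors = FALSE
    )))
  }
  nt <- nt[order(nt$query_id, nt$evalue, -nt$bitscore), , drop = FALSE]
  best_nt <- nt[!duplicated(nt$query_id), , drop = FALSE]
  og <- outgroup_hits[outgroup_hits$query_id %in% candidates, , drop = FALSE]
  best_rescue <- rep(NA_real_, length(candidates))
  if (nrow(og) > 0L) {
    agg <- tapply(og$evalue, og$query_id, min)
    best_rescue[match(names(agg), candidates)] <- as.numeric(agg)
  }
  rescued <- !is.na(best_rescue) & best_rescue <= rescue_evalue_max
  report <- data.frame(
    transcript_id = candidates,
    best_nt_subject = best_nt$subject_id[match(candidates, best_nt$query_id)],
    best_nt_evalue = best_nt$evalue[match(candidates, best_nt$query_id)],
    best_rescue_evalue = best_rescue,
    decision = ifelse(rescued, "rescued", "removed"),
    stringsAsFactors = FALSE
  )
  removed <- candidates[!rescued]
  calls$status[calls$transcript_id %in% removed] <- "contaminant"
  list(calls = calls, report = report)
}
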