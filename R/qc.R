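#' Top-ten replicate detections underlying the MTQ/MAQ scores
#'
#' Both quality scores count positive PCR-replicate detections across the
#' ten most read-abundant sequences of a sample, out of a possible
#' 10 x n_replicates detections (80 with the standard eight replicates).
#' Ties at rank ten are broken by lexicographic `sequence_id` so the score
#' is deterministic and row-order invariant. Samples with fewer than ten
#' sequences keep the full denominator: the missing slots contribute zero
#' detections.
#'
#' @param records record table rows belonging to one sample.
#' @param n_replicates number of PCR replicates amplified (default 8).
#' @return list with `score` and `n_detections`.
#' @keywords internal
top10_detections <- function(records, n_replicates = 8) {
  if (nrow(records) == 0L)
    return(list(score = 0, n_detections = 0L))
  m <- rep_matrix(records)
  tot <- rowSums(m)
  ord <- order(-tot, records$sequence_id)
  top <- head(ord, 10L)
  det <- sum(m[top, , drop = FALSE] > 0)
  list(score = det / (10 * n_replicates), n_detections = det)
}

#' Metabarcoding technical quality (MTQ) score
#'
#' Proportion of positive replicate detections among the sample's ten most
#' read-abundant sequences *before any taxonomic identification* (but after
#' the per-replicate low-count filter). Low MTQ indicates that even the most
#' abundant amplicons replicate only sporadically, as in negative controls,
#' extracts with ultralow template, or inhibited reactions.
#'
#' @param records post-per-replicate-filter record rows of one sample
#'   (identified or not).
#' @param n_replicates number of PCR replicates (default 8).
#' @return list with `mtq` and `n_detections_mtq`.
#' @export
#' @examples
#' # ten sequences each detected in all eight replicates -> mtq = 1
mtq_score <- function(records, n_replicates = 8) {
  r <- top10_detections(records, n_replicates)
  list(mtq = r$score, n_detections_mtq = r$n_detections)
}

#' Metabarcoding analytical quality (MAQ) score
#'
#' As [mtq_score()], but computed over the ten most read-abundant sequences
#' that are taxonomically identified and not blacklisted. Divergence between
#' MTQ and MAQ flags coamplification of unidentified and/or contaminant
#' sequences.
#'
#' @param records identified, blacklist-cleaned record rows of one sample.
#' @param n_replicates number of PCR replicates (default 8).
#' @return list with `maq` and `n_detections_maq`.
#' @export
maq_score <- function(records, n_replicates = 8) {
  r <- top10_detections(records, n_replicates)
  list(maq = r$score, n_detections_maq = r$n_detections)
}

#' Quality-gate samples on MTQ and MAQ thresholds
#'
#' A sample passes quality control iff both scores meet their thresholds
#' (inclusive): MTQ >= 0.75 (at least 60 of 80 detections) and MAQ >= 0.2
#' (at least 16 detections) at the defaults. Failed samples are excluded
#' from all downstream diversity analyses but kept in QC reports.
#'
#' @param qc data.frame with columns `mtq` and `maq` (one row per sample).
#' @param mtq_threshold,maq_threshold inclusive score thresholds.
#' @return `qc` with a logical `passed` column added.
#' @export
gate_samples <- function(qc, mtq_threshold = 0.75, maq_threshold = 0.2) {
  stopifnot(all(c("mtq", "maq") %in% names(qc)))
  qc$passed <- qc$mtq >= mtq_threshold & qc$maq >= maq_threshold
  qc
}

#' Choose among repeated DNA extractions of one sample
#'
#' When a sample was extracted more than once, the extract with the highest
#' MAQ score is retained; exact ties go to the lowest extract number
#' (extract 1 first).
#'
#' @param qc data.frame of the sample's extracts with columns `extract`
#'   and `maq`.
#' @return the chosen row.
#' @export
select_extraction_replicate <- function(qc) {
  stopifnot(nrow(qc) >= 1, all(c("extract", "maq") %in% names(qc)))
  qc[order(-qc$maq, qc$extract), , drop = FALSE][1, , drop = FALSE]
}

#' Per-sample quality diagnostics
#'
#' Three of the per-sample data-quality measures reported alongside the
#' scores: total raw reads summed across replicates, mean retained-barcode
#' length, and the proportion of raw reads assigned to terrestrial plant
#' taxa.
#'
#' @param raw raw (pre-filter) record rows of one sample; used for read
#'   totals.
#' @param retained harmonization output rows for the sample with `group`
#'   labels (identified, cleaned records); used for barcode lengths and the
#'   terrestrial read proportion.
#' @param weighted if `TRUE`, mean barcode length is weighted by reads;
#'   default is the unweighted mean over distinct retained barcodes.
#' @return list with `total_raw_reads`, `mean_barcode_length`,
#'   `prop_terrestrial_reads` (`NA` where undefined).
#' @export
quality_diagnostics <- function(raw, retained, weighted = FALSE) {
  total <- if (nrow(raw)) sum(rep_matrix(raw)) else 0
  mean_len <- NA_real_
  prop_terr <- NA_real_
  if (nrow(retained)) {
    dnas <- retained$dna[!duplicated(retained$dna)]
    if (weighted) {
      w <- rowsum(rowSums(rep_matrix(retained)), retained$dna)[dnas, 1]
      mean_len <- sum(nchar(dnas) * w) / sum(w)
    } else {
      mean_len <- mean(nchar(dnas))
    }
    if (total > 0 && "group" %in% names(retained)) {
      terr <- retained$group == "terrestrial"
      prop_terr <- sum(rep_matrix(retained)[terr, , drop = FALSE]) / total
    }
  }
  list(total_raw_reads = total, mean_barcode_length = mean_len,
       prop_terrestrial_reads = prop_terr)
}

#' Build the per-sample QC report
#'
#' Computes MTQ (on post-per-replicate-filter sequences), MAQ (on
#' identified, blacklist-cleaned sequences), quality diagnostics, the gate
#' decision, and -- where a sample has several extracts -- which extract is
#' retained.
#'
#' @param harmonized output of [harmonize()].
#' @param raw the raw record table the harmonization started from.
#' @param n_replicates number of PCR replicates.
#' @param mtq_threshold,maq_threshold gate thresholds, see [gate_samples()].
#' @return data.frame with one row per (sample, extract) and columns
#'   `lake_id`, `sample_id`, `extract`, `sample_type`, `mtq`,
#'   `n_detections_mtq`, `maq`, `n_detections_maq`, `total_raw_reads`,
#'   `mean_barcode_length`, `prop_terrestrial_reads`, `passed`,
#'   `selected_extract` (TRUE for the extract retained for analysis).
#' @export
sample_qc <- function(harmonized, raw, n_replicates = 8,
                      mtq_threshold = 0.75, maq_threshold = 0.2) {
  pre <- harmonized$prefiltered
  cln <- harmonized$cleaned
  if (!"extract" %in% names(raw)) raw$extract <- 1L
  if (!"extract" %in% names(pre)) pre$extract <- 1L
  if (!"extract" %in% names(cln)) cln$extract <- 1L
  key <- function(d) paste(d$sample_id, d$extract, sep = "\r")
  units <- raw[!duplicated(key(raw)),
               intersect(c("lake_id", "sample_id", "extract", "sample_type"),
                         names(raw)), drop = FALSE]
  rownames(units) <- NULL
  pre_k <- key(pre); cln_k <- key(cln); raw_k <- key(raw)
  rows <- lapply(seq_len(nrow(units)), function(i) {
    k <- paste(units$sample_id[i], units$extract[i], sep = "\r")
    p <- pre[pre_k == k, , drop = FALSE]
    cl <- cln[cln_k == k, , drop = FALSE]
    mt <- mtq_score(p, n_replicates)
    ma <- maq_score(cl, n_replicates)
    dg <- quality_diagnostics(raw[raw_k == k, , drop = FALSE], cl)
    cbind(units[i, , drop = FALSE],
          data.frame(mtq = mt$mtq, n_detections_mtq = mt$n_detections_mtq,
                     maq = ma$maq, n_detections_maq = ma$n_detections_maq,
                     dg, stringsAsFactors = FALSE))
  })
  qc <- do.call(rbind, rows)
  qc <- gate_samples(qc, mtq_threshold, maq_threshold)
  qc$selected_extract <- FALSE
  for (s in unique(qc$sample_id)) {
    sub <- qc[qc$sample_id == s, , drop = FALSE]
    chosen <- select_extraction_replicate(sub)$extract
    qc$selected_extract[qc$sample_id == s & qc$extract == chosen] <- TRUE
  }
  rownames(qc) <- NULL
  qc
}
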