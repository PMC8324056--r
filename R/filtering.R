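#' Sequence record tables
#'
#' Most filtering functions operate on a "record table": a data.frame with
#' one row per (sample, dereplicated sequence) and columns
#' `lake_id`, `sample_id`, `sample_type` (`"sample"` or `"neg_control"`),
#' `sequence_id`, `dna`, and per-replicate retained-read counts in columns
#' `rep1` ... `repN`. An optional `extract` column distinguishes repeated
#' DNA extractions of the same sample.
#'
#' @param records a record table.
#' @return `n_replicates()` returns the number of `rep*` columns.
#' @keywords internal
#' @noRd
n_replicates <- function(records) {
  sum(grepl("^rep[0-9]+$", names(records)))
}

rep_matrix <- function(records) {
  nr <- n_replicates(records)
  if (nr == 0L) stop_sedadiv("record table has no rep* count columns")
  as.matrix(records[, rep_cols(nr), drop = FALSE])
}

check_records <- function(records) {
  need <- c("sample_id", "sequence_id", "dna")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_sedadiv("record table lacks columns: ", paste(miss, collapse = ", "))
  m <- rep_matrix(records)
  if (any(m < 0) || any(m != floor(m)))
    stop_sedadiv("replicate counts must be non-negative integers")
  invisible(records)
}

#' Remove weakly supported counts within each PCR replicate
#'
#' Sets every (sequence, replicate) cell with fewer than `min_reads` reads to
#' zero and drops sequences whose counts become all-zero. With the default
#' `min_reads = 3` this removes cells supported by two reads or fewer, the
#' standard guard against index swaps and PCR/sequencing artifacts.
#'
#' @param records a record table (see package overview).
#' @param min_reads minimum reads for a cell to survive (default 3, i.e.
#'   cells with <= 2 reads are zeroed).
#' @return the filtered record table.
#' @export
#' @examples
#' rec <- data.frame(lake_id = "L1", sample_id = "s1", sample_type = "sample",
#'                   sequence_id = "q1", dna = "ACGT",
#'                   rep1 = 2, rep2 = 3, rep3 = 0, rep4 = 5)
#' filter_per_replicate_low_count(rec)$rep1  # 2 reads -> zeroed
filter_per_replicate_low_count <- function(records, min_reads = 3) {
  check_records(records)
  if (min_reads < 1) stop_sedadiv("min_reads must be >= 1")
  m <- rep_matrix(records)
  m[m < min_reads] <- 0L
  records[, rep_cols(ncol(m))] <- m
  records[rowSums(m) > 0, , drop = FALSE]
}

#' Assign taxonomy by exact sequence identity
#'
#' A record is identified if and only if its `dna` string is byte-identical
#' to a barcode in the reference database (100% identity, full length).
#' Unidentified records are kept separately: they still enter the MTQ score
#' and read-proportion diagnostics.
#'
#' Sequences belonging to the reference database's *Vaccinium*-type poly-A
#' group are resolved to species or genus from the length of their 3'
#' poly-A run via [resolve_vaccinium()].
#'
#' @param records a record table.
#' @param refdb a reference database from [read_reference()] or
#'   [generate_reference_db()].
#' @return a list with elements `identified` (record table gaining columns
#'   `taxon`, `rank`, `group`) and `unidentified`.
#' @export
assign_taxonomy_exact <- function(records, refdb) {
  check_records(records)
  if (nrow(refdb$taxonomy) == 0L) stop_sedadiv("reference database is empty")
  tax <- refdb$taxonomy
  idx <- match(records$dna, tax$barcode)
  hit <- !is.na(idx)
  identified <- records[hit, , drop = FALSE]
  if (nrow(identified)) {
    identified$taxon <- tax$taxon[idx[hit]]
    identified$rank  <- tax$rank[idx[hit]]
    identified$group <- tax$group[idx[hit]]
    pa <- tax$polyA_group[idx[hit]]
    if (any(pa)) {
      res <- vapply(identified$dna[pa], resolve_vaccinium, character(1))
      identified$taxon[pa] <- res
      identified$rank[pa] <- ifelse(res == "Vaccinium", "genus", "species")
    }
  } else {
    identified$taxon <- character(0)
    identified$rank <- character(0)
    identified$group <- character(0)
  }
  list(identified = identified, unidentified = records[!hit, , drop = FALSE])
}

#' Resolve a Vaccinium-type barcode from its 3' poly-A run
#'
#' The trnL p6-loop barcodes of *Vaccinium myrtillus* and *V. vitis-idaea*
#' differ only in the length of a homopolymer A run at the 3' end. A run of
#' 5 or fewer A's is assigned to *V. myrtillus*, more than 8 A's to
#' *V. vitis-idaea*, and the intermediate lengths (6-8) only to genus level.
#' A sequence with no terminal A counts as run length 0.
#'
#' @param dna a single DNA string assigned to the poly-A group.
#' @return one of `"Vaccinium myrtillus"`, `"Vaccinium vitis-idaea"`,
#'   `"Vaccinium"`.
#' @export
#' @examples
#' resolve_vaccinium("ACGTAAAAA")    # run of 5 -> V. myrtillus
#' resolve_vaccinium("ACGTAAAAAAAAA") # run of 9 -> V. vitis-idaea
resolve_vaccinium <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  run <- attr(regexpr("A*$", dna), "match.length")
  if (run <= 5) "Vaccinium myrtillus"
  else if (run > 8) "Vaccinium vitis-idaea"
  else "Vaccinium"
}

#' Remove blacklisted sequences
#'
#' Drops records whose `dna` exactly matches an entry of either blacklist
#' (synthetic positive-control sequences, or curated false positives such as
#' homopolymer variants of read-dominant sequences and food contaminants).
#' A blacklisted sequence is removed even if it also occurs in the reference
#' database: the blacklist wins.
#'
#' @inheritParams assign_taxonomy_exact
#' @return the cleaned record table.
#' @export
apply_blacklists <- function(records, refdb) {
  check_records(records)
  bad <- c(refdb$blacklist_synthetic, refdb$blacklist_false_positive)
  records[!(records$dna %in% bad), , drop = FALSE]
}

#' Dataset-wide rarity filter
#'
#' Aggregates each sequence across the *entire* dataset (all samples, all
#' lakes) and retains it only if it reaches both `min_total_reads` total
#' reads and `min_total_replicates` positive replicate cells. Sequences
#' failing either condition are removed everywhere.
#'
#' @param records a record table covering the whole dataset.
#' @param min_total_reads minimum summed reads dataset-wide (default 10).
#' @param min_total_replicates minimum positive (sequence, sample, replicate)
#'   cells dataset-wide (default 3).
#' @param scope `"dataset"` (default) applies the filter at whole-dataset
#'   scope; `"lake"` applies it within each lake separately (sensitivity
#'   analysis; drops low-frequency sequences only rescued by pooling lakes).
#' @return the filtered record table.
#' @export
filter_dataset_wide <- function(records, min_total_reads = 10,
                                min_total_replicates = 3,
                                scope = c("dataset", "lake")) {
  check_records(records)
  scope <- match.arg(scope)
  m <- rep_matrix(records)
  key <- if (scope == "dataset") records$dna
         else paste(records$lake_id, records$dna, sep = "\r")
  tot_reads <- rowsum(rowSums(m), key)
  tot_cells <- rowsum(rowSums(m > 0), key)
  ok <- rownames(tot_reads)[tot_reads[, 1] >= min_total_reads &
                            tot_cells[, 1] >= min_total_replicates]
  records[key %in% ok, , drop = FALSE]
}

#' Merge co-occurring barcodes assigned to the same taxon
#'
#' Within each sample, barcodes carrying the same taxon name are assumed to
#' represent the same taxon wherever they co-occur, and are merged: reads are
#' summed and the per-replicate detection pattern is the union of the inputs
#' (so the merged replicate count is at least the maximum of the inputs).
#' Same-name barcodes that never co-occur in any sample are kept as separate
#' taxa and disambiguated with sequential numeric suffixes (e.g. Asteraceae1,
#' Asteraceae2).
#'
#' Co-occurrence is resolved globally by connected components: if barcodes a
#' and b co-occur somewhere and b and c co-occur elsewhere, all three merge
#' into one taxon.
#'
#' @param identified an identified record table (with `taxon` column).
#' @return a taxon table: one row per (sample, taxon) with columns `lake_id`,
#'   `sample_id`, `sample_type`, `taxon`, `rank`, `group`, `reads`,
#'   `n_detections`, and detection flags `det1` ... `detN`.
#' @export
merge_cooccurring_barcodes <- function(identified) {
  check_records(identified)
  if (!"taxon" %in% names(identified))
    stop_sedadiv("records must carry taxonomy; run assign_taxonomy_exact() first")
  nr <- n_replicates(identified)
  m <- rep_matrix(identified)
  # extraction replicates of one sample are distinct observation units
  unit <- if ("extract" %in% names(identified))
    paste(identified$sample_id, identified$extract, sep = "\r")
  else identified$sample_id

  # group barcodes of one taxon name into co-occurrence components
  identified$.component <- NA_character_
  for (tx in unique(identified$taxon)) {
    rows <- which(identified$taxon == tx)
    bars <- unique(identified$dna[rows])
    comp <- stats::setNames(seq_along(bars), bars)  # union-find over barcodes
    find <- function(i) { while (comp[[i]] != i) i <- comp[[i]]; i }
    for (s in unique(unit[rows])) {
      here <- unique(identified$dna[rows][unit[rows] == s])
      if (length(here) > 1) {
        r1 <- find(match(here[1], bars))
        for (b in here[-1]) {
          r2 <- find(match(b, bars))
          if (r1 != r2) comp[r2] <- r1
        }
      }
    }
    roots <- vapply(seq_along(bars), find, integer(1))
    comp_id <- match(roots, sort(unique(roots)))
    suffix <- if (length(unique(comp_id)) > 1) comp_id
              else rep("", length(bars))
    lab <- paste0(tx, suffix)
    identified$.component[rows] <- lab[match(identified$dna[rows], bars)]
  }

  key <- paste(unit, identified$.component, sep = "\r")
  first <- !duplicated(key)
  out <- identified[first, c("lake_id", "sample_id",
                             intersect(c("extract", "sample_type"),
                                       names(identified)),
                             "rank", "group")]
  out$taxon <- identified$.component[first]
  out$reads <- as.vector(rowsum(rowSums(m), key)[unique(key), 1])
  det <- rowsum((m > 0) + 0L, key)[unique(key), , drop = FALSE] > 0
  colnames(det) <- paste0("det", seq_len(nr))
  out$n_detections <- rowSums(det)
  out <- cbind(out, det)
  rownames(out) <- NULL
  out[order(out$sample_id, out$taxon), , drop = FALSE]
}

#' Keep only target taxa
#'
#' Restricts a taxon table to terrestrial vascular plants and bryophytes
#' identified at family level or below: rows with rank `above-family` and
#' rows whose ecological group is aquatic (including wetland plants) or
#' algal are excluded.
#'
#' @param table a taxon table from [merge_cooccurring_barcodes()].
#' @return the restricted taxon table.
#' @export
exclude_nontarget <- function(table) {
  stopifnot(all(c("rank", "group") %in% names(table)))
  keep <- table$rank %in% c("species", "genus", "family") &
          table$group == "terrestrial"
  table[keep, , drop = FALSE]
}

#' Full sequence-to-taxon harmonization chain
#'
#' Applies the pinned filtering order: per-replicate low-count filter,
#' exact-match taxonomy, blacklist removal, dataset-wide rarity filter,
#' merging of co-occurring same-taxon barcodes, and exclusion of aquatic /
#' above-family taxa. Intermediate stages are returned because the QC scores
#' are defined on them (MTQ on the post-per-replicate-filter records, MAQ on
#' the identified, blacklist-cleaned records).
#'
#' @param records raw record table.
#' @param refdb reference database.
#' @param min_reads,min_total_reads,min_total_replicates,scope thresholds,
#'   see the individual filter functions.
#' @return list with `prefiltered`, `identified`, `unidentified`, `cleaned`
#'   (identified minus blacklists), `retained` (after dataset-wide filter),
#'   and `taxa` (final harmonized taxon table).
#' @export
harmonize <- function(records, refdb, min_reads = 3, min_total_reads = 10,
                      min_total_replicates = 3, scope = "dataset") {
  pre <- filter_per_replicate_low_count(records, min_reads)
  parts <- assign_taxonomy_exact(pre, refdb)
  cleaned <- apply_blacklists(parts$identified, refdb)
  retained <- filter_dataset_wide(cleaned, min_total_reads,
                                  min_total_replicates, scope = scope)
  taxa <- if (nrow(retained)) exclude_nontarget(merge_cooccurring_barcodes(retained))
          else NULL
  list(prefiltered = pre, identified = parts$identified,
       unidentified = parts$unidentified, cleaned = cleaned,
       retained = retained, taxa = taxa)
}
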