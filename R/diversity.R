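#' Read-depth-weighted taxon detectability (wtRep)
#'
#' PCR replicates differ widely in retained read totals, and read-rare taxa
#' drop out preferentially from shallow replicates. wtRep weights each
#' replicate by its share of the sample's retained reads: the detectability
#' of a taxon is the summed read total of the replicates in which it was
#' detected, divided by the grand total across all replicates. Replicates
#' with zero retained reads contribute to neither numerator nor denominator.
#'
#' @param detected logical vector: was the taxon detected in each replicate?
#' @param replicate_totals per-replicate total retained reads of the sample
#'   (all sequences summed), same length as `detected`.
#' @return wtRep value in (0, 1].
#' @export
#' @examples
#' wt_rep(c(TRUE, FALSE, TRUE, rep(FALSE, 5)),
#'        c(100, 0, 300, 0, 0, 0, 0, 0))  # = 400/400 = 1
wt_rep <- function(detected, replicate_totals) {
  stopifnot(length(detected) == length(replicate_totals),
            is.logical(detected))
  grand <- sum(replicate_totals)
  if (grand <= 0) stop_sedadiv("all replicate totals are zero; wtRep undefined")
  if (!any(detected & replicate_totals > 0))
    stop_sedadiv("taxon detected in no replicate with retained reads")
  sum(replicate_totals[detected]) / grand
}

#' Per-sample taxon detectability row
#'
#' Computes a detectability value per taxon for one sample. wtRep
#' overrepresents detections when a sample holds few barcodes or sparse
#' detections, so it is only applied when the sample is well supported: the
#' mean (over taxa) proportion of positive replicates must reach
#' `min_mean_prop` and the sample must hold at least `min_barcodes` taxa.
#' Otherwise the plain proportion of positive replicates is used (e.g. 2 of
#' 8 replicates gives 0.25).
#'
#' @param sample_taxa taxon-table rows of one sample (detection flags
#'   `det1..detN` and `reads`).
#' @param replicate_totals per-replicate retained-read totals for the sample.
#' @param min_mean_prop,min_barcodes applicability rule for wtRep
#'   (defaults 0.33 and 10).
#' @param n_replicates number of PCR replicates.
#' @return data.frame with columns `taxon`, `value`, and attribute `mode`
#'   (`"weighted"` or `"plain"`).
#' @export
detectability_matrix <- function(sample_taxa, replicate_totals,
                                 min_mean_prop = 0.33, min_barcodes = 10,
                                 n_replicates = 8) {
  det <- as.matrix(sample_taxa[, paste0("det", seq_len(n_replicates)),
                               drop = FALSE])
  mode(det) <- "logical"
  mean_prop <- mean(rowSums(det) / n_replicates)
  use_wtrep <- nrow(sample_taxa) >= min_barcodes && mean_prop >= min_mean_prop
  value <- if (use_wtrep) {
    apply(det, 1, wt_rep, replicate_totals = replicate_totals)
  } else {
    rowSums(det) / n_replicates
  }
  out <- data.frame(taxon = sample_taxa$taxon, value = value,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "mode") <- if (use_wtrep) "weighted" else "plain"
  out
}

#' Hill numbers N0 and N1
#'
#' N0 is taxonomic richness (the count of taxa present). N1, the exponent
#' of the Shannon entropy, is the effective number of common taxa:
#' `exp(-sum p_i log p_i)` with `p_i` the taxon's share of the sample's
#' summed detectability values. `1 <= N1 <= N0`, with equality at N0 when
#' all taxa are equally detectable. N1 is invariant to rescaling all values
#' by a constant.
#'
#' @param values positive detectability (or abundance) values of the taxa
#'   present in one sample.
#' @return `hill_n0()`: integer count; `hill_n1()`: numeric (NA for an
#'   empty sample).
#' @export
hill_n0 <- function(values) sum(values > 0)

#' @rdname hill_n0
#' @export
hill_n1 <- function(values) {
  values <- values[values > 0]
  if (!length(values)) return(NA_real_)
  p <- values / sum(values)
  exp(-sum(p * log(p)))
}

#' Expected rarefied richness
#'
#' Expected number of distinct taxa in a hypergeometric subsample of
#' `depth` reads from the sample's taxon read counts (the analytic
#' rarefaction of Hurlbert, via [vegan::rarefy()]). A Monte-Carlo mode
#' draws `n_resamples` subsamples without replacement instead and needs a
#' seed; it exists as a cross-check of the closed form.
#'
#' @param counts named integer vector of reads per taxon.
#' @param depth subsample size; conventionally the lowest read total of any
#'   sample within the lake.
#' @param method `"analytic"` (default) or `"montecarlo"`.
#' @param n_resamples,seed Monte-Carlo controls.
#' @return expected distinct-taxon count at `depth`.
#' @export
rarefied_richness <- function(counts, depth, method = c("analytic", "montecarlo"),
                              n_resamples = 1000, seed = NULL) {
  method <- match.arg(method)
  counts <- counts[counts > 0]
  if (depth <= 0 || !length(counts)) return(0)
  if (depth > sum(counts))
    stop_sedadiv("rarefaction depth exceeds the sample's total reads")
  if (method == "analytic")  # rarefy warns when the rarest taxon has > 1 read
    return(as.numeric(suppressWarnings(vegan::rarefy(matrix(counts, nrow = 1),
                                                     depth))))
  if (is.null(seed)) stop_sedadiv("Monte-Carlo rarefaction requires a seed")
  pool <- rep(seq_along(counts), counts)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mean(vapply(seq_len(n_resamples), function(i) {
    length(unique(sample(pool, depth)))
  }, numeric(1)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Correlation between rarefied and observed richness
#'
#' Pearson product-moment correlation across a lake's samples between
#' rarefied richness (at the lake's minimum read depth) and taxonomic
#' richness (Hill N0). Values near 1 indicate that differences in
#' sequencing depth do not drive the observed richness pattern.
#'
#' @param rarefied,n0 numeric vectors over the lake's samples.
#' @return Pearson r, or NA if fewer than 3 samples or zero variance.
#' @export
correlate_rarefied <- function(rarefied, n0) {
  stopifnot(length(rarefied) == length(n0))
  if (length(n0) < 3 || sd(rarefied) == 0 || sd(n0) == 0) return(NA_real_)
  cor(rarefied, n0)
}

#' Accumulated richness along a time-ordered sample series
#'
#' Cumulative count of distinct taxa from the oldest to the youngest
#' sample. The curve is non-decreasing and ends at the total number of
#' distinct taxa observed.
#'
#' @param sample_ids ordered (oldest to youngest) sample identifiers.
#' @param taxa_by_sample list mapping sample id to its character vector of
#'   taxa.
#' @return data.frame with columns `sample_id` and `accumulated`.
#' @export
accumulated_richness <- function(sample_ids, taxa_by_sample) {
  seen <- character(0)
  acc <- integer(length(sample_ids))
  for (i in seq_along(sample_ids)) {
    seen <- union(seen, taxa_by_sample[[sample_ids[i]]])
    acc[i] <- length(seen)
  }
  data.frame(sample_id = sample_ids, accumulated = acc,
             stringsAsFactors = FALSE)
}

#' Per-sample diversity table
#'
#' Applies the detectability rule and Hill numbers to every QC-passed
#' sample of a harmonized taxon table, plus analytic rarefied richness at
#' each lake's minimum read depth.
#'
#' @param taxa harmonized taxon table ([harmonize()] `$taxa`).
#' @param replicate_totals data.frame `sample_id`, `rep1..repN` of
#'   per-replicate retained-read totals per sample (post-filter, identified
#'   sequences), as produced by [replicate_read_totals()].
#' @param ages data.frame `sample_id`, `age` (cal yr BP).
#' @param min_mean_prop,min_barcodes,n_replicates see
#'   [detectability_matrix()].
#' @return data.frame: `lake_id`, `sample_id`, `age`, `n0`, `n1`,
#'   `rarefied`, `mode`, `mean_wtrep`.
#' @export
diversity_table <- function(taxa, replicate_totals, ages,
                            min_mean_prop = 0.33, min_barcodes = 10,
                            n_replicates = 8) {
  samples <- unique(taxa$sample_id)
  rt <- as.matrix(replicate_totals[, rep_cols(n_replicates), drop = FALSE])
  rownames(rt) <- replicate_totals$sample_id
  rows <- lapply(samples, function(s) {
    st <- taxa[taxa$sample_id == s, , drop = FALSE]
    dm <- detectability_matrix(st, rt[s, ], min_mean_prop, min_barcodes,
                               n_replicates)
    data.frame(lake_id = st$lake_id[1], sample_id = s,
               n0 = hill_n0(dm$value), n1 = hill_n1(dm$value),
               mode = attr(dm, "mode"), mean_wtrep = mean(dm$value),
               reads = sum(st$reads), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$age <- ages$age[match(out$sample_id, ages$sample_id)]
  # rarefy within lakes at the lake's minimum per-sample read total
  out$rarefied <- NA_real_
  for (lk in unique(out$lake_id)) {
    in_lake <- out$lake_id == lk
    depth <- min(out$reads[in_lake])
    for (s in out$sample_id[in_lake]) {
      st <- taxa[taxa$sample_id == s, , drop = FALSE]
      out$rarefied[out$sample_id == s] <-
        rarefied_richness(setNames(st$reads, st$taxon), depth)
    }
  }
  out[order(out$lake_id, -out$age), c("lake_id", "sample_id", "age", "n0",
                                      "n1", "rarefied", "mode",
                                      "mean_wtrep", "reads")]
}

#' Per-replicate retained-read totals per sample
#'
#' Sums retained reads over all sequences of each sample, per replicate;
#' this is the weighting basis of [wt_rep()].
#'
#' @param records an identified, cleaned record table.
#' @return data.frame `sample_id`, `rep1..repN`.
#' @export
replicate_read_totals <- function(records) {
  nr <- n_replicates(records)
  m <- rowsum(rep_matrix(records), records$sample_id)
  data.frame(sample_id = rownames(m), as.data.frame(m),
             stringsAsFactors = FALSE, row.names = NULL)
}
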