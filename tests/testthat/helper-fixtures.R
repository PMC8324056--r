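# Small deterministic builders used across the test files.

# A record table from a named list of per-replicate count vectors.
# counts: list(sequence_id = c(rep counts)); all sequences belong to one
# sample unless sample_id is a vector.
make_records <- function(counts, sample_id = "s1", lake_id = "L1",
                         sample_type = "sample", dna = NULL) {
  n <- length(counts)
  nrep <- length(counts[[1]])
  if (is.null(dna)) dna <- random_fixture_dna(n)
  m <- do.call(rbind, counts)
  colnames(m) <- paste0("rep", seq_len(nrep))
  data.frame(lake_id = rep_len(lake_id, n), sample_id = rep_len(sample_id, n),
             sample_type = rep_len(sample_type, n),
             sequence_id = names(counts) %||% sprintf("q%02d", seq_len(n)),
             dna = dna, m, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_fixture_dna <- function(n, len = 30) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Reference database with known structure: taxa T1..Tn, all terrestrial
# species unless overridden.
make_refdb <- function(barcodes, taxa = NULL, rank = "species",
                       group = "terrestrial", polyA = FALSE,
                       blacklist_synthetic = character(0),
                       blacklist_false_positive = character(0)) {
  n <- length(barcodes)
  list(taxonomy = data.frame(
         barcode = barcodes,
         taxon = taxa %||% sprintf("T%02d", seq_len(n)),
         rank = rep_len(rank, n), group = rep_len(group, n),
         polyA_group = rep_len(polyA, n), stringsAsFactors = FALSE),
       blacklist_synthetic = blacklist_synthetic,
       blacklist_false_positive = blacklist_false_positive)
}

# Random wide count table for oracle tests: n_seq sequences x n_rep reps.
random_count_table <- function(n_seq, n_rep = 8, lambda = 5,
                               sample_id = "s1") {
  counts <- lapply(seq_len(n_seq), function(i)
    rpois(n_rep, lambda) * rbinom(n_rep, 1, 0.6))
  names(counts) <- sprintf("q%03d", seq_len(n_seq))
  make_records(counts, sample_id = sample_id)
}

# Taxon-table row builder: detection flags + reads for one sample.
make_taxa <- function(det, reads = NULL, sample_id = "s1", lake_id = "L1",
                      taxon = NULL, rank = "species", group = "terrestrial") {
  n <- length(det)
  nrep <- length(det[[1]])
  dm <- do.call(rbind, lapply(det, as.logical))
  colnames(dm) <- paste0("det", seq_len(nrep))
  data.frame(lake_id = lake_id, sample_id = sample_id,
             taxon = taxon %||% sprintf("T%02d", seq_len(n)),
             rank = rep_len(rank, n), group = rep_len(group, n),
             reads = reads %||% rowSums(dm) * 10,
             n_detections = rowSums(dm), dm, stringsAsFactors = FALSE)
}

# Brute-force Beals oracle: literal triple loop over samples, taxa, taxa.
beals_oracle <- function(x) {
  x <- (as.matrix(x) > 0) + 0
  ns <- nrow(x); nt <- ncol(x)
  M <- matrix(0, nt, nt)
  for (j in seq_len(nt)) for (k in seq_len(nt))
    M[j, k] <- sum(x[, j] > 0 & x[, k] > 0)
  N <- diag(M)
  b <- matrix(0, ns, nt)
  for (i in seq_len(ns)) for (j in seq_len(nt)) {
    ks <- setdiff(which(x[i, ] > 0), j)
    if (!length(ks)) next
    b[i, j] <- mean(M[j, ks] / N[ks])
  }
  dimnames(b) <- dimnames(x)
  b
}

# A small simulated dataset shared by the heavier tests (built once).
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(
        n_lakes = 4, samples_per_lake = c(12, 18), pool_size = 150,
        colonization_rate_curve = data.frame(
          old = c(11700, 7000, 5000, 3300), young = c(7000, 5000, 3300, 0),
          rate = c(16, 4, 8, 2)),
        seed = 420)
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})
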