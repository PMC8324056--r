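test_that("per-replicate low-count filter zeroes weak cells and drops empty rows", {
  rec <- make_records(list(a = c(2, 3, 0, 5, 0, 0, 0, 0),
                           b = c(1, 2, 0, 0, 0, 0, 0, 0)))
  out <- filter_per_replicate_low_count(rec, min_reads = 3)
  expect_equal(nrow(out), 1L)                      # b is all below threshold
  expect_equal(unname(unlist(out[1, paste0("rep", 1:8)])),
               c(0, 3, 0, 5, 0, 0, 0, 0))
  # min_reads = 1 is the identity on non-negative counts
  set.seed(11)
  tab <- random_count_table(15)
  expect_equal(filter_per_replicate_low_count(tab, 1), tab)
})

test_that("per-replicate filter matches the elementwise brute-force oracle", {
  set.seed(21)
  for (rep in 1:5) {
    tab <- random_count_table(20)
    thr <- sample(2:6, 1)
    out <- filter_per_replicate_low_count(tab, thr)
    m <- as.matrix(tab[, paste0("rep", 1:8)])
    oracle <- m
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
      if (m[i, j] < thr) oracle[i, j] <- 0
    keep <- rowSums(oracle) > 0
    expect_equal(as.matrix(out[, paste0("rep", 1:8)]),
                 oracle[keep, , drop = FALSE], ignore_attr = TRUE)
    expect_equal(out$sequence_id, tab$sequence_id[keep])
  }
})

test_that("raising the per-replicate threshold never enlarges the survivor set", {
  set.seed(31)
  tab <- random_count_table(30)
  prev <- filter_per_replicate_low_count(tab, 1)$sequence_id
  for (thr in 2:8) {
    cur <- filter_per_replicate_low_count(tab, thr)$sequence_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("taxonomy assignment is exact-match only", {
  barcodes <- c("ACGTACGTAC", "TTTTCCCCGG")
  refdb <- make_refdb(barcodes)
  rec <- make_records(list(hit = rep(5, 8), miss = rep(5, 8)),
                      dna = c("ACGTACGTAC", "ACGTACGTAG"))  # one mismatch
  parts <- assign_taxonomy_exact(rec, refdb)
  expect_equal(parts$identified$sequence_id, "hit")
  expect_equal(parts$identified$taxon, "T01")
  expect_equal(parts$unidentified$sequence_id, "miss")
})

test_that("taxonomy partition equals hash-set membership on random queries", {
  set.seed(41)
  barcodes <- unique(random_fixture_dna(100, len = 20))
  refdb <- make_refdb(barcodes, taxa = sprintf("T%03d", seq_along(barcodes)))
  queries <- c(sample(barcodes, 500, replace = TRUE),
               random_fixture_dna(500, len = 21))
  rec <- make_records(setNames(rep(list(rep(4, 8)), 1000),
                               sprintf("q%04d", 1:1000)),
                      dna = queries)
  parts <- assign_taxonomy_exact(rec, refdb)
  in_set <- queries %in% barcodes
  expect_equal(sort(parts$identified$sequence_id), sort(rec$sequence_id[in_set]))
  expect_equal(sort(parts$unidentified$sequence_id), sort(rec$sequence_id[!in_set]))
  # labels agree with the lookup
  idx <- match(parts$identified$dna, barcodes)
  expect_equal(parts$identified$taxon, refdb$taxonomy$taxon[idx])
})

test_that("Vaccinium poly-A rule resolves species by 3' run length", {
  stem <- "GGATCAATTC"
  expect_equal(resolve_vaccinium(paste0(stem, strrep("A", 5))),
               "Vaccinium myrtillus")
  expect_equal(resolve_vaccinium(paste0(stem, strrep("A", 9))),
               "Vaccinium vitis-idaea")
  expect_equal(resolve_vaccinium(paste0(stem, strrep("A", 7))), "Vaccinium")
  expect_equal(resolve_vaccinium(stem), "Vaccinium myrtillus")  # no terminal A
})

test_that("blacklist removal equals set-membership partition", {
  set.seed(51)
  dna <- random_fixture_dna(40)
  bad <- sample(dna, 7)
  refdb <- make_refdb(dna, blacklist_synthetic = bad[1:3],
                      blacklist_false_positive = bad[4:7])
  rec <- make_records(setNames(rep(list(rep(4, 8)), 40), sprintf("q%02d", 1:40)),
                      dna = dna)
  out <- apply_blacklists(rec, refdb)
  expect_setequal(out$dna, setdiff(dna, bad))
  # empty blacklists are the identity
  refdb0 <- make_refdb(dna)
  expect_equal(apply_blacklists(rec, refdb0), rec)
})

test_that("dataset-wide filter applies both read and replicate conditions", {
  nine_reads_4reps  <- c(3, 2, 2, 2, 0, 0, 0, 0)   # 9 reads in 4 cells
  fifty_reads_2reps <- c(25, 25, 0, 0, 0, 0, 0, 0) # 50 reads in 2 cells
  boundary          <- c(4, 3, 3, 0, 0, 0, 0, 0)   # 10 reads in 3 cells
  rec <- make_records(list(a = nine_reads_4reps, b = fifty_reads_2reps,
                           c = boundary))
  out <- filter_dataset_wide(rec, 10, 3)
  expect_equal(out$sequence_id, "c")
})

test_that("dataset-wide filter aggregates across samples before deciding", {
  # 6 reads/2 cells in each of two samples: survives only at dataset scope
  dna <- random_fixture_dna(1)
  rec <- rbind(make_records(list(a = c(3, 3, 0, 0, 0, 0, 0, 0)),
                            sample_id = "s1", dna = dna),
               make_records(list(a = c(0, 0, 4, 3, 0, 0, 0, 0)),
                            sample_id = "s2", dna = dna))
  expect_equal(nrow(filter_dataset_wide(rec, 10, 3)), 2L)
  expect_equal(nrow(filter_dataset_wide(rec, 14, 3)), 0L)
})

test_that("merging unions replicate detections and conserves reads", {
  dna <- random_fixture_dna(2)
  rec <- rbind(
    make_records(list(b1 = c(5, 6, 0, 0, 0, 0, 0, 0)), dna = dna[1]),
    make_records(list(b2 = c(0, 4, 7, 0, 0, 0, 0, 0)), dna = dna[2]))
  rec$taxon <- "X"; rec$rank <- "species"; rec$group <- "terrestrial"
  out <- merge_cooccurring_barcodes(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(out$taxon, "X")
  expect_equal(out$n_detections, 3L)               # union {1,2} and {2,3}
  expect_equal(unname(unlist(out[, paste0("det", 1:8)])),
               c(TRUE, TRUE, TRUE, rep(FALSE, 5)))
  expect_equal(out$reads, sum(rec[, paste0("rep", 1:8)]))
  expect_gte(out$n_detections, max(rowSums(rec[, paste0("rep", 1:8)] > 0)))
})

test_that("same-name barcodes that never co-occur get numeric suffixes", {
  dna <- random_fixture_dna(2)
  rec <- rbind(
    make_records(list(b1 = c(5, 6, 0, 0, 0, 0, 0, 0)), sample_id = "s1",
                 dna = dna[1]),
    make_records(list(b2 = c(0, 4, 7, 0, 0, 0, 0, 0)), sample_id = "s2",
                 dna = dna[2]))
  rec$taxon <- "Asteraceae"; rec$rank <- "family"; rec$group <- "terrestrial"
  out <- merge_cooccurring_barcodes(rec)
  expect_setequal(out$taxon, c("Asteraceae1", "Asteraceae2"))
})

test_that("co-occurrence components chain across samples and reads are conserved", {
  set.seed(61)
  dna <- random_fixture_dna(3)
  # a,b co-occur in s1; b,c co-occur in s2 -> all one taxon
  rec <- rbind(
    make_records(list(a = c(5, 0, 0, 0, 0, 0, 0, 0),
                      b = c(0, 5, 0, 0, 0, 0, 0, 0)), sample_id = "s1",
                 dna = dna[1:2]),
    make_records(list(b = c(3, 0, 0, 0, 0, 0, 0, 0),
                      c = c(0, 0, 6, 0, 0, 0, 0, 0)), sample_id = "s2",
                 dna = dna[2:3]))
  rec$taxon <- "Y"; rec$rank <- "genus"; rec$group <- "terrestrial"
  out <- merge_cooccurring_barcodes(rec)
  expect_equal(unique(out$taxon), "Y")
  expect_equal(sum(out$reads), sum(rec[, paste0("rep", 1:8)]))
  # per-sample read conservation
  for (s in c("s1", "s2"))
    expect_equal(sum(out$reads[out$sample_id == s]),
                 sum(rec[rec$sample_id == s, paste0("rep", 1:8)]))
})

test_that("non-target exclusion keeps only terrestrial family-or-below taxa", {
  tab <- make_taxa(rep(list(c(1, 1, 0, 0, 0, 0, 0, 0)), 4),
                   rank = c("species", "above-family", "species", "genus"),
                   group = c("terrestrial", "terrestrial", "alga", "aquatic"))
  out <- exclude_nontarget(tab)
  expect_equal(out$taxon, "T01")
})

test_that("the full harmonization chain is idempotent", {
  ds <- small_dataset()
  h1 <- harmonize(ds$counts, ds$refdb)
  # re-feed the retained records: chain applied twice equals once
  h2 <- harmonize(h1$retained, ds$refdb)
  t1 <- h1$taxa[order(h1$taxa$sample_id, h1$taxa$taxon), ]
  t2 <- h2$taxa[order(h2$taxa$sample_id, h2$taxa$taxon), ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1, t2)
})
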