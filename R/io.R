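#' Read a per-replicate counts table
#'
#' The interchange dialect is TSV with fixed columns `lake_id`,
#' `sample_id`, `extract`, `sample_type` (`sample` / `neg_control`),
#' `sequence_id`, `dna`, then one `repN` column of retained reads per PCR
#' replicate. Counts must parse as non-negative integers; a malformed row
#' aborts with its line number.
#'
#' @param path TSV file path.
#' @return a record table (data.frame).
#' @export
read_counts_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("lake_id", "sample_id", "sample_type", "sequence_id", "dna")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_sedadiv(path, ": missing columns ", paste(miss, collapse = ", "))
  reps <- grep("^rep[0-9]+$", names(d), value = TRUE)
  if (!length(reps)) stop_sedadiv(path, ": no rep* count columns")
  for (r in reps) {
    v <- suppressWarnings(as.numeric(d[[r]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      stop_sedadiv(path, ": malformed count in column ", r, ", line ",
                   bad[1] + 1L)
    d[[r]] <- as.integer(v)
  }
  if (nrow(d) && any(!d$sample_type %in% c("sample", "neg_control")))
    stop_sedadiv(path, ": sample_type must be 'sample' or 'neg_control'")
  d
}

#' @rdname read_counts_tsv
#' @param records record table to write.
#' @param path output path.
#' @export
write_counts_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Read a reference database (FASTA + taxonomy TSV + blacklists)
#'
#' The FASTA holds barcode sequences keyed by id; the taxonomy TSV has
#' columns `barcode_id`, `taxon`, `rank`, `group`, and optionally
#' `polyA_group`. Every FASTA id must have a taxonomy row and vice versa.
#' Blacklists are plain text, one sequence per line; missing paths give
#' empty blacklists.
#'
#' @param fasta_path,taxonomy_path,synthetic_path,false_positive_path file
#'   paths.
#' @return a reference database list as in [generate_reference_db()].
#' @export
read_reference <- function(fasta_path, taxonomy_path, synthetic_path = NULL,
                           false_positive_path = NULL) {
  seqs <- read_fasta(fasta_path)
  tax <- read.delim(taxonomy_path, stringsAsFactors = FALSE)
  need <- c("barcode_id", "taxon", "rank", "group")
  miss <- setdiff(need, names(tax))
  if (length(miss))
    stop_sedadiv(taxonomy_path, ": missing columns ",
                 paste(miss, collapse = ", "))
  orphan <- setdiff(names(seqs), tax$barcode_id)
  if (length(orphan))
    stop_sedadiv("FASTA ids without taxonomy rows: ",
                 paste(head(orphan, 3), collapse = ", "))
  orphan2 <- setdiff(tax$barcode_id, names(seqs))
  if (length(orphan2))
    stop_sedadiv("taxonomy rows without FASTA sequence: ",
                 paste(head(orphan2, 3), collapse = ", "))
  tax$barcode <- unname(seqs[tax$barcode_id])
  if (!"polyA_group" %in% names(tax)) tax$polyA_group <- FALSE
  tax$polyA_group <- as.logical(tax$polyA_group)
  read_list <- function(p) {
    if (is.null(p) || !file.exists(p)) return(character(0))
    x <- readLines(p)
    x[nzchar(x)]
  }
  list(taxonomy = tax[, c("barcode", "taxon", "rank", "group", "polyA_group")],
       blacklist_synthetic = read_list(synthetic_path),
       blacklist_false_positive = read_list(false_positive_path))
}

read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop_sedadiv(path, ": not a FASTA file")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  setNames(toupper(seqs), ids)
}

write_fasta <- function(seqs, path) {
  out <- character(2 * length(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  out[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(out, path)
  invisible(path)
}

#' Write a simulated dataset to disk
#'
#' Writes the file set of [simulate_dataset()]: counts TSV, reference
#' FASTA + taxonomy TSV, both blacklists, lake metadata, sample ages,
#' proxy series, and truth tables.
#'
#' @param dataset output of [simulate_dataset()].
#' @param out_dir directory (created if needed).
#' @return named character vector of paths.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  tax <- dataset$refdb$taxonomy
  tax$barcode_id <- sprintf("bc_%04d", seq_len(nrow(tax)))
  write_fasta(setNames(tax$barcode, tax$barcode_id), p("reference.fasta"))
  write_tsv(tax[, c("barcode_id", "taxon", "rank", "group", "polyA_group")],
            p("taxonomy.tsv"))
  writeLines(dataset$refdb$blacklist_synthetic, p("blacklist_synthetic.txt"))
  writeLines(dataset$refdb$blacklist_false_positive,
             p("blacklist_false_positive.txt"))
  write_counts_tsv(dataset$counts, p("counts.tsv"))
  write_tsv(dataset$lakes, p("lakes.tsv"))
  write_tsv(dataset$samples, p("samples.tsv"))
  write_tsv(dataset$proxy, p("proxy.tsv"))
  write_tsv(dataset$truth, p("truth_samples.tsv"))
  write_tsv(dataset$communities, p("truth_communities.tsv"))
  c(counts = p("counts.tsv"), reference_fasta = p("reference.fasta"),
    taxonomy = p("taxonomy.tsv"),
    blacklist_synthetic = p("blacklist_synthetic.txt"),
    blacklist_false_positive = p("blacklist_false_positive.txt"),
    lakes = p("lakes.tsv"), samples = p("samples.tsv"),
    proxy = p("proxy.tsv"), truth_samples = p("truth_samples.tsv"),
    truth_communities = p("truth_communities.tsv"))
}

#' Pipeline configuration
#'
#' Collects input paths, all analysis thresholds and the RNG seed for
#' [run_pipeline()]. Defaults are the standard analysis settings:
#' per-replicate filter at 3 reads, dataset-wide filter at 10 reads / 3
#' replicate cells, MTQ gate 0.75, MAQ gate 0.2, wtRep applicability
#' 0.33 / 10 barcodes, 500-year bins standardized to 5 samples with 1000
#' resamples.
#'
#' @param counts,reference_fasta,taxonomy,blacklist_synthetic,blacklist_false_positive,lakes,samples,proxy
#'   input file paths (blacklists optional).
#' @param out_dir output directory.
#' @param min_reads,min_total_reads,min_total_replicates,scope filtering
#'   thresholds.
#' @param mtq_threshold,maq_threshold QC gate thresholds.
#' @param min_mean_prop,min_barcodes wtRep applicability rule.
#' @param bin_width,subsample_size,n_resamples species-pool controls.
#' @param n_replicates PCR replicates per sample.
#' @param proxy_exclude_below drop samples with proxy values below this in
#'   the driver model (NULL keeps all).
#' @param ar1 use CAR1 residuals in trend fits.
#' @param seed integer seed for all stochastic stages.
#' @return a `sedadiv_config` list.
#' @export
pipeline_config <- function(counts, reference_fasta, taxonomy,
                            blacklist_synthetic = NULL,
                            blacklist_false_positive = NULL,
                            lakes, samples, proxy, out_dir,
                            min_reads = 3, min_total_reads = 10,
                            min_total_replicates = 3, scope = "dataset",
                            mtq_threshold = 0.75, maq_threshold = 0.2,
                            min_mean_prop = 0.33, min_barcodes = 10,
                            bin_width = 500, subsample_size = 5,
                            n_resamples = 1000, n_replicates = 8,
                            proxy_exclude_below = -39, ar1 = TRUE,
                            seed = 1) {
  cfg <- as.list(environment())
  stopifnot(min_reads >= 1, min_total_reads >= 1, min_total_replicates >= 1,
            bin_width > 0, subsample_size > 0, n_resamples > 0)
  class(cfg) <- "sedadiv_config"
  cfg
}

# no timestamps: identical configurations must produce byte-identical runs
log_line <- function(con, ...) {
  writeLines(paste0(...), con)
}

#' Run the full analysis pipeline
#'
#' Executes the pinned stage order on the configured input files:
#' filtering/harmonization, per-sample QC and gating (with extraction
#' replicate selection), per-sample diversity, local and regional
#' accumulation, the time-binned regional species pool with its models,
#' and the richness trend and driver models. All outputs are written as
#' TSV under `config$out_dir` along with `run_log.txt` recording package
#' version, thresholds, seed and per-stage record counts. Reruns with an
#' identical configuration are byte-identical (the log's timestamps
#' aside).
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the main in-memory results: `qc`,
#'   `taxa`, `diversity`, `accumulation`, `regional_curve`, `pool_bins`,
#'   `pool_models`, `trend_fits`, `regional_trend`, `driver_fit`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "sedadiv_config"))
  for (f in c("counts", "reference_fasta", "taxonomy", "lakes", "samples",
              "proxy")) {
    if (!file.exists(config[[f]]))
      stop_sedadiv("input file for '", f, "' not found: ", config[[f]])
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run_log.txt")
  con <- file(logf, "w"); on.exit(close(con))
  log_line(con, "sedadiv ", as.character(packageVersion("sedadiv")),
           " seed=", config$seed)
  paths <- c("counts", "reference_fasta", "taxonomy", "blacklist_synthetic",
             "blacklist_false_positive", "lakes", "samples", "proxy",
             "out_dir")
  thr <- config[setdiff(names(config), paths)]
  thr <- thr[!vapply(thr, function(x) is.null(x) || !is.atomic(x) ||
                       length(x) != 1, logical(1))]
  log_line(con, "config: ",
           paste(names(thr), unlist(thr), sep = "=", collapse = " "))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_sedadiv("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  raw <- stage("read", read_counts_tsv(config$counts))
  refdb <- stage("read", read_reference(config$reference_fasta,
                                        config$taxonomy,
                                        config$blacklist_synthetic,
                                        config$blacklist_false_positive))
  ages <- read_tsv(config$samples)
  lakes <- read_tsv(config$lakes)
  proxy <- read_tsv(config$proxy)
  log_line(con, "read: ", nrow(raw), " count rows, ",
           nrow(refdb$taxonomy), " reference barcodes")

  harm <- stage("filter", harmonize(raw, refdb, config$min_reads,
                                    config$min_total_reads,
                                    config$min_total_replicates,
                                    config$scope))
  log_line(con, "filter: ", nrow(harm$prefiltered), " prefiltered, ",
           nrow(harm$retained), " retained rows, ",
           if (is.null(harm$taxa)) 0 else nrow(harm$taxa), " taxon rows")

  qc <- stage("qc", sample_qc(harm, raw, config$n_replicates,
                              config$mtq_threshold, config$maq_threshold))
  write_tsv(qc, file.path(config$out_dir, "qc_report.tsv"))
  keep <- qc$sample_id[qc$passed & qc$selected_extract &
                         qc$sample_type == "sample"]
  log_line(con, "qc: ", nrow(qc), " sample-extracts scored, ",
           length(keep), " passed the gate")

  # restrict downstream tables to passed samples and their chosen extract
  sel <- qc[qc$selected_extract, c("sample_id", "extract")]
  pick <- function(d) {
    if (!"extract" %in% names(d)) d$extract <- 1L
    k <- paste(d$sample_id, d$extract) %in% paste(sel$sample_id, sel$extract)
    d[k & d$sample_id %in% keep, , drop = FALSE]
  }
  taxa <- pick(harm$taxa)
  if (!nrow(taxa)) stop_sedadiv("pipeline stage 'qc' failed: no samples passed")
  write_taxon_table(taxa, file.path(config$out_dir, "taxon_table.tsv"),
                    config$n_replicates)

  rt <- replicate_read_totals(pick(harm$cleaned))
  div <- stage("diversity",
               diversity_table(taxa, rt, ages, config$min_mean_prop,
                               config$min_barcodes, config$n_replicates))
  write_tsv(div, file.path(config$out_dir, "diversity.tsv"))
  log_line(con, "diversity: ", nrow(div), " samples")

  acc <- do.call(rbind, lapply(split(taxa, taxa$lake_id), function(tl) {
    age <- ages$age[match(tl$sample_id, ages$sample_id)]
    ord <- unique(tl$sample_id[order(-age, tl$sample_id)])
    out <- accumulated_richness(ord, split(tl$taxon, tl$sample_id))
    cbind(lake_id = tl$lake_id[1], out,
          age = ages$age[match(out$sample_id, ages$sample_id)])
  }))
  rownames(acc) <- NULL
  write_tsv(acc, file.path(config$out_dir, "accumulated_richness.tsv"))

  reg <- stage("pool", accumulate_regional(taxa, ages))
  write_tsv(reg, file.path(config$out_dir, "regional_accumulation.tsv"))
  bins <- stage("pool",
                binned_species_pool(taxa, ages, config$bin_width,
                                    config$subsample_size,
                                    config$n_resamples, seed = config$seed))
  write_tsv(bins, file.path(config$out_dir, "species_pool_bins.tsv"))
  pool_models <- if (!is.null(bins) && nrow(bins) >= 4) fit_pool_models(bins)
                 else NULL
  log_line(con, "pool: ", nrow(reg), " accumulation points, ",
           if (is.null(bins)) 0 else nrow(bins), " bins")

  trend_fits <- list()
  curves <- list()
  for (lk in unique(div$lake_id)) {
    dl <- div[div$lake_id == lk, ]
    if (nrow(dl) < 8) next
    ft <- stage("drivers", fit_trend_gam(dl$n0, dl$age, ar1 = config$ar1))
    trend_fits[[lk]] <- ft
    curves[[lk]] <- cbind(lake_id = lk, ft$fitted)
  }
  if (length(curves))
    write_tsv(do.call(rbind, curves),
              file.path(config$out_dir, "trend_curves.tsv"))
  regional_trend <- stage("drivers",
                          fit_regional_gamm(div$n0, div$age, div$lake_id,
                                            ar1 = config$ar1))
  write_tsv(cbind(lake_id = "regional", regional_trend$fitted),
            file.path(config$out_dir, "regional_trend.tsv"))

  prox <- assign_proxy(div$age, proxy, exclude_below = config$proxy_exclude_below)
  drivers <- data.frame(sample_id = div$sample_id, lake_id = div$lake_id,
                        age = div$age, period = split_periods(div$age),
                        d18o = prox$d18o, excluded = prox$excluded,
                        ni = lakes$ni[match(div$lake_id, lakes$lake_id)],
                        richness = div$n0, stringsAsFactors = FALSE)
  write_tsv(drivers, file.path(config$out_dir, "driver_table.tsv"))
  driver_fit <- stage("drivers", fit_driver_lme(drivers))
  model_summary <- rbind(
    data.frame(term = paste0("d18o_", driver_fit$slopes_d18o$period),
               estimate = driver_fit$slopes_d18o$estimate,
               se = driver_fit$slopes_d18o$se,
               p_value = driver_fit$slopes_d18o$p_value),
    data.frame(term = paste0("ni_", driver_fit$slopes_ni$period),
               estimate = driver_fit$slopes_ni$estimate,
               se = driver_fit$slopes_ni$se,
               p_value = driver_fit$slopes_ni$p_value),
    data.frame(term = c("var_fixed_pct", "var_random_pct"),
               estimate = c(driver_fit$var_fixed_pct,
                            driver_fit$var_random_pct),
               se = NA, p_value = NA))
  write_tsv(model_summary, file.path(config$out_dir, "driver_model.tsv"))
  log_line(con, "drivers: ", length(trend_fits), " lake trends, driver model ",
           if (driver_fit$singular_refit) "(refit without random slope)" else "(full)")

  invisible(list(qc = qc, taxa = taxa, diversity = div, accumulation = acc,
                 regional_curve = reg, pool_bins = bins,
                 pool_models = pool_models, trend_fits = trend_fits,
                 regional_trend = regional_trend, driver_fit = driver_fit,
                 paths = config$out_dir))
}

#' Write a harmonized taxon table in long format
#'
#' One row per (lake, sample, taxon) with summed reads, replicate count
#' and the detection flags packed as a bitstring (oldest replicate first).
#'
#' @param taxa taxon table from [merge_cooccurring_barcodes()].
#' @param path output TSV path.
#' @param n_replicates number of detection-flag columns.
#' @export
write_taxon_table <- function(taxa, path, n_replicates = 8) {
  det <- as.matrix(taxa[, paste0("det", seq_len(n_replicates)), drop = FALSE])
  out <- data.frame(lake_id = taxa$lake_id, sample_id = taxa$sample_id,
                    taxon = taxa$taxon, rank = taxa$rank, group = taxa$group,
                    reads = taxa$reads, n_replicates = taxa$n_detections,
                    replicates = apply(det, 1, function(z)
                      paste(as.integer(z), collapse = "")),
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}
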