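#' Configuration of the synthetic multi-lake generator
#'
#' Builds the parameter list consumed by [simulate_dataset()] and its
#' component generators. Defaults emulate a ten-lake Holocene sedaDNA
#' metabarcoding study: 12-55 samples per lake spanning 11.7 ka to the
#' present, eight PCR replicates per sample, a regional pool of ~290
#' terrestrial taxa accumulating in four piecewise phases (fast Early
#' Holocene colonization, a mid-Holocene slowdown, a later uptick, then a
#' plateau), per-sample log richness responding to the warming proxy
#' (Early Holocene only, slope 0.24 per delta-18O unit) and to the
#' catchment nutrient index (slope 0.15), heterogeneous lognormal
#' per-replicate sequencing depth with saturating detection (dropout), a
#' trickle of off-target contaminant sequences, and sporadic low-level
#' detections in negative controls.
#'
#' @param n_lakes number of lakes.
#' @param samples_per_lake inclusive (min, max) range of samples per lake.
#' @param n_replicates PCR replicates per sample (>= 2).
#' @param age_range (oldest, youngest) in cal yr BP; must span at least
#'   two Holocene periods.
#' @param pool_size size of the regional terrestrial taxon pool.
#' @param n_initial_taxa taxa already present at the start of the record.
#' @param colonization_rate_curve data.frame `old`, `young`, `rate`
#'   (taxa per millennium) covering `age_range`.
#' @param beta_temperature effect of the (centered) climate proxy on log
#'   richness; length 1 (all periods) or 3 (Early, Middle, Late).
#' @param beta_nutrient effect of the nutrient index on log richness.
#' @param intercept intercept of log richness at proxy reference and NI 0.
#' @param d18o_ref proxy centering value (the effect is
#'   `beta * (d18o - d18o_ref)`).
#' @param smooth_age optional function(age) added to log richness
#'   (default NULL = flat; temporal structure then comes from pool
#'   truncation and the proxy effect).
#' @param abundance_sdlog sdlog of the lognormal relative abundances.
#' @param depth_lognormal_params (meanlog, sdlog) of per-replicate
#'   retained reads.
#' @param dropout_halfsat expected reads at which per-replicate detection
#'   probability is 0.5.
#' @param contaminant_rate expected off-target sequences per sample.
#' @param negative_control_rate expected sporadic detections per control.
#' @param controls_per_lake negative controls per lake.
#' @param frac_aquatic fraction of reference-database taxa that are
#'   aquatic or algal.
#' @param aquatic_background_rate expected aquatic taxa co-detected per
#'   sample.
#' @param seed integer RNG seed.
#' @return a `sedadiv_simconfig` list.
#' @export
simulation_config <- function(n_lakes = 10,
                              samples_per_lake = c(12, 55),
                              n_replicates = 8,
                              age_range = c(11700, 0),
                              pool_size = 300,
                              n_initial_taxa = 20,
                              colonization_rate_curve = data.frame(
                                old = c(11700, 7000, 5000, 3300),
                                young = c(7000, 5000, 3300, 0),
                                rate = c(42.37, 9.35, 21.82, 4.85)),
                              beta_temperature = c(0.24, 0, 0),
                              beta_nutrient = 0.15,
                              intercept = log(28),
                              d18o_ref = -35.1,
                              smooth_age = NULL,
                              abundance_sdlog = 1.5,
                              depth_lognormal_params = c(meanlog = 8.5, sdlog = 1),
                              dropout_halfsat = 10,
                              contaminant_rate = 5,
                              negative_control_rate = 3,
                              controls_per_lake = 2,
                              frac_aquatic = 0.15,
                              aquatic_background_rate = 2,
                              seed = 1) {
  cfg <- list(n_lakes = n_lakes, samples_per_lake = samples_per_lake,
              n_replicates = n_replicates, age_range = age_range,
              pool_size = pool_size, n_initial_taxa = n_initial_taxa,
              colonization_rate_curve = colonization_rate_curve,
              beta_temperature = rep_len(beta_temperature, 3),
              beta_nutrient = beta_nutrient, intercept = intercept,
              d18o_ref = d18o_ref, smooth_age = smooth_age,
              abundance_sdlog = abundance_sdlog,
              depth_lognormal_params = depth_lognormal_params,
              dropout_halfsat = dropout_halfsat,
              contaminant_rate = contaminant_rate,
              negative_control_rate = negative_control_rate,
              controls_per_lake = controls_per_lake,
              frac_aquatic = frac_aquatic,
              aquatic_background_rate = aquatic_background_rate,
              seed = as.integer(seed))
  stopifnot(cfg$n_lakes > 0, cfg$n_replicates >= 2,
            all(cfg$samples_per_lake > 0), cfg$pool_size > 0,
            cfg$age_range[1] > cfg$age_range[2])
  if (length(unique(split_periods(cfg$age_range))) < 2)
    stop_sedadiv("age_range must span at least two Holocene periods")
  class(cfg) <- "sedadiv_simconfig"
  cfg
}

random_dna <- function(n, len_range = c(10, 80)) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate a synthetic barcode reference database
#'
#' Emulates a local taxonomic reference database: unique barcode sequences
#' of 10-80 nt, each mapped to a taxon with a rank (species / genus /
#' family / above-family) and an ecological group (terrestrial / aquatic /
#' alga). The construction always includes (i) a *Vaccinium*-type pair of
#' barcodes differing only in the length of their 3' poly-A run (one with
#' <= 5 A's, one with > 8), resolved by [resolve_vaccinium()], and (ii)
#' several taxa carrying two distinct barcodes, to exercise barcode
#' merging. Two blacklists accompany the database: synthetic
#' positive-control sequences and curated false positives; both are
#' disjoint from the barcodes here but a pipeline may also blacklist a
#' referenced sequence (the blacklist wins).
#'
#' @param n_taxa number of taxa (>= 10).
#' @param frac_aquatic fraction of taxa that are aquatic or algal
#'   (0 <= f < 1).
#' @param seed RNG seed; the same seed reproduces the database exactly.
#' @param n_false_positive size of the false-positive blacklist.
#' @return list with `taxonomy` (data.frame `barcode`, `taxon`, `rank`,
#'   `group`, `polyA_group`), `blacklist_synthetic`,
#'   `blacklist_false_positive`.
#' @export
generate_reference_db <- function(n_taxa, frac_aquatic = 0.1, seed = 1,
                                  n_false_positive = 8) {
  stopifnot(n_taxa >= 10, frac_aquatic >= 0, frac_aquatic < 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  n_aq <- round(frac_aquatic * n_taxa)
  n_multi <- max(2L, ceiling(0.08 * n_taxa))   # taxa with two barcodes
  taxon <- sprintf("Taxon_%03d", seq_len(n_taxa))
  rank <- sample(c("species", "genus", "family", "above-family"), n_taxa,
                 replace = TRUE, prob = c(0.55, 0.2, 0.15, 0.1))
  group <- rep("terrestrial", n_taxa)
  if (n_aq > 0) {
    aq_idx <- seq_len(n_aq)                    # first taxa are off-target
    group[aq_idx] <- rep(c("aquatic", "alga"), length.out = n_aq)
  }
  # the last two terrestrial taxa become the Vaccinium poly-A pair
  terr <- which(group == "terrestrial")
  vac <- utils::tail(terr, 2)
  rank[vac] <- "species"
  # multi-barcode taxa: terrestrial, outside the Vaccinium pair
  multi <- utils::head(setdiff(terr, vac), n_multi)

  n_barcodes <- n_taxa + length(multi)
  for (try in 1:20) {
    dna <- random_dna(n_barcodes + 6 + n_false_positive)
    stem <- substr(dna[n_taxa - 1], 1, 30)
    stem <- sub("A+$", "", stem)
    if (nchar(stem) < 8) next
    dna[vac[1]] <- paste0(stem, strrep("A", 4))    # run 4  -> V. myrtillus
    dna[vac[2]] <- paste0(stem, strrep("A", 10))   # run 10 -> V. vitis-idaea
    if (!anyDuplicated(dna)) break
    if (try == 20) stop_sedadiv("barcode collision persisted after max retries")
  }
  barcode <- dna[seq_len(n_taxa)]
  tax <- data.frame(barcode = barcode, taxon = taxon, rank = rank,
                    group = group, polyA_group = FALSE,
                    stringsAsFactors = FALSE)
  tax$polyA_group[vac] <- TRUE
  tax$taxon[vac] <- vapply(tax$barcode[vac], resolve_vaccinium, character(1))
  # second barcodes for the multi-barcode taxa
  extra <- data.frame(barcode = dna[n_taxa + seq_along(multi)],
                      taxon = taxon[multi], rank = rank[multi],
                      group = group[multi], polyA_group = FALSE,
                      stringsAsFactors = FALSE)
  tax <- rbind(tax, extra)
  rownames(tax) <- NULL
  list(taxonomy = tax,
       blacklist_synthetic = dna[n_barcodes + 1:6],
       blacklist_false_positive = dna[n_barcodes + 6 + seq_len(n_false_positive)])
}

#' Simulate regional colonization ages
#'
#' Assigns each taxon of the regional pool a colonization age following
#' the configured piecewise rates (taxa per millennium): within each rate
#' window, `round(rate * width_ka)` taxa colonize at ages drawn uniformly.
#' `n_initial_taxa` are present from the start. The cumulative count of
#' colonized taxa toward the present is therefore non-decreasing with the
#' configured slopes in expectation.
#'
#' @param config a [simulation_config()]; uses `pool_size`,
#'   `n_initial_taxa`, `colonization_rate_curve`, `age_range`, `seed`.
#' @param taxa optional character vector of taxon names to assign
#'   (defaults to `Pool_###` placeholders).
#' @return data.frame `taxon`, `colonization_age` (cal yr BP), oldest
#'   first.
#' @export
simulate_regional_colonization <- function(config, taxa = NULL) {
  crv <- config$colonization_rate_curve
  if (max(crv$old) < config$age_range[1] || min(crv$young) > config$age_range[2])
    stop_sedadiv("colonization rate curve does not cover age_range")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  n_window <- round(crv$rate * (crv$old - crv$young) / 1000)
  n_total <- config$n_initial_taxa + sum(n_window)
  if (n_total > config$pool_size)
    stop_sedadiv("pool_size (", config$pool_size,
                 ") smaller than implied cumulative colonizations (", n_total, ")")
  ages <- c(rep(config$age_range[1], config$n_initial_taxa),
            unlist(lapply(seq_len(nrow(crv)), function(i)
              if (n_window[i] > 0) runif(n_window[i], crv$young[i], crv$old[i])
              else numeric(0))))
  ages <- sort(ages, decreasing = TRUE)
  if (is.null(taxa)) taxa <- sprintf("Pool_%03d", seq_len(config$pool_size))
  data.frame(taxon = sample(taxa, length(ages)),
             colonization_age = ages, stringsAsFactors = FALSE)
}

#' Synthetic climate-proxy series
#'
#' A delta-18O temperature proxy on a 50-year grid shaped like the
#' Greenland ice-core Holocene: a steep Early Holocene warming (0.92
#' delta-18O units per ka from 11.7 to 8.3 ka), a flat warm Middle
#' Holocene, and a slight Late Holocene cooling (-0.13 per ka), with
#' small smooth wiggles. The two oldest grid points carry a cold
#' excursion below -39, mirroring the extreme values conventionally
#' excluded from driver models.
#'
#' @param config a [simulation_config()].
#' @return data.frame `age` (cal yr BP, old to young, 50-yr step), `d18o`.
#' @export
simulate_proxy_series <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 2L)
  age <- seq(11700, 0, by = -50)
  base <- ifelse(age >= 8300, -35.07 - 0.92 * (age - 8300) / 1000,
          ifelse(age >= 4250, -35.05 + 0.1 * sin((age - 4250) / 700),
                 -35.6 + 0.13 * age / 1000))
  wig <- stats::filter(rnorm(length(age), 0, 0.25), rep(1 / 5, 5),
                       circular = TRUE)
  d18o <- base + as.numeric(wig)
  d18o[1:2] <- c(-39.5, -39.1)   # terminal cold snap, excludable
  data.frame(age = age, d18o = round(d18o, 3))
}

#' Synthetic lake metadata
#'
#' Catchment geology (P, K, Ca in weight percent, extended Mohs hardness
#' of the most weatherable principal mineral) spanning nutrient-poor to
#' nutrient-rich bedrock, the derived nutrient index, and per-lake sample
#' counts and ages.
#'
#' @param config a [simulation_config()].
#' @return list with `lakes` (data.frame `lake_id`, `P`, `K`, `Ca`,
#'   `H_min`, `ni`, `n_samples`) and `samples` (data.frame `lake_id`,
#'   `sample_id`, `age`).
#' @export
simulate_lakes <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 3L)
  n <- config$n_lakes
  lakes <- data.frame(
    lake_id = sprintf("L%02d", seq_len(n)),
    P = round(runif(n, 0.2, 2), 3),
    K = round(runif(n, 0.5, 4), 3),
    Ca = round(runif(n, 1, 30), 2),
    H_min = round(runif(n, 2, 7), 1),
    stringsAsFactors = FALSE)
  lakes$ni <- nutrient_index(lakes$P, lakes$K, lakes$Ca, lakes$H_min)
  lakes$n_samples <- sample(config$samples_per_lake[1]:config$samples_per_lake[2],
                            n, replace = TRUE)
  samples <- do.call(rbind, lapply(seq_len(n), function(i) {
    ages <- sort(round(runif(lakes$n_samples[i], config$age_range[2],
                             config$age_range[1])), decreasing = TRUE)
    data.frame(lake_id = lakes$lake_id[i],
               sample_id = sprintf("%s_s%03d", lakes$lake_id[i],
                                   seq_along(ages)),
               age = ages, stringsAsFactors = FALSE)
  }))
  list(lakes = lakes, samples = samples)
}

#' Simulate the true community of each sample in a lake record
#'
#' Expected log richness per sample is
#' `intercept + beta_temperature[period] * (d18o - d18o_ref) +
#' beta_nutrient * NI + smooth(age)`; realized richness is Poisson around
#' the expectation, truncated to the taxa that have colonized the region
#' by the sample's age (a warning is issued when the expectation exceeds
#' the colonized pool). Community members are drawn from the colonized
#' pool and given lognormal relative abundances renormalized to the
#' simplex (few dominant, many rare). A small number of aquatic / algal
#' background taxa join each community with down-weighted abundances.
#'
#' @param lake one row of `simulate_lakes()$lakes` (needs `lake_id`, `ni`).
#' @param samples the lake's rows of `simulate_lakes()$samples`.
#' @param colonization output of [simulate_regional_colonization()].
#' @param proxy output of [simulate_proxy_series()].
#' @param config a [simulation_config()].
#' @param aquatic_taxa character vector of off-target taxa available as
#'   background (may be empty).
#' @return list with `communities` (data.frame `sample_id`, `taxon`,
#'   `rel_abundance`) and `truth` (data.frame `sample_id`, `age`, `d18o`,
#'   `period`, `ni`, `expected_log_richness`, `true_richness`).
#' @export
simulate_lake_record <- function(lake, samples, colonization, proxy, config,
                                 aquatic_taxa = character(0)) {
  stopifnot(all(samples$age <= config$age_range[1]),
            all(samples$age >= config$age_range[2]))
  prox <- assign_proxy(samples$age, proxy)
  period <- split_periods(samples$age)
  beta_t <- config$beta_temperature[as.integer(period)]
  smooth <- if (is.null(config$smooth_age)) 0 else config$smooth_age(samples$age)
  eta <- config$intercept + beta_t * (prox$d18o - config$d18o_ref) +
    config$beta_nutrient * lake$ni + smooth
  comm <- vector("list", nrow(samples))
  true_rich <- integer(nrow(samples))
  clamped <- FALSE
  for (i in seq_len(nrow(samples))) {
    avail <- colonization$taxon[colonization$colonization_age >= samples$age[i]]
    if (exp(eta[i]) > length(avail)) clamped <- TRUE
    r <- max(1L, min(rpois(1, exp(eta[i])), length(avail)))
    members <- sample(avail, r)
    w <- rlnorm(r, 0, config$abundance_sdlog)
    n_aq <- if (length(aquatic_taxa))
      min(rpois(1, config$aquatic_background_rate), length(aquatic_taxa)) else 0L
    if (n_aq > 0) {
      members <- c(members, sample(aquatic_taxa, n_aq))
      w <- c(w, 0.5 * rlnorm(n_aq, 0, config$abundance_sdlog))
    }
    comm[[i]] <- data.frame(sample_id = samples$sample_id[i], taxon = members,
                            rel_abundance = w / sum(w),
                            stringsAsFactors = FALSE)
    true_rich[i] <- r
  }
  if (clamped)
    warning("expected richness exceeded the colonized pool for some samples; clamped")
  list(communities = do.call(rbind, comm),
       truth = data.frame(sample_id = samples$sample_id, age = samples$age,
                          d18o = prox$d18o, period = period, ni = lake$ni,
                          expected_log_richness = eta,
                          true_richness = true_rich,
                          stringsAsFactors = FALSE))
}

#' Simulate per-replicate read counts for one community
#'
#' Each PCR replicate draws a lognormal total depth; each community taxon
#' is detected in a replicate with saturating probability
#' `a / (a + halfsat)` where `a = rel_abundance * depth` is its expected
#' read count there, and contributes `max(1, Poisson(a))` reads when
#' detected (the downstream per-replicate filter then removes weak cells).
#' A taxon with several reference barcodes spreads its reads over them.
#' Contaminant sequences absent from the reference database are injected
#' at rate `contaminant_rate` with sporadic replicate patterns (and are
#' occasionally read-abundant, which depresses MTQ but not MAQ);
#' false-positive blacklist sequences are injected occasionally. Negative
#' controls (`community = NULL`) contain only `Poisson(negative_control_rate)`
#' single-replicate low-count detections.
#'
#' @param community data.frame `taxon`, `rel_abundance` for one sample, or
#'   NULL for a negative control.
#' @param refdb reference database.
#' @param config a [simulation_config()].
#' @return data.frame `dna`, `rep1..repN` (only rows with any reads).
#' @export
simulate_reads <- function(community, refdb, config) {
  nrep <- config$n_replicates
  p <- config$depth_lognormal_params
  rows <- list()
  add <- function(dna, counts) {
    rows[[length(rows) + 1L]] <<-
      c(list(dna = dna), as.list(setNames(as.integer(round(counts)),
                                          rep_cols(length(counts)))))
  }
  all_known <- c(refdb$taxonomy$barcode, refdb$blacklist_synthetic,
                 refdb$blacklist_false_positive)

  if (!is.null(community) && nrow(community)) {
    depth <- rlnorm(nrep, p[["meanlog"]], p[["sdlog"]])
    for (i in seq_len(nrow(community))) {
      bars <- refdb$taxonomy$barcode[refdb$taxonomy$taxon == community$taxon[i]]
      if (!length(bars)) next
      use <- if (length(bars) > 1 && runif(1) < 0.5) bars else bars[1]
      a <- community$rel_abundance[i] * depth
      detected <- runif(nrep) < a / (a + config$dropout_halfsat)
      if (!any(detected)) next
      for (b in seq_along(use)) {
        counts <- integer(nrep)
        frac <- if (length(use) > 1) c(0.6, 0.4)[b] else 1
        counts[detected] <- pmax(1L, rpois(sum(detected), frac * a[detected]))
        add(use[b], counts)
      }
    }
    # contaminants: novel sequences, sporadic replicate patterns
    n_c <- rpois(1, config$contaminant_rate)
    for (j in seq_len(n_c)) {
      repeat {
        dna <- random_dna(1, c(20, 60))
        if (!dna %in% all_known) break
      }
      counts <- integer(nrep)
      k <- 1 + rbinom(1, 2, 0.3)
      reps <- sample.int(nrep, k)
      counts[reps] <- if (runif(1) < 0.1) rpois(k, 2000) else 3 + rpois(k, 20)
      add(dna, counts)
    }
    # occasional known false positive, caught by the blacklist
    if (runif(1) < 0.3 && length(refdb$blacklist_false_positive)) {
      counts <- integer(nrep)
      reps <- sample.int(nrep, min(nrep, 3))
      counts[reps] <- 3 + rpois(3, 30)
      add(sample(refdb$blacklist_false_positive, 1), counts)
    }
  } else {
    # negative control: sporadic low-level detections only
    n_d <- rpois(1, config$negative_control_rate)
    pool <- c(refdb$taxonomy$barcode, random_dna(max(1, n_d), c(20, 60)))
    for (j in seq_len(n_d)) {
      counts <- integer(nrep)
      counts[sample.int(nrep, 1)] <- 3 + rpois(1, 15)
      add(sample(pool, 1), counts)
    }
  }
  if (!length(rows)) {
    out <- data.frame(dna = character(0))
    for (r in rep_cols(nrep)) out[[r]] <- integer(0)
    return(out)
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  names(out) <- c("dna", rep_cols(nrep))
  # collapse repeated dna rows (same sequence drawn twice)
  if (anyDuplicated(out$dna)) {
    m <- rowsum(as.matrix(out[, -1]), out$dna)
    out <- data.frame(dna = rownames(m), m, row.names = NULL,
                      stringsAsFactors = FALSE)
    names(out) <- c("dna", rep_cols(nrep))
  }
  out[rowSums(out[, -1, drop = FALSE]) > 0, , drop = FALSE]
}

#' Simulate a complete multi-lake sedaDNA dataset
#'
#' Orchestrates the component generators into the file set the pipeline
#' consumes: a reference database with blacklists, lake metadata with
#' nutrient indices, sample ages, a climate-proxy series, per-replicate
#' read counts for every sample and negative control, and truth tables
#' for recovery tests. Two samples are given a second extraction
#' replicate to exercise extract selection. Identical configurations
#' (including seed) yield identical outputs.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory; when given, all tables are written
#'   there as TSV/FASTA via the `write_*` helpers and the paths returned.
#' @return list with `counts`, `refdb`, `lakes`, `samples`, `proxy`,
#'   `truth`, `communities`, `config`, and (if written) `paths`.
#' @export
simulate_dataset <- function(config = simulation_config(), out_dir = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  n_refdb_taxa <- ceiling(config$pool_size / (1 - config$frac_aquatic)) + 10
  refdb <- generate_reference_db(n_refdb_taxa, config$frac_aquatic,
                                 seed = config$seed)
  tax <- refdb$taxonomy
  terrestrial <- unique(tax$taxon[tax$group == "terrestrial"])
  off_target <- unique(tax$taxon[tax$group != "terrestrial"])
  pool <- utils::head(terrestrial, config$pool_size)
  colonization <- simulate_regional_colonization(config, taxa = pool)
  proxy <- simulate_proxy_series(config)
  geo <- simulate_lakes(config)

  set.seed(config$seed + 4L)
  counts <- list(); truths <- list(); comms <- list()
  for (i in seq_len(nrow(geo$lakes))) {
    lake <- geo$lakes[i, ]
    smp <- geo$samples[geo$samples$lake_id == lake$lake_id, ]
    rec <- simulate_lake_record(lake, smp, colonization, proxy, config,
                                aquatic_taxa = off_target)
    truths[[i]] <- cbind(lake_id = lake$lake_id, rec$truth)
    comms[[i]] <- cbind(lake_id = lake$lake_id, rec$communities)
    for (s in smp$sample_id) {
      cm <- rec$communities[rec$communities$sample_id == s, ]
      tab <- simulate_reads(cm, refdb, config)
      if (nrow(tab))
        counts[[length(counts) + 1L]] <- cbind(
          lake_id = lake$lake_id, sample_id = s, extract = 1L,
          sample_type = "sample", tab)
    }
    for (k in seq_len(config$controls_per_lake)) {
      tab <- simulate_reads(NULL, refdb, config)
      if (nrow(tab))
        counts[[length(counts) + 1L]] <- cbind(
          lake_id = lake$lake_id,
          sample_id = sprintf("%s_nc%02d", lake$lake_id, k), extract = 1L,
          sample_type = "neg_control", tab)
    }
  }
  counts <- do.call(rbind, counts)
  # re-extract two samples (new reads from the same community)
  resampled <- utils::head(unique(counts$sample_id[counts$sample_type == "sample"]), 2)
  allcomm <- do.call(rbind, comms)
  for (s in resampled) {
    cm <- allcomm[allcomm$sample_id == s, ]
    tab <- simulate_reads(cm[, c("taxon", "rel_abundance")], refdb, config)
    if (nrow(tab))
      counts <- rbind(counts, cbind(lake_id = cm$lake_id[1], sample_id = s,
                                    extract = 2L, sample_type = "sample", tab))
  }
  # stable sequence ids across the dataset
  dict <- sort(unique(counts$dna))
  counts$sequence_id <- sprintf("seq_%05d", match(counts$dna, dict))
  counts <- counts[order(counts$lake_id, counts$sample_id, counts$extract,
                         counts$sequence_id),
                   c("lake_id", "sample_id", "extract", "sample_type",
                     "sequence_id", "dna", rep_cols(config$n_replicates))]
  rownames(counts) <- NULL
  out <- list(counts = counts, refdb = refdb, lakes = geo$lakes,
              samples = geo$samples, proxy = proxy,
              truth = do.call(rbind, truths), communities = allcomm,
              config = config)
  if (!is.null(out_dir)) out$paths <- write_dataset(out, out_dir)
  out
}
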