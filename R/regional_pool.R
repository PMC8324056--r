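#' Regional taxon accumulation across all lakes
#'
#' Cumulative count of distinct taxa over all QC-passed samples of the
#' region, ordered from oldest to youngest. Variants excluding taxa with few
#' dataset-wide occurrences, or excluding named lakes, assess the
#' sensitivity of the trajectory to rare taxa and short records.
#'
#' @param taxa harmonized taxon table restricted to QC-passed samples.
#' @param ages data.frame `sample_id`, `age` (cal yr BP).
#' @param min_occurrences drop taxa observed in fewer than this many
#'   samples dataset-wide (default 1 = keep all).
#' @param exclude_lakes character vector of lake ids to drop.
#' @return data.frame `sample_id`, `age`, `accumulated`, ordered oldest
#'   first (ties broken by sample id).
#' @export
accumulate_regional <- function(taxa, ages, min_occurrences = 1,
                                exclude_lakes = character(0)) {
  taxa <- taxa[!(taxa$lake_id %in% exclude_lakes), , drop = FALSE]
  if (min_occurrences > 1) {
    occ <- table(unique(taxa[, c("sample_id", "taxon")])$taxon)
    keep <- names(occ)[occ >= min_occurrences]
    taxa <- taxa[taxa$taxon %in% keep, , drop = FALSE]
  }
  age <- ages$age[match(taxa$sample_id, ages$sample_id)]
  ord_samples <- unique(taxa$sample_id[order(-age, taxa$sample_id)])
  by_sample <- split(taxa$taxon, taxa$sample_id)
  curve <- accumulated_richness(ord_samples, by_sample)
  curve$age <- ages$age[match(curve$sample_id, ages$sample_id)]
  curve[, c("sample_id", "age", "accumulated")]
}

#' Growth rate of the regional pool over an age window
#'
#' Two summaries of an accumulation curve restricted to an age window:
#' the ordinary least-squares slope of log(cumulative count) on log(years
#' since the curve's first sample) (the scaling exponent of accumulation),
#' and the linear-scale rate in taxa per millennium over the window.
#'
#' @param curve output of [accumulate_regional()] (needs `age`,
#'   `accumulated`).
#' @param window age pair (old, young) in cal yr BP, inclusive.
#' @return list with `log_slope`, `taxa_per_millennium`, `n_points`.
#' @export
pool_growth_rate <- function(curve, window) {
  stopifnot(length(window) == 2)
  window <- sort(window, decreasing = TRUE)
  in_win <- curve$age <= window[1] & curve$age >= window[2]
  pts <- curve[in_win, , drop = FALSE]
  if (nrow(pts) < 3)
    stop_sedadiv("fewer than 3 accumulation points in the age window")
  elapsed <- max(curve$age) - pts$age   # years since the first sample
  ok <- elapsed > 0 & pts$accumulated > 0
  if (sum(ok) < 3) stop_sedadiv("window has too few log-definable points")
  fit <- lm(log(pts$accumulated[ok]) ~ log(elapsed[ok]))
  lin <- lm(pts$accumulated ~ I(-pts$age / 1000))
  list(log_slope = unname(coef(fit)[2]),
       taxa_per_millennium = unname(coef(lin)[2]),
       n_points = nrow(pts))
}

#' Beals smoothing: co-occurrence probabilities of taxa in samples
#'
#' For sample i and taxon j, the Beals probability is the mean, over the
#' taxa k present in i (excluding j itself), of the conditional frequency
#' M_jk / N_k, where M_jk counts samples holding both j and k and N_k
#' counts samples holding k:
#'
#'   b_ij = (1 / S_i') * sum_{k in i, k != j} M_jk / N_k
#'
#' with S_i' the number of taxa present in i excluding j. It estimates how
#' likely taxon j is to occur in sample i given the company i keeps, and
#' underlies the species-pool completion of [threshold_beal_pool()].
#'
#' @param x binary (or logical) sample-by-taxon presence matrix with at
#'   least 2 samples and 2 taxa.
#' @return matrix of the same shape with entries in \[0, 1\]; rows with no
#'   taxa give 0.
#' @export
beals_probabilities <- function(x) {
  x <- (as.matrix(x) > 0) + 0
  if (nrow(x) < 2 || ncol(x) < 2)
    stop_sedadiv("Beals smoothing needs >= 2 samples and >= 2 taxa")
  M <- crossprod(x)            # joint occurrences, M[j,j] = N_j
  N <- diag(M)
  C <- sweep(M, 2, pmax(N, 1), "/")  # C[j,k] = M_jk / N_k
  diag(C) <- 0                 # k = j never conditions
  S <- rowSums(x)
  raw <- x %*% t(C)            # sum over k present in i of M_jk/N_k
  denom <- matrix(S, nrow(x), ncol(x)) - x  # S_i' excludes j when present
  b <- ifelse(denom > 0, raw / denom, 0)
  dimnames(b) <- dimnames(x)
  b
}

#' Complete a time bin's species pool by probability thresholding
#'
#' Given Beals probabilities computed over the samples of one 500-year bin,
#' each taxon observed in the bin defines its own threshold: the minimum
#' Beals value among the bin's samples where it was observed. The taxon is
#' then marked present in every sample whose Beals value reaches that
#' threshold (observed occurrences are always kept; the threshold equals
#' their minimum, so completion only adds). Taxa never observed in the bin
#' have no threshold and are never added. The bin's estimated pool is the
#' union over samples of the completed matrix.
#'
#' @param x binary sample-by-taxon matrix of the bin's samples.
#' @param beals optional precomputed [beals_probabilities()] of `x`.
#' @return list with `completed` (binary matrix) and `pool` (character
#'   vector of taxa).
#' @export
threshold_beal_pool <- function(x, beals = NULL) {
  x <- (as.matrix(x) > 0) + 0
  if (is.null(beals)) beals <- beals_probabilities(x)
  completed <- x
  for (j in seq_len(ncol(x))) {
    obs <- x[, j] > 0
    if (!any(obs)) next
    thr <- min(beals[obs, j])
    completed[, j] <- as.integer(obs | beals[, j] >= thr)
  }
  pool <- colnames(x)[colSums(completed) > 0]
  list(completed = completed, pool = pool %||% character(0))
}

#' Assign samples to 500-year age bins
#'
#' Each sample goes to the nearest multiple of `width` years of its median
#' age; exact midpoints round toward the older bin.
#'
#' @param age ages in cal yr BP.
#' @param width bin width in years (default 500).
#' @return bin center ages (same units).
#' @export
bin_ages <- function(age, width = 500) {
  lower <- floor(age / width) * width
  off <- age - lower
  ifelse(off >= width / 2, lower + width, lower)
}

#' Standardized species-pool size of a bin
#'
#' Mean and SD of the accumulated taxon count over `n_resamples` random
#' subsamples of `size` samples drawn without replacement from the bin's
#' (completed) presence matrix. Standardizing to the minimum bin size
#' (5 samples) makes pool estimates comparable across unevenly sampled
#' bins.
#'
#' @param x binary sample-by-taxon matrix of the bin (typically the
#'   `completed` matrix of [threshold_beal_pool()]).
#' @param size subsample size (default 5).
#' @param n_resamples number of draws (default 1000).
#' @param seed RNG seed for the draws.
#' @return list with `mean`, `sd`, `n_samples`; NULL (with a warning) if
#'   the bin holds fewer than `size` samples.
#' @export
standardized_pool <- function(x, size = 5, n_resamples = 1000, seed = 1) {
  x <- (as.matrix(x) > 0) + 0
  if (nrow(x) < size) {
    warning("bin has fewer than ", size, " samples; excluded")
    return(NULL)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  counts <- vapply(seq_len(n_resamples), function(i) {
    rows <- sample.int(nrow(x), size)
    sum(colSums(x[rows, , drop = FALSE]) > 0)
  }, numeric(1))
  list(mean = mean(counts), sd = sd(counts), n_samples = nrow(x))
}

#' Time-binned regional species pool
#'
#' Full binned-pool workflow: assign QC-passed samples to 500-year bins,
#' complete each bin's presence matrix by Beals thresholding, and
#' standardize pool size by resampling `size` samples per bin. Bins with
#' fewer than `size` samples are dropped.
#'
#' @param taxa harmonized taxon table of QC-passed samples.
#' @param ages data.frame `sample_id`, `age`.
#' @param width bin width, years (default 500).
#' @param size,n_resamples standardization controls (defaults 5, 1000).
#' @param seed RNG seed; each bin uses an independent substream derived
#'   from it.
#' @return data.frame: `bin_age`, `n_samples`, `observed_pool`,
#'   `completed_pool`, `standardized_mean`, `standardized_sd`,
#'   `mean_richness` (mean per-sample taxon count in the bin).
#' @export
binned_species_pool <- function(taxa, ages, width = 500, size = 5,
                                n_resamples = 1000, seed = 1) {
  age <- ages$age[match(taxa$sample_id, ages$sample_id)]
  taxa$bin <- bin_ages(age, width)
  bins <- sort(unique(taxa$bin), decreasing = TRUE)
  rows <- list()
  for (b in bins) {
    tb <- taxa[taxa$bin == b, , drop = FALSE]
    samples <- sort(unique(tb$sample_id))
    taxa_b <- sort(unique(tb$taxon))
    x <- matrix(0L, length(samples), length(taxa_b),
                dimnames = list(samples, taxa_b))
    x[cbind(match(tb$sample_id, samples), match(tb$taxon, taxa_b))] <- 1L
    if (nrow(x) < size) next
    comp <- if (nrow(x) >= 2 && ncol(x) >= 2) threshold_beal_pool(x)
            else list(completed = x, pool = colnames(x))
    sp <- standardized_pool(comp$completed, size, n_resamples,
                            seed = seed + match(b, bins))
    rows[[length(rows) + 1L]] <- data.frame(
      bin_age = b, n_samples = length(samples),
      observed_pool = length(taxa_b),
      completed_pool = length(comp$pool),
      standardized_mean = sp$mean, standardized_sd = sp$sd,
      mean_richness = mean(rowSums(x)))
  }
  do.call(rbind, rows)
}

#' Pool trajectory and richness-pool regressions
#'
#' Two linear models over the binned pools: the standardized pool size
#' against bin age with a second-order polynomial term (compared with the
#' plain linear fit), and mean per-sample richness against standardized
#' pool size. Reports coefficients, adjusted R-squared, F and p for each.
#'
#' @param bins output of [binned_species_pool()].
#' @return list with elements `pool_vs_age_poly`, `pool_vs_age_linear`,
#'   `richness_vs_pool`, each a list of `coefficients`, `adj_r_squared`,
#'   `f_statistic`, `df`, `p_value`, and the underlying `lm` fit.
#' @export
fit_pool_models <- function(bins) {
  if (nrow(bins) < 4) stop_sedadiv("need >= 4 bins to fit pool models")
  age_ka <- bins$bin_age / 1000
  summ <- function(fit) {
    s <- summary(fit)
    f <- s$fstatistic
    list(coefficients = coef(fit), adj_r_squared = s$adj.r.squared,
         f_statistic = unname(f[1]), df = unname(f[2:3]),
         p_value = unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE)),
         fit = fit)
  }
  list(
    pool_vs_age_poly = summ(lm(bins$standardized_mean ~ stats::poly(age_ka, 2))),
    pool_vs_age_linear = summ(lm(bins$standardized_mean ~ age_ka)),
    richness_vs_pool = summ(lm(bins$mean_richness ~ bins$standardized_mean))
  )
}
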