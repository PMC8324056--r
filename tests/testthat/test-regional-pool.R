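test_that("regional accumulation reduces to one lake and matches the union oracle", {
  set.seed(131)
  taxa <- do.call(rbind, lapply(1:3, function(l)
    do.call(rbind, lapply(1:6, function(s) {
      tx <- sample(letters, sample(2:8, 1))
      data.frame(lake_id = paste0("L", l),
                 sample_id = sprintf("L%d_s%d", l, s), taxon = tx)
    }))))
  ages <- data.frame(sample_id = unique(taxa$sample_id),
                     age = seq(11000, 500,
                               length.out = length(unique(taxa$sample_id))))
  curve <- accumulate_regional(taxa, ages)
  expect_true(all(diff(curve$accumulated) >= 0))
  ord <- curve$sample_id
  oracle <- vapply(seq_along(ord), function(k)
    length(unique(taxa$taxon[taxa$sample_id %in% ord[seq_len(k)]])),
    integer(1))
  expect_equal(curve$accumulated, oracle)
  expect_equal(max(curve$accumulated), length(unique(taxa$taxon)))

  one <- accumulate_regional(taxa[taxa$lake_id == "L2", ], ages)
  expect_equal(max(one$accumulated),
               length(unique(taxa$taxon[taxa$lake_id == "L2"])))
  # variant curves never exceed the full curve
  v <- accumulate_regional(taxa, ages, min_occurrences = 3)
  expect_true(all(v$accumulated <=
                    curve$accumulated[match(v$sample_id, curve$sample_id)]))
})

test_that("rare-taxon exclusion lowers the final count by the excluded taxa", {
  taxa <- data.frame(
    lake_id = "L1",
    sample_id = rep(c("s1", "s2", "s3"), times = c(3, 2, 2)),
    taxon = c("a", "b", "c", "a", "b", "a", "d"))
  ages <- data.frame(sample_id = c("s1", "s2", "s3"), age = c(9000, 6000, 3000))
  full <- accumulate_regional(taxa, ages)
  # occurrences: a=3, b=2, c=1, d=1 -> dropping singletons removes c and d
  v <- accumulate_regional(taxa, ages, min_occurrences = 2)
  expect_equal(max(full$accumulated) - max(v$accumulated), 2)
})

test_that("pool growth rate recovers closed-form slopes", {
  age <- seq(11000, 1000, by = -250)
  t_since <- max(age) - age
  # exact power law: cumulative = (t/1000)^1.7 (log slope 1.7)
  curve <- data.frame(age = age, accumulated = pmax((t_since / 1000)^1.7, 1e-9))
  r <- pool_growth_rate(curve, c(10000, 1000))
  expect_equal(r$log_slope, 1.7, tolerance = 1e-6)
  # linear curve: 8 taxa per millennium
  lin <- data.frame(age = age, accumulated = 5 + 8 * t_since / 1000)
  expect_equal(pool_growth_rate(lin, c(10000, 2000))$taxa_per_millennium, 8,
               tolerance = 1e-8)
  # constant curve: zero rates
  flat <- data.frame(age = age, accumulated = rep(40, length(age)))
  r0 <- pool_growth_rate(flat, c(10000, 2000))
  expect_equal(r0$log_slope, 0, tolerance = 1e-9)
  expect_equal(r0$taxa_per_millennium, 0, tolerance = 1e-9)
  expect_error(pool_growth_rate(lin, c(400, 0)), "window")
})

test_that("noisy growth-rate fit equals an independent least-squares oracle", {
  set.seed(141)
  age <- seq(10000, 0, by = -100)
  acc <- round(pmax(cumsum(rpois(length(age), 2)), 1))
  curve <- data.frame(age = age, accumulated = acc)
  win <- c(8000, 2000)
  r <- pool_growth_rate(curve, win)
  pts <- curve[curve$age <= win[1] & curve$age >= win[2], ]
  el <- max(curve$age) - pts$age
  oracle <- cov(log(el), log(pts$accumulated)) / var(log(el))
  expect_equal(r$log_slope, oracle, tolerance = 1e-10)
})

test_that("Beals probabilities: degenerate co-occurrence patterns", {
  # two taxa always together -> probability 1 for each given the other
  x <- matrix(c(1, 1, 1, 1, 1, 1), nrow = 3,
              dimnames = list(paste0("s", 1:3), c("a", "b")))
  b <- beals_probabilities(x)
  expect_true(all(b == 1))
  # a taxon sharing no samples with the focal community scores 0
  y <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1))
  colnames(y) <- c("a", "b", "c"); rownames(y) <- paste0("s", 1:3)
  by <- beals_probabilities(y)
  expect_equal(by["s1", "c"], 0)
  expect_equal(by["s3", "a"], 0)
  expect_true(all(by >= 0 & by <= 1))
})

test_that("Beals matrix equals the triple-loop oracle, exhaustively to 4x4", {
  # every binary matrix up to 3 samples x 3 taxa, and a stratified sweep of
  # the 4x4 space via all matrices with a fixed random complement
  for (ns in 2:3) for (nt in 2:3) {
    cells <- ns * nt
    for (code in 0:(2^cells - 1)) {
      x <- matrix(as.integer(intToBits(code)[1:cells]), ns, nt)
      expect_equal(beals_probabilities(x), beals_oracle(x),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
  set.seed(151)
  for (rep in 1:300) {
    x <- matrix(rbinom(16, 1, runif(1, 0.2, 0.8)), 4, 4)
    expect_equal(beals_probabilities(x), beals_oracle(x),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # and the random 5x6 case
  for (rep in 1:20) {
    x <- matrix(rbinom(30, 1, 0.5), 5, 6)
    expect_equal(beals_probabilities(x), beals_oracle(x),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("Beals agrees with the vegan implementation", {
  set.seed(161)
  x <- matrix(rbinom(80, 1, 0.4), 8, 10,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:10)))
  got <- beals_probabilities(x)
  ref <- vegan::beals(x, type = 0, include = FALSE)
  ref[is.nan(ref)] <- 0
  expect_equal(got, ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("threshold completion only adds occurrences and keeps observed ones", {
  set.seed(171)
  x <- matrix(rbinom(35, 1, 0.5), 7, 5,
              dimnames = list(paste0("s", 1:7), paste0("t", 1:5)))
  x[, 1] <- 1                       # taxon observed everywhere: unchanged
  res <- threshold_beal_pool(x)
  expect_true(all(res$completed >= x))
  expect_equal(res$completed[, 1], x[, 1])
  # taxon absent from the whole bin is never added
  x2 <- cbind(x, never = 0)
  res2 <- threshold_beal_pool(x2)
  expect_true(all(res2$completed[, "never"] == 0))
  expect_false("never" %in% res2$pool)
  # pool superset of observed taxa
  expect_true(all(colnames(x)[colSums(x) > 0] %in% res$pool))
})

test_that("threshold completion matches exhaustive rule application on a toy bin", {
  x <- rbind(s1 = c(1, 1, 0), s2 = c(1, 0, 1), s3 = c(0, 1, 1))
  colnames(x) <- c("a", "b", "c")
  b <- beals_oracle(x)
  want <- x
  for (j in 1:3) {
    thr <- min(b[x[, j] > 0, j])
    want[, j] <- as.integer(x[, j] > 0 | b[, j] >= thr)
  }
  got <- threshold_beal_pool(x)
  expect_equal(got$completed, want)
})

test_that("sample binning rounds to the nearest 500 years, midpoints older", {
  expect_equal(bin_ages(c(0, 249, 250, 251, 499, 500, 750, 760)),
               c(0, 0, 500, 500, 500, 500, 1000, 1000))
  expect_equal(bin_ages(10250), 10500)   # exact midpoint -> older bin
})

test_that("standardized pool: degenerate draws, exhaustive mean, monotonicity", {
  x <- rbind(s1 = c(1, 1, 0, 0), s2 = c(0, 1, 1, 0), s3 = c(0, 0, 1, 1))
  # subsample size equal to bin size: no randomness
  full <- standardized_pool(x, size = 3, n_resamples = 50, seed = 5)
  expect_equal(full$mean, 4)
  expect_equal(full$sd, 0)
  # size 2: exhaustive average over the three pairs = (3 + 4 + 3) / 3
  two <- standardized_pool(x, size = 2, n_resamples = 4000, seed = 5)
  expect_equal(two$mean, 10 / 3, tolerance = 0.05)
  # determinism under a fixed seed
  again <- standardized_pool(x, size = 2, n_resamples = 4000, seed = 5)
  expect_identical(two, again)
  # monotone non-decreasing in subsample size
  one <- standardized_pool(x, size = 1, n_resamples = 4000, seed = 5)
  expect_lte(one$mean, two$mean)
  expect_lte(two$mean, full$mean)
  expect_warning(standardized_pool(x, size = 5), "fewer")
})

test_that("pool models recover known structure", {
  set.seed(181)
  bins <- data.frame(bin_age = seq(11000, 500, by = -500))
  age_ka <- bins$bin_age / 1000
  bins$n_samples <- 8
  bins$observed_pool <- bins$completed_pool <- 0
  # noiseless line: adjusted R^2 = 1
  bins$standardized_mean <- 200 - 12 * age_ka
  bins$mean_richness <- 5 + 0.2 * bins$standardized_mean
  fits <- suppressWarnings(fit_pool_models(bins))  # perfect fit is the point
  expect_equal(fits$pool_vs_age_linear$adj_r_squared, 1, tolerance = 1e-9)
  expect_equal(fits$richness_vs_pool$adj_r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(fits$richness_vs_pool$coefficients[2]), 0.2,
               tolerance = 1e-9)
  # quadratic + small noise: coefficients recovered within 95% CI
  beta <- c(180, -25, 1.4)
  bins$standardized_mean <- beta[1] + beta[2] * age_ka + beta[3] * age_ka^2 +
    rnorm(nrow(bins), 0, 2)
  fits2 <- fit_pool_models(bins)
  raw <- lm(bins$standardized_mean ~ age_ka + I(age_ka^2))
  ci <- confint(raw)
  expect_true(all(beta >= ci[, 1] & beta <= ci[, 2]))
  # the package's poly fit explains the same variance as the raw quadratic
  expect_equal(fits2$pool_vs_age_poly$adj_r_squared,
               summary(raw)$adj.r.squared, tolerance = 1e-12)
  expect_error(fit_pool_models(bins[1:3, ]), ">= 4 bins")
})

test_that("binned pools nest observed within completed and standardized below", {
  ds <- small_dataset()
  harm <- harmonize(ds$counts, ds$refdb)
  qc <- sample_qc(harm, ds$counts)
  keep <- qc$sample_id[qc$passed & qc$selected_extract &
                         qc$sample_type == "sample"]
  taxa <- harm$taxa[harm$taxa$sample_id %in% keep & harm$taxa$extract == 1, ]
  bins <- binned_species_pool(taxa, ds$samples, n_resamples = 100, seed = 3)
  expect_true(all(bins$completed_pool >= bins$observed_pool))
  expect_true(all(bins$standardized_mean <= bins$completed_pool + 1e-9))
  expect_true(all(bins$n_samples >= 5))
})
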