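#' Catchment nutrient index
#'
#' A bedrock-weathering surrogate for nutrient availability:
#' `NI = (P + K + ln(Ca)) / H_min`, where P, K and Ca are the phosphorus,
#' potassium and calcium content of the catchment bedrock and `H_min` is
#' the extended Mohs hardness of the most easily weathered principal
#' mineral. The log of Ca enters because Ca relates to pH, which controls
#' nutrient (especially P) availability; dividing by hardness makes the
#' index fall as the bedrock becomes harder to weather. A multiplicative
#' variant (`operator = "multiply"`) is kept for sensitivity analysis.
#'
#' @param P,K,Ca element content of the bedrock (consistent units; Ca > 0).
#' @param H_min extended Mohs hardness of the most weatherable principal
#'   mineral (> 0).
#' @param operator `"divide"` (default) or `"multiply"`.
#' @return the nutrient index (vectorized).
#' @export
#' @examples
#' nutrient_index(100, 50, exp(1), 1)  # 151
nutrient_index <- function(P, K, Ca, H_min, operator = c("divide", "multiply")) {
  operator <- match.arg(operator)
  if (any(Ca <= 0)) stop_sedadiv("Ca must be > 0 (log-defined)")
  if (any(H_min <= 0)) stop_sedadiv("H_min must be > 0")
  base <- P + K + log(Ca)
  if (operator == "divide") base / H_min else base * H_min
}

#' Assign climate-proxy values to sample ages
#'
#' Matches each sample to the nearest age of a proxy series (e.g. an
#' ice-core delta-18O record at 50-year resolution). Exact midpoints
#' resolve to the older grid point. Optionally flags (for exclusion)
#' samples whose assigned value falls below a floor, the convention used
#' when a few extreme cold excursions are left out of driver models.
#'
#' @param age sample ages, cal yr BP.
#' @param series data.frame `age`, `d18o` with strictly ordered ages.
#' @param exclude_below optional numeric: values strictly below it get
#'   `excluded = TRUE`.
#' @return data.frame `age`, `d18o`, `excluded`.
#' @export
assign_proxy <- function(age, series, exclude_below = NULL) {
  if (!nrow(series)) stop_sedadiv("empty proxy series")
  ser <- series[order(series$age), , drop = FALSE]
  if (min(age) < min(ser$age) || max(age) > max(ser$age))
    warning("some sample ages fall outside the proxy series; nearest endpoint used")
  idx <- vapply(age, function(a) {
    d <- abs(ser$age - a)
    cand <- which(d == min(d))
    cand[which.max(ser$age[cand])]  # tie -> older grid point
  }, integer(1))
  out <- data.frame(age = age, d18o = ser$d18o[idx])
  out$excluded <- if (is.null(exclude_below)) FALSE else out$d18o < exclude_below
  out
}

#' Holocene period of an age
#'
#' Early (11.7 to 8.3 ka), Middle (8.3 to 4.25 ka) and Late Holocene
#' (4.25 to 0 ka); boundary ages belong to the older period. Ages beyond
#' 11.7 ka are rejected (the analysis is Holocene-only).
#'
#' @param age ages in cal yr BP (0 to 11700).
#' @return factor with levels `Early`, `Middle`, `Late`.
#' @export
split_periods <- function(age) {
  if (any(age < 0 | age > 11700))
    stop_sedadiv("ages must lie within the Holocene (0..11700 cal yr BP)")
  p <- ifelse(age >= 8300, "Early", ifelse(age >= 4250, "Middle", "Late"))
  factor(p, levels = c("Early", "Middle", "Late"))
}

#' Smooth richness trend for one lake
#'
#' Penalized-spline Poisson GAM of richness on sample age, optionally with
#' continuous-time AR1 (CAR1) residual correlation estimated by
#' [mgcv::gamm()]. Fitted values with pointwise 95% confidence intervals
#' (t critical value) are returned at 300 evenly spaced ages across the
#' lake's record. Hill N1 responses should be rounded to integers before
#' fitting (Poisson family). On CAR1 non-convergence the plain GAM is
#' returned with `ar1_converged = FALSE`.
#'
#' @param richness non-negative integer richness per sample.
#' @param age sample ages, cal yr BP.
#' @param ar1 estimate a CAR1 residual process (default FALSE).
#' @param k basis dimension of the smooth; default `min(10, n/2)` rounded,
#'   at least 3.
#' @param n_pred number of prediction ages (default 300).
#' @return list: `fitted` (data.frame `age`, `fit`, `lower`, `upper`, on
#'   the response scale), `edf`, `adj_r_squared`, `phi` (CAR1 coefficient
#'   or NA), `ar1_converged`, `model`.
#' @export
# corCAR1 needs strictly distinct time points within a group; tied sample
# ages (integer-rounded) get a negligible deterministic offset.
dedup_ages <- function(age, group = rep(1L, length(age))) {
  out <- age
  for (g in unique(group)) {
    i <- which(group == g)
    d <- stats::ave(age[i], age[i], FUN = seq_along) - 1
    out[i] <- age[i] + d * 1e-4
  }
  out
}

fit_trend_gam <- function(richness, age, ar1 = FALSE, k = NULL, n_pred = 300) {
  stopifnot(length(richness) == length(age))
  if (length(age) < 8) stop_sedadiv("need >= 8 samples to fit a trend")
  dat <- data.frame(y = round(richness), age = age,
                    age_c = dedup_ages(age))
  if (is.null(k)) k <- max(3, min(10, floor(length(age) / 2)))
  phi <- NA_real_
  converged <- TRUE
  model <- NULL
  if (ar1) {
    model <- tryCatch(
      mgcv::gamm(y ~ s(age, k = k), data = dat, family = stats::poisson(),
                 correlation = nlme::corCAR1(form = ~age_c),
                 verbosePQL = FALSE),
      error = function(e) NULL)
    if (!is.null(model)) {
      cs <- model$lme$modelStruct$corStruct
      phi <- as.numeric(coef(cs, unconstrained = FALSE))
      gam_fit <- model$gam
    } else {
      converged <- FALSE
    }
  }
  if (!ar1 || !converged) {
    gam_fit <- mgcv::gam(y ~ s(age, k = k), data = dat,
                         family = stats::poisson(), method = "REML")
    model <- gam_fit
  }
  grid <- data.frame(age = seq(min(age), max(age), length.out = n_pred))
  pr <- predict(gam_fit, newdata = grid, type = "link", se.fit = TRUE)
  crit <- qt(0.975, df = sum(gam_fit$edf))
  fitted <- data.frame(age = grid$age,
                       fit = exp(pr$fit),
                       lower = exp(pr$fit - crit * pr$se.fit),
                       upper = exp(pr$fit + crit * pr$se.fit))
  s <- summary(gam_fit)
  list(fitted = fitted, edf = unname(s$edf[1]),
       adj_r_squared = s$r.sq, phi = phi,
       ar1_converged = converged, model = model)
}

#' Regional smooth richness trend with lake random effects
#'
#' One shared Poisson smooth of richness on age over all lakes, with
#' lake-level random intercepts, fitted with [mgcv::gamm()]; optionally a
#' CAR1 residual process (ordered within lake). Predictions are for the
#' population-level smooth.
#'
#' @param richness,age per-sample values across all lakes.
#' @param lake factor (or character) of lake ids.
#' @param ar1,k,n_pred as in [fit_trend_gam()].
#' @return as [fit_trend_gam()], plus `random_intercept_sd`.
#' @export
fit_regional_gamm <- function(richness, age, lake, ar1 = FALSE, k = NULL,
                              n_pred = 300) {
  lake <- factor(lake)
  if (nlevels(lake) < 2) {
    res <- fit_trend_gam(richness, age, ar1 = ar1, k = k, n_pred = n_pred)
    res$random_intercept_sd <- 0
    return(res)
  }
  dat <- data.frame(y = round(richness), age = age, lake = lake,
                    age_c = dedup_ages(age, lake))
  if (is.null(k)) k <- max(3, min(10, floor(length(age) / 4)))
  corr <- if (ar1) nlme::corCAR1(form = ~age_c | lake) else NULL
  model <- tryCatch(
    mgcv::gamm(y ~ s(age, k = k), data = dat, family = stats::poisson(),
               random = list(lake = ~1), correlation = corr,
               verbosePQL = FALSE),
    error = function(e) NULL)
  converged <- !is.null(model)
  phi <- NA_real_
  if (converged && ar1) {
    cs <- model$lme$modelStruct$corStruct
    phi <- as.numeric(coef(cs, unconstrained = FALSE))
  }
  if (!converged) {
    model <- mgcv::gamm(y ~ s(age, k = k), data = dat,
                        family = stats::poisson(),
                        random = list(lake = ~1), verbosePQL = FALSE)
  }
  gam_fit <- model$gam
  vc <- nlme::VarCorr(model$lme)
  re_sd <- suppressWarnings(
    as.numeric(vc[rownames(vc) == "(Intercept)", "StdDev"]))
  re_sd <- re_sd[is.finite(re_sd)]
  grid <- data.frame(age = seq(min(age), max(age), length.out = n_pred),
                     lake = levels(lake)[1])
  pr <- predict(gam_fit, newdata = grid, type = "link", se.fit = TRUE)
  crit <- qt(0.975, df = sum(gam_fit$edf))
  s <- summary(gam_fit)
  list(fitted = data.frame(age = grid$age, fit = exp(pr$fit),
                           lower = exp(pr$fit - crit * pr$se.fit),
                           upper = exp(pr$fit + crit * pr$se.fit)),
       edf = unname(s$edf[1]), adj_r_squared = s$r.sq, phi = phi,
       ar1_converged = converged,
       random_intercept_sd = if (length(re_sd)) re_sd[1] else NA_real_,
       model = model)
}

#' Mixed model of richness on climate and nutrient drivers
#'
#' Linear mixed-effects model of log richness with fixed effects
#' `period + d18o:period + ni:period` (period-specific climate-proxy and
#' nutrient-index slopes) and, per lake, a random intercept and a random
#' slope of sample age (different lakes change richness at different
#' rates). Sample age enters the random part in ka. If the full random
#' structure is singular or fails, the model is refitted without the
#' random age slope and flagged.
#'
#' Reported per-period slopes come from [emmeans::emtrends()];
#' interaction F tests from the Satterthwaite ANOVA of
#' \pkg{lmerTest}; and the fixed/random variance decomposition is the
#' standard marginal/conditional one (variance of the fixed-effect linear
#' predictor, summed random-effect variances, residual variance).
#'
#' @param drivers data.frame with columns `sample_id`, `lake_id`, `age`,
#'   `period`, `d18o`, `ni`, `richness` (Hill N0; log is taken internally),
#'   and optionally `excluded` (rows to drop, e.g. extreme proxy values).
#' @return list: `slopes_d18o`, `slopes_ni` (data.frames per period with
#'   `estimate`, `se`, `df`, `p_value`), `anova` (F tests), `var_fixed_pct`,
#'   `var_random_pct` (percent of response variance), `singular_refit`,
#'   `model`.
#' @export
fit_driver_lme <- function(drivers) {
  need <- c("lake_id", "age", "period", "d18o", "ni", "richness")
  stopifnot(all(need %in% names(drivers)))
  d <- drivers
  if ("excluded" %in% names(d)) d <- d[!d$excluded, , drop = FALSE]
  d <- d[d$richness > 0, , drop = FALSE]
  d$log_rich <- log(d$richness)
  d$age_ka <- d$age / 1000
  d$period <- factor(d$period, levels = c("Early", "Middle", "Late"))
  if (length(unique(d$lake_id)) < 3)
    stop_sedadiv("driver model needs >= 3 lakes")
  if (nlevels(droplevels(d$period)) < 3)
    stop_sedadiv("driver model needs samples from all three Holocene periods")
  if (length(unique(d$ni)) < 2)
    stop_sedadiv("nutrient index is constant across lakes; NI terms inestimable")

  form_full <- log_rich ~ period + d18o:period + ni:period + (1 + age_ka | lake_id)
  form_noslope <- log_rich ~ period + d18o:period + ni:period + (1 | lake_id)
  ctrl <- lme4::lmerControl(check.conv.singular = lme4::.makeCC("ignore", tol = 1e-4))
  fit <- tryCatch(lmerTest::lmer(form_full, data = d, REML = TRUE, control = ctrl),
                  error = function(e) NULL)
  singular_refit <- FALSE
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-4)) {
    fit2 <- tryCatch(lmerTest::lmer(form_noslope, data = d, REML = TRUE,
                                    control = ctrl),
                     error = function(e) NULL)
    if (!is.null(fit2)) {
      if (!is.null(fit)) singular_refit <- TRUE
      if (is.null(fit) || lme4::isSingular(fit, tol = 1e-4)) {
        fit <- fit2
        singular_refit <- TRUE
      }
    }
    if (is.null(fit)) stop_sedadiv("driver mixed model failed to fit")
  }

  trends <- function(var) {
    em <- emmeans::emtrends(fit, ~period, var = var,
                            lmer.df = "satterthwaite")
    s <- as.data.frame(summary(em, infer = c(TRUE, TRUE)))
    data.frame(period = s$period, estimate = s[[paste0(var, ".trend")]],
               se = s$SE, df = s$df, lower = s$lower.CL, upper = s$upper.CL,
               p_value = s$p.value, stringsAsFactors = FALSE)
  }
  an <- as.data.frame(anova(fit, type = 3))
  an$term <- rownames(an)

  # marginal / conditional variance decomposition
  X <- model.matrix(fit)
  var_f <- var(as.vector(X %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  Zt <- lme4::getME(fit, "Zt")
  var_r <- 0
  for (g in names(vc)) {
    Sg <- as.matrix(vc[[g]])
    vars_g <- attr(vc[[g]], "stddev")^2
    terms_g <- rownames(Sg)
    # mean over observations of z' Sigma z for this grouping factor
    cols <- lapply(terms_g, function(tm) {
      if (tm == "(Intercept)") rep(1, nrow(d)) else d[[tm]]
    })
    Z <- do.call(cbind, cols)
    var_r <- var_r + mean(rowSums((Z %*% Sg) * Z))
  }
  var_e <- attr(vc, "sc")^2
  tot <- var_f + var_r + var_e
  list(slopes_d18o = trends("d18o"), slopes_ni = trends("ni"),
       anova = an,
       var_fixed_pct = 100 * var_f / tot,
       var_random_pct = 100 * var_r / tot,
       singular_refit = singular_refit, model = fit)
}
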