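#' Fit a population-level thermal reaction norm
#'
#' Random-regression mixed model for one species x trait: the trait is a
#' linear function of temperature with correlated population-specific random
#' intercepts and slopes plus a replicate (chamber) random intercept.
#' Temperature is z-scaled internally (sample mean 0, SD 1 over the
#' observation rows); all slopes are also reported back-transformed to
#' per-degree-C units by dividing by the temperature SD.
#'
#' Gaussian traits use an identity link and a maximum-likelihood fit (not
#' REML, so AIC comparisons across random-effect structures share one
#' likelihood); germination uses a binomial error with a logit link and the
#' Laplace-approximate marginal likelihood. Population-level deviations are
#' conditional modes (BLUPs) given the fitted variance parameters.
#'
#' Degenerate inputs are handled explicitly: when the Gaussian residual
#' variance is numerically zero the exact per-population least-squares
#' solution is returned with all variance parameters at the boundary, and a
#' random term whose grouping factor has a single level is dropped (a
#' single-population fit therefore reproduces ordinary least squares). Both
#' cases set the `boundary` flag, as do singular variance estimates
#' (SD of the random slope estimated at 0).
#'
#' @param data data frame with columns `population`, `replicate`,
#'   `treatment_C`, and `value` (Gaussian) or `n_germinated` + `n_viable`
#'   (binomial).
#' @param family `"gaussian"` or `"binomial"`.
#' @param trait,species labels stored in the fit.
#' @return an object of class `"reaction_norm"` with `print`, `summary`,
#'   `coef`, `predict`, `plot`, `residuals`, and [plasticity()] methods.
#' @seealso [random_slope_support()] for the random-slope AIC test,
#'   [plasticity()] for absolute population slopes.
#' @export
fit_reaction_norm <- function(data, family = c("gaussian", "binomial"),
                              trait = NULL, species = NULL) {
  family <- match.arg(family)
  data <- .validate_norm_data(data, family)
  n_pop <- length(unique(data$population))
  if (length(unique(data$treatment_C)) < 2L) {
    .stopf("need >= 2 distinct treatment temperatures")
  }
  temp_mean <- mean(data$treatment_C)
  temp_sd <- stats::sd(data$treatment_C)
  data$ts <- (data$treatment_C - temp_mean) / temp_sd

  if (family == "gaussian" && .is_noiseless(data)) {
    fit <- .degenerate_gaussian_fit(data)
  } else {
    fit <- .fit_lme(data, family, random_slope = TRUE)
  }

  structure(c(fit, list(
    family = family, trait = trait, species = species,
    temp_mean = temp_mean, temp_sd = temp_sd,
    n_obs = nrow(data), n_pop = n_pop, data = data
  )), class = "reaction_norm")
}

.validate_norm_data <- function(data, family) {
  need <- c("population", "replicate", "treatment_C")
  need <- c(need, if (family == "gaussian") "value"
            else c("n_germinated", "n_viable"))
  miss <- setdiff(need, names(data))
  if (length(miss)) .stopf("missing columns: %s", paste(miss, collapse = ", "))
  if (length(unique(data$population)) < 1L) .stopf("no populations in data")
  if (family == "binomial") {
    if (any(data$n_viable <= 0)) .stopf("binomial rows need n_viable > 0")
    if (any(data$n_germinated > data$n_viable)) {
      .stopf("n_germinated exceeds n_viable")
    }
  }
  data$population <- factor(data$population)
  data$replicate <- factor(data$replicate)
  data
}

.is_noiseless <- function(data) {
  form <- if (nlevels(data$population) > 1L) value ~ ts * population
          else value ~ ts
  res <- stats::resid(stats::lm(form, data = data))
  stats::var(res) < 1e-12 * max(stats::var(data$value), 1e-300)
}

# Exact solution when residuals vanish: per-population least squares, all
# variance parameters at the boundary.
.degenerate_gaussian_fit <- function(data) {
  pops <- levels(data$population)
  co <- t(vapply(pops, function(p) {
    d <- data[data$population == p, ]
    stats::coef(stats::lm(value ~ ts, data = d))
  }, numeric(2L)))
  fix <- colMeans(co)
  ran <- data.frame(population = pops,
                    intercept_dev = co[, 1L] - fix[1L],
                    slope_dev = co[, 2L] - fix[2L],
                    row.names = NULL, stringsAsFactors = FALSE)
  list(model = NULL,
       fixef = c(intercept = unname(fix[1L]), slope = unname(fix[2L])),
       vcov_fixed = matrix(0, 2L, 2L,
                           dimnames = list(c("intercept", "slope"),
                                           c("intercept", "slope"))),
       ranef = ran,
       sd_intercept = if (nrow(ran) > 1L) stats::sd(ran$intercept_dev) else 0,
       sd_slope = if (nrow(ran) > 1L) stats::sd(ran$slope_dev) else 0,
       corr = NA_real_,
       sd_replicate = 0, sigma_resid = 0,
       logLik = NA_real_, aic = NA_real_,
       boundary = TRUE, degenerate = TRUE)
}

.fit_lme <- function(data, family, random_slope = TRUE) {
  pop_term <- if (nlevels(data$population) > 1L) {
    if (random_slope) "(1 + ts | population)" else "(1 | population)"
  } else NULL
  rep_term <- if (nlevels(data$replicate) > 1L) "(1 | replicate)" else NULL
  rhs <- paste(c("ts", pop_term, rep_term), collapse = " + ")
  lhs <- if (family == "gaussian") "value"
         else "cbind(n_germinated, n_viable - n_germinated)"
  form <- stats::as.formula(paste(lhs, "~", rhs))

  if (is.null(pop_term) && is.null(rep_term)) {
    return(.plain_glm_fit(form, data, family))
  }
  model <- withCallingHandlers(
    if (family == "gaussian") {
      lme4::lmer(form, data = data, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))
    } else {
      lme4::glmer(form, data = data, family = stats::binomial(),
                  control = lme4::glmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE))
    },
    warning = function(w) {
      if (grepl("converge|Model failed", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )

  vc <- lme4::VarCorr(model)
  fe <- lme4::fixef(model)
  fixef <- c(intercept = unname(fe[["(Intercept)"]]),
             slope = unname(fe[["ts"]]))
  V <- as.matrix(stats::vcov(model))
  dimnames(V) <- list(c("intercept", "slope"), c("intercept", "slope"))

  sd_int <- sd_slope <- corr <- 0
  if (!is.null(vc$population)) {
    sds <- attr(vc$population, "stddev")
    sd_int <- unname(sds[["(Intercept)"]])
    if (random_slope && "ts" %in% names(sds)) {
      sd_slope <- unname(sds[["ts"]])
      cc <- attr(vc$population, "correlation")
      corr <- if (sd_slope > 0 && sd_int > 0) cc["(Intercept)", "ts"] else NA_real_
    }
  }
  sd_rep <- if (!is.null(vc$replicate)) {
    unname(attr(vc$replicate, "stddev")[[1L]])
  } else 0
  sigma_resid <- if (family == "gaussian") stats::sigma(model) else NA_real_

  ran <- if (!is.null(vc$population)) {
    re <- lme4::ranef(model)$population
    data.frame(population = rownames(re),
               intercept_dev = re[["(Intercept)"]],
               slope_dev = if (random_slope && "ts" %in% colnames(re)) {
                 re[["ts"]]
               } else 0,
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(population = levels(data$population),
               intercept_dev = 0, slope_dev = 0, stringsAsFactors = FALSE)
  }

  list(model = model, fixef = fixef, vcov_fixed = V, ranef = ran,
       sd_intercept = sd_int, sd_slope = sd_slope, corr = corr,
       sd_replicate = sd_rep, sigma_resid = sigma_resid,
       logLik = as.numeric(stats::logLik(model)),
       aic = stats::AIC(model),
       boundary = lme4::isSingular(model) || (random_slope && sd_slope < 1e-8),
       degenerate = FALSE)
}

# Fixed-effects-only fallback (single population and single replicate).
.plain_glm_fit <- function(form, data, family) {
  model <- if (family == "gaussian") {
    stats::lm(form, data = data)
  } else {
    stats::glm(form, data = data, family = stats::binomial())
  }
  fe <- stats::coef(model)
  V <- stats::vcov(model)
  dimnames(V) <- list(c("intercept", "slope"), c("intercept", "slope"))
  list(model = model,
       fixef = c(intercept = unname(fe[[1L]]), slope = unname(fe[["ts"]])),
       vcov_fixed = V,
       ranef = data.frame(population = levels(data$population),
                          intercept_dev = 0, slope_dev = 0,
                          stringsAsFactors = FALSE),
       sd_intercept = 0, sd_slope = 0, corr = NA_real_, sd_replicate = 0,
       sigma_resid = if (family == "gaussian") {
         sqrt(sum(stats::resid(model)^2) / stats::nobs(model))
       } else NA_real_,
       logLik = as.numeric(stats::logLik(model)), aic = stats::AIC(model),
       boundary = TRUE, degenerate = FALSE)
}

#' AIC support for population-specific slopes
#'
#' Fits the random-regression model twice -- with population random
#' intercept and slope, and with random intercept only -- and returns
#' `delta_aic = AIC(intercept-only) - AIC(intercept + slope)`. Values above
#' the threshold (default 2) indicate support for the random-slope
#' component, i.e. for among-population variation in thermal response.
#'
#' @inheritParams fit_reaction_norm
#' @param threshold support threshold on the AIC difference.
#' @return list of class `"ranslope_support"`: `delta_aic`, `supported`,
#'   `aic_full`, `aic_intercept_only`.
#' @export
random_slope_support <- function(data, family = c("gaussian", "binomial"),
                                 threshold = 2) {
  family <- match.arg(family)
  data <- .validate_norm_data(data, family)
  if (nlevels(data$population) < 2L) {
    .stopf("random-slope support needs >= 2 populations")
  }
  data$ts <- .zscale(data$treatment_C)
  full <- .fit_lme(data, family, random_slope = TRUE)
  null <- .fit_lme(data, family, random_slope = FALSE)
  delta <- null$aic - full$aic
  structure(list(delta_aic = delta, supported = delta > threshold,
                 aic_full = full$aic, aic_intercept_only = null$aic,
                 threshold = threshold),
            class = "ranslope_support")
}

#' @export
print.ranslope_support <- function(x, ...) {
  cat(sprintf(
    "Random-slope support: dAIC = %.2f (intercept-only %.2f - full %.2f); %s\n",
    x$delta_aic, x$aic_intercept_only, x$aic_full,
    if (x$supported) sprintf("supported (dAIC > %g)", x$threshold)
    else "not supported"))
  invisible(x)
}

#' Population-specific plasticity from a fitted reaction norm
#'
#' The total slope of population *k* is the fixed slope plus its BLUP slope
#' deviation, back-transformed to per-degree-C units by dividing the
#' scaled-unit slope by the temperature SD; plasticity is its absolute
#' value.
#'
#' @param object a fitted model.
#' @param ... passed to methods.
#' @return data frame: `species`, `population`, `trait`, `slope_scaled`,
#'   `slope_per_C`, `plasticity` (units per degree C, >= 0).
#' @export
plasticity <- function(object, ...) UseMethod("plasticity")

#' @rdname plasticity
#' @export
plasticity.reaction_norm <- function(object, ...) {
  total_scaled <- object$fixef[["slope"]] + object$ranef$slope_dev
  per_c <- total_scaled / object$temp_sd
  data.frame(
    species = if (is.null(object$species)) NA_character_ else object$species,
    population = object$ranef$population,
    trait = if (is.null(object$trait)) NA_character_ else object$trait,
    slope_scaled = total_scaled,
    slope_per_C = per_c,
    plasticity = abs(per_c),
    stringsAsFactors = FALSE
  )
}

#' Logit-scale slope as percentage points per degree C
#'
#' Converts a logit-scale temperature slope into the change in probability
#' (in percentage points) for a +1 degree C step, evaluated at the
#' intercept: `100 * [p(eta0) - p(eta0 - slope)]` with
#' `p(eta) = exp(eta) / (1 + exp(eta))`. The sign of the slope is
#' preserved; the derivative form `100 * p(1-p) * slope` is the small-slope
#' approximation.
#'
#' @param intercept_logit linear predictor at the reference temperature
#'   (log-odds).
#' @param slope_logit_per_C slope in log-odds per degree C.
#' @return percentage points per degree C.
#' @export
logit_slope_to_percentage_points <- function(intercept_logit,
                                             slope_logit_per_C) {
  100 * (stats::plogis(intercept_logit) -
           stats::plogis(intercept_logit - slope_logit_per_C))
}

#' @export
coef.reaction_norm <- function(object, ...) {
  data.frame(
    population = object$ranef$population,
    intercept = object$fixef[["intercept"]] + object$ranef$intercept_dev,
    slope_scaled = object$fixef[["slope"]] + object$ranef$slope_dev,
    slope_per_C = (object$fixef[["slope"]] + object$ranef$slope_dev) /
      object$temp_sd,
    stringsAsFactors = FALSE
  )
}

#' Predict trait values along a temperature gradient
#'
#' Evaluates the fitted reaction norms at new temperatures, on the response
#' scale by default (the inverse logit is applied for binomial fits), with
#' confidence bands from the fixed-effect covariance (delta method on the
#' link scale).
#'
#' @param object a `"reaction_norm"`.
#' @param temperatures temperatures in degrees C.
#' @param population population ids (`NULL` = fixed effects only, `"all"` =
#'   every fitted population).
#' @param level confidence level of the bands.
#' @param type `"response"` or `"link"`.
#' @param ... unused.
#' @return data frame: `population`, `treatment_C`, `fit`, `lwr`, `upr`.
#' @export
predict.reaction_norm <- function(object, temperatures = NULL,
                                  population = NULL, level = 0.95,
                                  type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(temperatures)) {
    temperatures <- sort(unique(object$data$treatment_C))
  }
  rng <- range(object$data$treatment_C)
  span <- diff(rng)
  if (any(temperatures < rng[1L] - span | temperatures > rng[2L] + span)) {
    warning("predicting far outside the fitted temperature range",
            call. = FALSE)
  }
  ts <- (temperatures - object$temp_mean) / object$temp_sd
  pops <- if (is.null(population)) NA_character_
          else if (identical(population, "all")) object$ranef$population
          else population
  out <- do.call(rbind, lapply(pops, function(p) {
    if (is.na(p)) {
      di <- ds <- 0
    } else {
      i <- match(p, object$ranef$population)
      if (is.na(i)) .stopf("unknown population `%s`", p)
      di <- object$ranef$intercept_dev[i]
      ds <- object$ranef$slope_dev[i]
    }
    eta <- (object$fixef[["intercept"]] + di) +
      (object$fixef[["slope"]] + ds) * ts
    X <- cbind(1, ts)
    se <- sqrt(rowSums((X %*% object$vcov_fixed) * X))
    z <- stats::qnorm(1 - (1 - level) / 2)
    data.frame(population = p, treatment_C = temperatures,
               fit = eta, lwr = eta - z * se, upr = eta + z * se,
               stringsAsFactors = FALSE)
  }))
  if (type == "response" && object$family == "binomial") {
    out$fit <- stats::plogis(out$fit)
    out$lwr <- stats::plogis(out$lwr)
    out$upr <- stats::plogis(out$upr)
  }
  out
}

#' @export
residuals.reaction_norm <- function(object, ...) {
  if (is.null(object$model)) {
    co <- coef(object)
    i <- match(object$data$population, co$population)
    object$data$value - (co$intercept[i] + co$slope_scaled[i] * object$data$ts)
  } else {
    stats::resid(object$model, ...)
  }
}

#' @export
print.reaction_norm <- function(x, ...) {
  cat(sprintf("Thermal reaction norm (%s)%s\n", x$family,
              if (isTRUE(x$boundary)) " [boundary fit]" else ""))
  if (!is.null(x$species) || !is.null(x$trait)) {
    cat(sprintf("  %s / %s\n", x$species, x$trait))
  }
  cat(sprintf("  %d obs, %d populations; temperature SD %.3f C\n",
              x$n_obs, x$n_pop, x$temp_sd))
  cat(sprintf("  fixed: intercept %.4g, slope %.4g per scaled unit (%.4g per C)\n",
              x$fixef[["intercept"]], x$fixef[["slope"]],
              x$fixef[["slope"]] / x$temp_sd))
  cat(sprintf("  random: SD(intercept) %.4g, SD(slope) %.4g, corr %.3g; SD(replicate) %.4g\n",
              x$sd_intercept, x$sd_slope, x$corr, x$sd_replicate))
  if (!is.na(x$aic)) cat(sprintf("  AIC %.2f\n", x$aic))
  invisible(x)
}

#' @export
summary.reaction_norm <- function(object, ...) {
  est <- object$fixef
  se <- sqrt(diag(object$vcov_fixed))
  zval <- ifelse(se > 0, est / se, NA_real_)
  pval <- 2 * stats::pnorm(-abs(zval))
  coefs <- data.frame(
    term = c("(Intercept)", "temperature"),
    estimate_scaled = unname(est), se_scaled = unname(se),
    estimate_per_C = unname(est) / c(1, object$temp_sd),
    se_per_C = unname(se) / c(1, object$temp_sd),
    statistic = unname(zval), p_value = unname(pval),
    stringsAsFactors = FALSE
  )
  pl <- plasticity(object)
  structure(list(
    coefficients = coefs,
    sd_pop_per_C = stats::sd(pl$slope_per_C),
    min_pop_per_C = min(pl$slope_per_C),
    max_pop_per_C = max(pl$slope_per_C),
    sd_intercept = object$sd_intercept,
    sd_slope_per_C = object$sd_slope / object$temp_sd,
    corr = object$corr, sd_replicate = object$sd_replicate,
    sigma_resid = object$sigma_resid, aic = object$aic,
    family = object$family, species = object$species, trait = object$trait,
    boundary = object$boundary, n_obs = object$n_obs, n_pop = object$n_pop
  ), class = "summary.reaction_norm")
}

#' @export
print.summary.reaction_norm <- function(x, ...) {
  cat(sprintf("Thermal reaction norm summary (%s%s)\n", x$family,
              if (isTRUE(x$boundary)) ", boundary" else ""))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf(
    "population slopes per C: SD %.4g, min %.4g, max %.4g (%d populations)\n",
    x$sd_pop_per_C, x$min_pop_per_C, x$max_pop_per_C, x$n_pop))
  invisible(x)
}

#' @export
plot.reaction_norm <- function(x, n_grid = 50, ...) {
  temps <- seq(min(x$data$treatment_C), max(x$data$treatment_C),
               length.out = n_grid)
  pred <- predict(x, temps, population = "all")
  ylab <- if (is.null(x$trait)) "trait value" else x$trait
  pops <- unique(pred$population)
  cols <- grDevices::hcl.colors(length(pops), "Dark 3")
  graphics::plot(NA, xlim = range(temps), ylim = range(pred$fit),
                 xlab = "temperature (C)", ylab = ylab, ...)
  for (i in seq_along(pops)) {
    d <- pred[pred$population == pops[i], ]
    graphics::lines(d$treatment_C, d$fit, col = cols[i])
  }
  invisible(x)
}

#' Table of reaction-norm estimates across species and traits
#'
#' Collects per-degree-C fixed-effect estimates, population-slope spread,
#' and the random-slope AIC support into one table (one row per fitted
#' term), mirroring the usual reporting layout for random-regression
#' analyses.
#'
#' @param fits list of `"reaction_norm"` objects.
#' @param supports optional list of `"ranslope_support"` objects aligned
#'   with `fits`.
#' @return data frame with columns `species`, `trait`, `term`, `estimate`,
#'   `se`, `statistic`, `p_value`, `sd_pop`, `min_pop`, `max_pop`,
#'   `delta_aic`.
#' @export
reaction_norm_table <- function(fits, supports = NULL) {
  rows <- lapply(seq_along(fits), function(i) {
    s <- summary(fits[[i]])
    co <- s$coefficients
    data.frame(
      species = if (is.null(s$species)) NA_character_ else s$species,
      trait = if (is.null(s$trait)) NA_character_ else s$trait,
      term = co$term,
      estimate = co$estimate_per_C, se = co$se_per_C,
      statistic = co$statistic, p_value = co$p_value,
      sd_pop = c(NA, s$sd_pop_per_C),
      min_pop = c(NA, s$min_pop_per_C),
      max_pop = c(NA, s$max_pop_per_C),
      delta_aic = c(NA, if (is.null(supports)) NA_real_
                    else supports[[i]]$delta_aic),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
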