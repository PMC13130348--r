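#' Assemble the plasticity driver table
#'
#' Joins per-population plasticity values with the five site metrics and
#' freshly z-scales every metric column across the included populations
#' (re-scaling after any row exclusion, so the scaled columns always have
#' mean 0 and SD 1 on the rows actually analysed).
#'
#' @param plasticity data frame from [plasticity()] (columns `population`,
#'   `plasticity`; `species`/`trait` carried through when present).
#' @param metrics data frame with `population` and the metric columns
#'   (default `dre`, `dce`, `shdi`, `par`, `are`).
#' @param metric_cols names of the metric columns to scale.
#' @return joined data frame with z-scaled metric columns.
#' @export
assemble_driver_table <- function(plasticity, metrics,
                                  metric_cols = c("dre", "dce", "shdi",
                                                  "par", "are")) {
  miss_col <- setdiff(metric_cols, names(metrics))
  if (length(miss_col)) {
    .stopf("metrics table lacks column(s): %s", paste(miss_col, collapse = ", "))
  }
  unmatched <- setdiff(plasticity$population, metrics$population)
  if (length(unmatched)) {
    .stopf("no site metrics for population(s): %s",
           paste(unmatched, collapse = ", "))
  }
  i <- match(plasticity$population, metrics$population)
  out <- cbind(plasticity, metrics[i, metric_cols, drop = FALSE])
  rownames(out) <- NULL
  if (anyNA(out[metric_cols]) || anyNA(out$plasticity)) {
    bad <- out$population[!stats::complete.cases(out[c("plasticity", metric_cols)])]
    .stopf("missing metric or plasticity values for: %s",
           paste(bad, collapse = ", "))
  }
  for (m in metric_cols) out[[m]] <- .zscale(out[[m]], m)
  out
}

#' Enumerate the candidate driver models
#'
#' All combinations of one range-position metric, one environmental-
#' heterogeneity metric, with and without their interaction; each candidate
#' has at most two main effects plus optionally their product. Two RP and
#' three EH metrics give the 12-model grid.
#'
#' @param rp_set range-position metric names.
#' @param eh_set environmental-heterogeneity metric names.
#' @return data frame: `rp`, `eh`, `interaction`, `formula`.
#' @export
enumerate_candidate_models <- function(rp_set = c("dre", "dce"),
                                       eh_set = c("shdi", "par", "are")) {
  if (!length(rp_set) || !length(eh_set)) {
    .stopf("`rp_set` and `eh_set` must be non-empty")
  }
  grid <- expand.grid(interaction = c(FALSE, TRUE), eh = eh_set, rp = rp_set,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("rp", "eh", "interaction")]
  grid$formula <- ifelse(
    grid$interaction,
    sprintf("plasticity ~ %s * %s", grid$eh, grid$rp),
    sprintf("plasticity ~ %s + %s", grid$eh, grid$rp)
  )
  rownames(grid) <- NULL
  grid
}

#' Fit and AIC-rank the candidate driver models
#'
#' Fits each candidate by ordinary least squares, ranks by AIC (Gaussian
#' log-likelihood with the residual variance counted as a parameter),
#' selects the lowest-AIC model (ties broken by fewest parameters), and
#' lists competitors within `delta_aic_threshold` as additional supported
#' models. LMG variance shares are computed for the selected model.
#'
#' @param table a driver table from [assemble_driver_table()] (or any data
#'   frame with a `plasticity` column and the metric columns).
#' @param rp_set,eh_set metric names passed to
#'   [enumerate_candidate_models()].
#' @param delta_aic_threshold support window above the best AIC (default 2).
#' @return object of class `"driver_scan"`: `grid` (one row per candidate
#'   with AIC, delta AIC, R2), `fits` (the `lm` objects), `selected` (index
#'   into `grid`), `supported` (indices with delta AIC <= threshold),
#'   `lmg` (shares for the selected model), `table`.
#' @export
fit_plasticity_drivers <- function(table, rp_set = c("dre", "dce"),
                                   eh_set = c("shdi", "par", "are"),
                                   delta_aic_threshold = 2) {
  specs <- enumerate_candidate_models(rp_set, eh_set)
  max_par <- 4L  # intercept + 2 mains + interaction
  if (nrow(table) <= max_par + 2L) {
    .stopf("need more rows (%d) than parameters + 2", nrow(table))
  }
  fits <- lapply(specs$formula, function(f) {
    fit <- stats::lm(stats::as.formula(f), data = table)
    if (fit$rank < length(stats::coef(fit))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      .stopf("rank-deficient design in `%s` (collinear: %s)", f,
             paste(bad, collapse = ", "))
    }
    fit
  })
  specs$n_par <- vapply(fits, function(f) length(stats::coef(f)), integer(1L))
  specs$aic <- vapply(fits, stats::AIC, numeric(1L))
  specs$delta_aic <- specs$aic - min(specs$aic)
  specs$r_squared <- vapply(fits, function(f) summary(f)$r.squared,
                            numeric(1L))
  ord <- order(specs$aic, specs$n_par)
  selected <- ord[1L]
  supported <- setdiff(which(specs$delta_aic <= delta_aic_threshold), selected)
  structure(list(grid = specs, fits = fits, selected = selected,
                 supported = supported,
                 lmg = lmg_importance(fits[[selected]]),
                 delta_aic_threshold = delta_aic_threshold,
                 table = table),
            class = "driver_scan")
}

#' LMG relative importance of regressors
#'
#' Decomposes the R-squared of a linear model over its regressor columns:
#' each column receives the average, over all orderings of the columns, of
#' its sequential increment to R-squared when added in that order (the
#' interaction column, when present, is treated as an ordinary regressor).
#' Shares are non-negative and sum to the full-model R-squared; the
#' unexplained share is `1 - R2`.
#'
#' Computed over all regressor subsets with the standard order-count
#' weights `|S|! (t - 1 - |S|)! / t!`, equivalent to full permutation
#' enumeration but needing `2^t` rather than `t!` fits.
#'
#' @param object a fitted `lm`, or a model matrix of regressors (no
#'   intercept column).
#' @param y response vector (ignored for `lm` input).
#' @return list of class `"lmg"`: `shares` (named, one per regressor),
#'   `r_squared`, `unexplained`.
#' @export
lmg_importance <- function(object, y = NULL) {
  if (inherits(object, "lm")) {
    X <- stats::model.matrix(object)
    keep <- colnames(X) != "(Intercept)"
    X <- X[, keep, drop = FALSE]
    y <- stats::model.response(stats::model.frame(object))
  } else {
    X <- as.matrix(object)
    if (is.null(y)) .stopf("`y` required when `object` is a matrix")
  }
  t_reg <- ncol(X)
  if (t_reg < 1L) .stopf("need at least one regressor")
  if (t_reg > 10L) {
    .stopf(paste("refusing LMG with %d regressors (subset enumeration grows",
                 "as 2^t); reduce the model"), t_reg)
  }
  yc <- y - mean(y)
  tss <- sum(yc^2)
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    fit <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    1 - sum(fit$residuals^2) / tss
  }
  n_sub <- 2L^t_reg
  r2_sub <- numeric(n_sub)
  members <- vector("list", n_sub)
  for (mask in 0:(n_sub - 1L)) {
    cols <- which(bitwAnd(mask, 2L^(seq_len(t_reg) - 1L)) > 0L)
    members[[mask + 1L]] <- cols
    r2_sub[mask + 1L] <- r2(cols)
  }
  w <- function(s) factorial(s) * factorial(t_reg - 1L - s) / factorial(t_reg)
  shares <- numeric(t_reg)
  for (j in seq_len(t_reg)) {
    bit <- 2L^(j - 1L)
    for (mask in 0:(n_sub - 1L)) {
      if (bitwAnd(mask, bit) > 0L) next
      s <- length(members[[mask + 1L]])
      shares[j] <- shares[j] +
        w(s) * (r2_sub[mask + bit + 1L] - r2_sub[mask + 1L])
    }
  }
  names(shares) <- colnames(X)
  full <- r2_sub[n_sub]
  structure(list(shares = shares, r_squared = full, unexplained = 1 - full),
            class = "lmg")
}

#' @export
print.lmg <- function(x, ...) {
  cat("LMG variance shares (of total variance):\n")
  print(round(x$shares, 4))
  cat(sprintf("R2 = %.4f, unexplained = %.4f\n", x$r_squared, x$unexplained))
  invisible(x)
}

#' Spearman correlation screen of explanatory metrics
#'
#' Pairwise Spearman rank correlations among the metric columns, flagging
#' pairs at or above the multicollinearity threshold.
#'
#' @param metrics data frame of site metrics.
#' @param metric_cols columns to screen.
#' @param threshold absolute-correlation flag level (default 0.7).
#' @return list: `rho` (correlation matrix), `flagged` (data frame of
#'   flagged pairs).
#' @export
correlation_screen <- function(metrics,
                               metric_cols = c("dre", "dce", "shdi", "par",
                                               "are"),
                               threshold = 0.7) {
  m <- as.matrix(metrics[intersect(metric_cols, names(metrics))])
  if (nrow(m) < 3L) .stopf("need >= 3 populations")
  const <- colnames(m)[apply(m, 2L, stats::sd) == 0]
  if (length(const)) {
    .stopf("correlation undefined for constant column(s): %s",
           paste(const, collapse = ", "))
  }
  rho <- stats::cor(m, method = "spearman")
  pairs <- which(upper.tri(rho) & abs(rho) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(
    var1 = colnames(rho)[pairs[, 1L]],
    var2 = colnames(rho)[pairs[, 2L]],
    rho = rho[pairs],
    stringsAsFactors = FALSE
  )
  list(rho = rho, flagged = flagged)
}

#' @export
print.driver_scan <- function(x, ...) {
  sel <- x$grid[x$selected, ]
  cat(sprintf("Driver-model AIC scan: %d candidates over %d populations\n",
              nrow(x$grid), nrow(x$table)))
  cat(sprintf("selected: %s (AIC %.2f, R2 %.3f)\n",
              sel$formula, sel$aic, sel$r_squared))
  if (length(x$supported)) {
    cat(sprintf("additional supported models (dAIC <= %g): %s\n",
                x$delta_aic_threshold,
                paste(x$grid$formula[x$supported], collapse = "; ")))
  }
  invisible(x)
}

#' @export
coef.driver_scan <- function(object, ...) {
  stats::coef(object$fits[[object$selected]])
}

#' @export
summary.driver_scan <- function(object, ...) {
  fit <- object$fits[[object$selected]]
  s <- summary(fit)
  co <- as.data.frame(s$coefficients)
  names(co) <- c("estimate", "se", "statistic", "p_value")
  co$term <- rownames(co)
  rownames(co) <- NULL
  co$signif <- cut(co$p_value, c(0, 0.01, 0.05, 0.1, 1),
                   labels = c("< 0.01", "< 0.05", "< 0.1", ""),
                   include.lowest = TRUE)
  structure(list(
    grid = object$grid[order(object$grid$aic), ],
    selected = object$grid[object$selected, ],
    coefficients = co[, c("term", "estimate", "se", "statistic", "p_value",
                          "signif")],
    lmg = object$lmg,
    n = nrow(object$table)
  ), class = "summary.driver_scan")
}

#' @export
print.summary.driver_scan <- function(x, ...) {
  cat(sprintf("Selected driver model (n = %d): %s\n", x$n,
              x$selected$formula))
  print(x$coefficients, row.names = FALSE, digits = 4)
  print(x$lmg)
  cat("\nAIC ranking:\n")
  print(x$grid[, c("rp", "eh", "interaction", "aic", "delta_aic",
                   "r_squared")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.driver_scan <- function(x, ...) {
  shares <- c(x$lmg$shares, unexplained = x$lmg$unexplained)
  graphics::barplot(matrix(shares, ncol = 1L),
                    col = c(grDevices::hcl.colors(length(x$lmg$shares),
                                                  "Viridis"), "grey85"),
                    legend.text = names(shares),
                    ylab = "share of total variance in plasticity",
                    ylim = c(0, 1), ...)
  invisible(x)
}

#' Variance-partition table for one or more driver scans
#'
#' One row per model term plus the unexplained component, shares of total
#' variance; rows of each scan sum to 1.
#'
#' @param scans a `"driver_scan"` or a named list of them (names used as
#'   trait labels).
#' @return data frame: `trait`, `term`, `share`.
#' @export
variance_partition <- function(scans) {
  if (inherits(scans, "driver_scan")) scans <- list(trait = scans)
  rows <- lapply(names(scans), function(nm) {
    l <- scans[[nm]]$lmg
    data.frame(trait = nm,
               term = c(names(l$shares), "unexplained"),
               share = c(unname(l$shares), l$unexplained),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
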