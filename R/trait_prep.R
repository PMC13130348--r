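#' Viable seeds from a cut-test record
#'
#' Viability excludes only empty and infested seeds: germinated, full, and
#' moldy seeds all count as viable.
#'
#' @param records data frame with non-negative integer columns
#'   `n_germinated`, `n_full`, `n_empty`, `n_moldy`, `n_infested` (one row
#'   per dish).
#' @return integer vector of viable counts per dish.
#' @export
count_viable_seeds <- function(records) {
  need <- c("n_germinated", "n_full", "n_empty", "n_moldy", "n_infested")
  miss <- setdiff(need, names(records))
  if (length(miss)) .stopf("missing columns: %s", paste(miss, collapse = ", "))
  counts <- records[need]
  if (any(as.matrix(counts) < 0)) .stopf("cut-test counts must be >= 0")
  total <- rowSums(counts)
  as.integer(total - records$n_empty - records$n_infested)
}

#' Dish-level germination proportion
#'
#' @param germinated,viable integer vectors (per dish).
#' @return numeric proportions in `[0, 1]`.
#' @export
germination_proportion <- function(germinated, viable) {
  if (any(viable == 0)) {
    .stopf("germination proportion undefined for dishes with 0 viable seeds")
  }
  if (any(germinated > viable)) .stopf("germinated counts exceed viable seeds")
  germinated / viable
}

#' Germination phenology from weekly census counts
#'
#' Expands weekly germination tallies over a 4-week monitoring period into
#' per-seed day values; the day assigned to a seed is its census day
#' (`census_days` after sowing). Seeds that never germinated contribute no
#' rows.
#'
#' @param weekly matrix or data frame with one column per census
#'   (dishes in rows).
#' @param census_days day of each census after sowing.
#' @return numeric vector of per-seed germination days.
#' @export
germination_phenology <- function(weekly, census_days = c(7, 14, 21, 28)) {
  weekly <- as.matrix(weekly)
  if (ncol(weekly) != length(census_days)) {
    .stopf("`weekly` needs one column per census day")
  }
  if (any(weekly < 0)) .stopf("weekly counts must be >= 0")
  rep(rep(census_days, nrow(weekly)), as.vector(t(weekly)))
}

#' Population inclusion filter on pooled germination
#'
#' A population is retained only when its pooled germination proportion
#' (total germinated over total viable, across dishes) is strictly greater
#' than the threshold; exactly 5% is excluded.
#'
#' @param records data frame with columns `population`, `n_germinated`,
#'   `n_viable`.
#' @param threshold minimum pooled proportion (default 0.05).
#' @param per_treatment if `TRUE`, apply the rule within each level of a
#'   `treatment_C` column and keep a population only when every treatment
#'   passes.
#' @return data frame: `population`, `proportion` (pooled), `included`.
#' @export
apply_germination_filter <- function(records, threshold = 0.05,
                                     per_treatment = FALSE) {
  need <- c("population", "n_germinated", "n_viable")
  miss <- setdiff(need, names(records))
  if (length(miss)) .stopf("missing columns: %s", paste(miss, collapse = ", "))
  key <- if (per_treatment) {
    interaction(records$population, records$treatment_C, drop = TRUE)
  } else {
    factor(records$population)
  }
  germ <- tapply(records$n_germinated, key, sum)
  viab <- tapply(records$n_viable, key, sum)
  prop <- as.numeric(germ) / as.numeric(viab)
  if (per_treatment) {
    pop <- sub("\\..*$", "", names(germ))
    ok <- tapply(prop > threshold, pop, all)
    pooled_g <- tapply(records$n_germinated, records$population, sum)
    pooled_v <- tapply(records$n_viable, records$population, sum)
    out <- data.frame(population = names(pooled_g),
                      proportion = as.numeric(pooled_g) / as.numeric(pooled_v),
                      included = as.logical(ok[names(pooled_g)]),
                      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(population = names(germ), proportion = prop,
                      included = prop > threshold,
                      row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}

#' Prepare the analysis trait table
#'
#' Applies the analysis transforms to a validated long trait table:
#' flower-abundance values are square-root transformed, and a z-scaled
#' temperature column (`temp_scaled`, sample mean 0 and SD 1 over the
#' observation rows of each species x trait subset) is added alongside the
#' original degrees-C column so per-degree back-transformation stays
#' possible (`temp_mean`, `temp_sd` columns record the scaling).
#'
#' @param observations data frame with columns `species`, `population`,
#'   `replicate`, `treatment_C`, `trait`, `value` (plus `n_viable`,
#'   `n_germinated` for germination rows).
#' @param sqrt_traits trait names to square-root transform.
#' @return the prepared data frame.
#' @export
prepare_trait_table <- function(observations,
                                sqrt_traits = "flower_abundance") {
  need <- c("species", "population", "replicate", "treatment_C", "trait",
            "value")
  miss <- setdiff(need, names(observations))
  if (length(miss)) .stopf("missing columns: %s", paste(miss, collapse = ", "))
  out <- observations
  to_sqrt <- out$trait %in% sqrt_traits
  if (any(to_sqrt)) {
    if (any(out$value[to_sqrt] < 0, na.rm = TRUE)) {
      .stopf("negative counts in square-root-transformed trait(s)")
    }
    out$value[to_sqrt] <- sqrt(out$value[to_sqrt])
  }
  grp <- interaction(out$species, out$trait, drop = TRUE)
  out$temp_mean <- stats::ave(out$treatment_C, grp, FUN = mean)
  out$temp_sd <- stats::ave(out$treatment_C, grp, FUN = stats::sd)
  if (any(!is.finite(out$temp_sd) | out$temp_sd == 0)) {
    .stopf("temperature has zero variance in at least one species x trait subset")
  }
  out$temp_scaled <- (out$treatment_C - out$temp_mean) / out$temp_sd
  out
}
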