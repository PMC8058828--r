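# Synthetic generator for plausible German-like stratum inputs.

#' Specification for the synthetic stratum generator
#'
#' Controls the ranges and qualitative structure of the generated 12-stratum
#' input table. The generator stands in for national survey intake data and
#' registry incidence data, reproducing their qualitative structure (males
#' consume more sugar than females; consumption is highest in adolescence,
#' declines through midlife, and shows a small uptick in the oldest band so
#' that women aged 51-64 are the lowest-consuming stratum) without claiming
#' any actual survey value.
#'
#' @param seed integer seed; generation is fully deterministic given it.
#' @param sugar_range `(min, max)` g/day bounds within which every stratum
#'   mean intake must fall.
#' @param male_excess multiplicative male/female intake ratio within each age
#'   band (> 1).
#' @param age_gradient positive length-6 profile across the age bands; only
#'   its ranks are used: uniform draws are sorted and assigned so that the
#'   within-sex intake ordering follows the profile's ranks. The default
#'   declines with age with a small uptick in the oldest band.
#' @param incidence_range `(min, max)` annual caries incidence probabilities,
#'   a subset of `[0, 1]`.
#' @param population_scale persons per stratum in the reference population.
#' @return A validated list of class `fopfl_synth_spec`.
#' @export
synthetic_spec <- function(seed = 2017,
                           sugar_range = c(40, 110),
                           male_excess = 1.25,
                           age_gradient = c(1.00, 0.93, 0.86, 0.78, 0.66, 0.70),
                           incidence_range = c(0.08, 0.30),
                           population_scale = 1e6) {
  out <- list(seed = as.integer(seed),
              sugar_range = as.numeric(sugar_range),
              male_excess = as.numeric(male_excess),
              age_gradient = as.numeric(age_gradient),
              incidence_range = as.numeric(incidence_range),
              population_scale = as.numeric(population_scale))
  class(out) <- "fopfl_synth_spec"
  if (length(out$sugar_range) != 2 || out$sugar_range[1] <= 0 ||
      out$sugar_range[1] >= out$sugar_range[2])
    stop("sugar_range must be an ordered positive (min, max) pair")
  if (!is.finite(out$male_excess) || out$male_excess <= 1)
    stop("male_excess must be > 1")
  if (out$sugar_range[2] / out$male_excess <= out$sugar_range[1])
    stop("sugar_range too narrow for male_excess: need max/male_excess > min")
  if (length(out$age_gradient) != 6 || any(out$age_gradient <= 0))
    stop("age_gradient must be 6 positive factors")
  if (length(out$incidence_range) != 2 ||
      out$incidence_range[1] < 0 || out$incidence_range[2] > 1 ||
      out$incidence_range[1] >= out$incidence_range[2])
    stop("incidence_range must be an ordered pair within [0,1]")
  if (!is.finite(out$population_scale) || out$population_scale < 1)
    stop("population_scale must be >= 1")
  out
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic 12-stratum input table
#'
#' Female intakes are drawn uniformly in
#' `[min, max / male_excess]`, sorted, and assigned to age bands following
#' the rank order of `age_gradient`; male intakes are the female intake of
#' the same band times `male_excess`. This guarantees, by construction:
#' containment of every intake in `sugar_range`, male > female within every
#' band, intake declining over the first five age bands within each sex, and
#' the global maximum / minimum falling in males 15-18 / females 51-64 (the
#' structure observed in German consumption data). Incidences are drawn
#' uniformly in `incidence_range`; population is `population_scale` in every
#' stratum.
#'
#' @param spec a [synthetic_spec()].
#' @return A 12-row strata table (see [strata_table()]).
#' @export
synthetic_strata <- function(spec) {
  if (!inherits(spec, "fopfl_synth_spec")) spec <- do.call(synthetic_spec, spec)
  with_seed(spec$seed, {
    lo <- spec$sugar_range[1]
    hi <- spec$sugar_range[2] / spec$male_excess
    draws <- sort(stats::runif(6, lo, hi), decreasing = TRUE)
    band_rank <- order(spec$age_gradient, decreasing = TRUE)
    female <- numeric(6)
    female[band_rank] <- draws
    male <- female * spec$male_excess
    incidence <- stats::runif(12, spec$incidence_range[1],
                              spec$incidence_range[2])
    strata_table(
      sex = rep(SEXES, each = 6),
      age_band = rep(AGE_BANDS, 2),
      sugar_intake = c(male, female),
      incidence = incidence,
      population = rep(spec$population_scale, 12)
    )
  })
}

#' Strata with the highest and lowest sugar consumption
#'
#' Returns the two strata used for the probabilistic sensitivity analysis:
#' the stratum with maximal and the stratum with minimal mean sugar intake.
#' Ties are broken by canonical order (males first, age ascending): the
#' maximum takes the first tied stratum, the minimum the last, so a
#' degenerate all-equal table yields the first and last stratum.
#'
#' @param config a `fopfl_config`.
#' @return A list with elements `max` and `min`, each a one-row strata table.
#' @export
extreme_strata <- function(config) {
  validate_config(config)
  df <- config$strata  # already canonical order
  i_max <- which(df$sugar_intake == max(df$sugar_intake))[1]
  ties_min <- which(df$sugar_intake == min(df$sugar_intake))
  i_min <- ties_min[length(ties_min)]
  list(max = df[i_max, , drop = FALSE], min = df[i_min, , drop = FALSE])
}
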