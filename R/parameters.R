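# Parameter containers, validation, config file I/O, canonical defaults.

#' Age bands used throughout the model
#'
#' The six age bands of the stratified adult population (years of age at
#' baseline). Together with the two sexes they define the 12 strata of the
#' model.
#'
#' @format Character vector of length 6.
#' @export
AGE_BANDS <- c("15-18", "19-24", "25-34", "35-50", "51-64", "65-80")

#' @rdname AGE_BANDS
#' @format NULL
#' @export
SEXES <- c("male", "female")

# Canonical stratum ordering: male first, then female, age ascending within sex.
canonical_grid <- function() {
  data.frame(
    sex = rep(SEXES, each = length(AGE_BANDS)),
    age_band = rep(AGE_BANDS, times = length(SEXES)),
    stringsAsFactors = FALSE
  )
}

stratum_key <- function(sex, age_band) {
  grid <- canonical_grid()
  match(paste(sex, age_band), paste(grid$sex, grid$age_band))
}

stratum_id <- function(sex, age_band) paste(sex, age_band)

#' Build the per-stratum input table
#'
#' Assembles and validates the 12-row table of stratum-level inputs: mean
#' added-sugar intake (g/person/day), annual probability of developing at
#' least one new caries lesion, and the reference population size.
#'
#' @param sex character, `"male"` or `"female"`.
#' @param age_band character, one of [AGE_BANDS].
#' @param sugar_intake numeric, grams of added sugar per person per day (> 0).
#' @param incidence numeric, annual probability in `[0, 1]` of developing one
#'   or more new caries lesions.
#' @param population non-negative integer, persons in the reference
#'   population for this stratum.
#' @return A `data.frame` with one row per stratum, in canonical order
#'   (males first, age ascending).
#' @export
strata_table <- function(sex, age_band, sugar_intake, incidence, population) {
  df <- data.frame(
    sex = as.character(sex), age_band = as.character(age_band),
    sugar_intake = as.numeric(sugar_intake),
    incidence = as.numeric(incidence),
    population = as.numeric(population),
    stringsAsFactors = FALSE
  )
  validate_strata(df)
  df[order(match(df$sex, SEXES), match(df$age_band, AGE_BANDS)), , drop = FALSE]
}

validate_strata <- function(df) {
  needed <- c("sex", "age_band", "sugar_intake", "incidence", "population")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("strata table is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(df) != 12)
    stop("expected 12 strata (2 sexes x 6 age bands), got ", nrow(df))
  if (!all(df$sex %in% SEXES))
    stop("sex must be one of: ", paste(SEXES, collapse = ", "))
  if (!all(df$age_band %in% AGE_BANDS))
    stop("age_band must be one of: ", paste(AGE_BANDS, collapse = ", "))
  if (anyDuplicated(paste(df$sex, df$age_band)))
    stop("each (sex, age_band) combination must appear exactly once")
  if (!all(is.finite(df$sugar_intake)) || any(df$sugar_intake <= 0))
    stop("sugar_intake must be > 0")
  if (!all(is.finite(df$incidence)) || any(df$incidence < 0 | df$incidence > 1))
    stop("incidence must be in [0,1]")
  if (!all(is.finite(df$population)) || any(df$population < 0) ||
      any(df$population != floor(df$population)))
    stop("population must be a non-negative integer")
  invisible(df)
}

#' Economic valuation parameters
#'
#' Unit treatment cost, discount rate, GDP per capita used to value DALYs as
#' productivity losses, and the three components of the per-lesion DALY
#' weight. The per-lesion DALY is the product
#' `p_symptomatic * duration * disability_weight`.
#'
#' @param unit_cost euro cost of one single-surface restoration; default
#'   74.10. See [unit_cost_presets] for alternative treatment-cost scenarios.
#' @param discount_rate annual discount rate applied to both costs and health
#'   outcomes; default 0.03.
#' @param gdp_per_capita euros of annual GDP per capita used to monetise one
#'   DALY (Commission on Macroeconomics and Health approach); default 40332.
#' @param daly list with elements `p_symptomatic` (fraction of lesions that
#'   become symptomatic with severe pain, in `[0,1]`), `duration` (years
#'   symptomatic per lesion, > 0) and `disability_weight` (GBD-style severity
#'   weight in `[0,1]`).
#' @return A validated list of class `fopfl_economics`.
#' @export
economic_params <- function(unit_cost = 74.10, discount_rate = 0.03,
                            gdp_per_capita = 40332,
                            daly = list(p_symptomatic = 0.28583,
                                        duration = 0.1,
                                        disability_weight = 0.010)) {
  out <- list(unit_cost = as.numeric(unit_cost),
              discount_rate = as.numeric(discount_rate),
              gdp_per_capita = as.numeric(gdp_per_capita),
              daly = lapply(daly, as.numeric))
  class(out) <- "fopfl_economics"
  validate_economics(out)
  out
}

validate_economics <- function(e) {
  if (!is.finite(e$unit_cost) || e$unit_cost <= 0)
    stop("unit_cost must be > 0")
  if (!is.finite(e$discount_rate) || e$discount_rate < 0)
    stop("discount_rate must be >= 0")
  if (!is.finite(e$gdp_per_capita) || e$gdp_per_capita <= 0)
    stop("gdp_per_capita must be > 0")
  d <- e$daly
  needed <- c("p_symptomatic", "duration", "disability_weight")
  if (!all(needed %in% names(d)))
    stop("daly must have components: ", paste(needed, collapse = ", "))
  if (d$p_symptomatic < 0 || d$p_symptomatic > 1)
    stop("p_symptomatic must be in [0,1]")
  if (d$disability_weight < 0 || d$disability_weight > 1)
    stop("disability_weight must be in [0,1]")
  if (d$duration <= 0) stop("duration must be > 0")
  dpl <- d$p_symptomatic * d$duration * d$disability_weight
  if (dpl <= 0 || dpl >= 1)
    stop("per-lesion DALY (product of daly components) must be in (0,1)")
  invisible(e)
}

#' Per-lesion DALY weight implied by the economic parameters
#'
#' @param economics an [economic_params()] object.
#' @return `p_symptomatic * duration * disability_weight`.
#' @export
daly_per_lesion <- function(economics) {
  d <- economics$daly
  d$p_symptomatic * d$duration * d$disability_weight
}

#' Alternative unit-cost scenarios
#'
#' Named unit costs (euro per lesion treated) for the base case and the two
#' higher-cost scenarios: additional patient copayments, and restoration
#' failures with their consequences. The scenario values are derived from
#' published scenario cost totals divided by the published total lesion
#' count, and are therefore derived constants rather than tariff values.
#'
#' @format Named numeric vector.
#' @export
unit_cost_presets <- c(base = 74.10, copayment = 118.11,
                       restoration_failure = 148.73)

#' Labeling-intervention parameters
#'
#' @param effect_fraction fractional reduction in added-sugar consumption
#'   attributable to front-of-package labeling; default 0.066 (meta-analytic
#'   point estimate), with deterministic sensitivity bounds 0.044 and 0.088.
#' @param sugar_caries_slope reduction in annual caries incidence probability
#'   per g/day of sugar intake reduction (>= 0); default 0.002.
#' @param dose_response `"absolute"` (default) subtracts
#'   `slope * delta_sugar` from the incidence probability; `"relative"`
#'   multiplies it by `1 - slope * delta_sugar`. Both are clamped to
#'   `[0, baseline]`.
#' @return A validated list of class `fopfl_intervention`.
#' @export
intervention_params <- function(effect_fraction = 0.066,
                                sugar_caries_slope = 0.002,
                                dose_response = c("absolute", "relative")) {
  out <- list(effect_fraction = as.numeric(effect_fraction),
              sugar_caries_slope = as.numeric(sugar_caries_slope),
              dose_response = match.arg(dose_response))
  class(out) <- "fopfl_intervention"
  validate_intervention(out)
  out
}

validate_intervention <- function(iv) {
  if (!is.finite(iv$effect_fraction) ||
      iv$effect_fraction < 0 || iv$effect_fraction > 1)
    stop("effect_fraction must be in [0,1]")
  if (!is.finite(iv$sugar_caries_slope) || iv$sugar_caries_slope < 0)
    stop("sugar_caries_slope must be >= 0")
  if (!iv$dose_response %in% c("absolute", "relative"))
    stop("dose_response must be 'absolute' or 'relative'")
  invisible(iv)
}

#' Simulation controls
#'
#' @param horizon number of yearly cycles simulated; default 10.
#' @param n_individuals persons simulated per stratum and scenario;
#'   default 500000.
#' @param seed master random seed; all simulation streams are derived from it
#'   deterministically.
#' @param common_random_numbers when `TRUE` (default) the baseline and
#'   labeling scenarios reuse the same uniform draws per individual-year, so
#'   incremental lesion counts are non-negative run by run.
#' @return A validated list of class `fopfl_controls`.
#' @export
sim_controls <- function(horizon = 10, n_individuals = 500000, seed = 1,
                         common_random_numbers = TRUE) {
  out <- list(horizon = as.integer(horizon),
              n_individuals = as.integer(n_individuals),
              seed = as.integer(seed),
              common_random_numbers = isTRUE(common_random_numbers))
  class(out) <- "fopfl_controls"
  validate_controls(out)
  out
}

validate_controls <- function(ct) {
  if (is.na(ct$horizon) || ct$horizon < 1) stop("horizon must be >= 1")
  if (is.na(ct$n_individuals) || ct$n_individuals < 1)
    stop("n_individuals must be >= 1")
  if (is.na(ct$seed)) stop("seed must be an integer")
  invisible(ct)
}

#' Full model configuration
#'
#' Container for everything a model run needs: the 12-stratum input table,
#' economic valuation parameters, intervention parameters, simulation
#' controls, and an optional pass-through implementation-cost range (euro)
#' reported alongside results but never entering the simulation.
#'
#' @param strata a 12-row strata table, see [strata_table()].
#' @param economics see [economic_params()].
#' @param intervention see [intervention_params()].
#' @param controls see [sim_controls()].
#' @param implementation_cost_range optional numeric length-2 `(low, high)`
#'   euro range for policy implementation costs.
#' @return A validated object of class `fopfl_config`.
#' @export
model_config <- function(strata, economics = economic_params(),
                         intervention = intervention_params(),
                         controls = sim_controls(),
                         implementation_cost_range = NULL) {
  out <- list(strata = strata, economics = economics,
              intervention = intervention, controls = controls,
              implementation_cost_range = implementation_cost_range)
  class(out) <- "fopfl_config"
  validate_config(out)
  out
}

#' Validate a model configuration
#'
#' Checks every invariant of the configuration (stratum completeness and
#' bounds, economic and intervention parameter domains, controls). Called by
#' all constructors and by [read_config()]; exported so that programmatically
#' assembled configurations can be checked too.
#'
#' @param config a `fopfl_config` object.
#' @return The config, invisibly; stops with a message naming the offending
#'   field otherwise.
#' @export
validate_config <- function(config) {
  validate_strata(config$strata)
  validate_economics(config$economics)
  validate_intervention(config$intervention)
  validate_controls(config$controls)
  icr <- config$implementation_cost_range
  if (!is.null(icr)) {
    if (length(icr) != 2 || !all(is.finite(icr)) || any(icr < 0) ||
        icr[1] > icr[2])
      stop("implementation_cost_range must be an ordered non-negative (low, high) pair")
  }
  invisible(config)
}

#' @export
print.fopfl_config <- function(x, ...) {
  cat("Model configuration (", nrow(x$strata), " strata)\n", sep = "")
  cat(sprintf("  unit cost: EUR %.2f | discount rate: %.1f%% | GDP/capita: EUR %s\n",
              x$economics$unit_cost, 100 * x$economics$discount_rate,
              format(x$economics$gdp_per_capita, big.mark = ",")))
  cat(sprintf("  per-lesion DALY: %.4e\n", daly_per_lesion(x$economics)))
  cat(sprintf("  labeling effect: %.1f%% sugar reduction | slope: %g per g/day (%s)\n",
              100 * x$intervention$effect_fraction,
              x$intervention$sugar_caries_slope, x$intervention$dose_response))
  cat(sprintf("  horizon: %d y | %s individuals/stratum | seed %d | CRN %s\n",
              x$controls$horizon,
              format(x$controls$n_individuals, big.mark = ","),
              x$controls$seed,
              if (x$controls$common_random_numbers) "on" else "off"))
  if (!is.null(x$implementation_cost_range))
    cat(sprintf("  implementation cost (pass-through): EUR %.2fM-%.2fM\n",
                x$implementation_cost_range[1] / 1e6,
                x$implementation_cost_range[2] / 1e6))
  print(utils::head(x$strata, 3), row.names = FALSE)
  cat("  ... (", nrow(x$strata) - 3, " more strata)\n", sep = "")
  invisible(x)
}

#' Packaged default configuration
#'
#' The canonical German-like parameter set: unit cost EUR 74.10, 3% annual
#' discount rate, 6.6% labeling effect, 10-year horizon, per-lesion DALY
#' components whose product is 2.8583e-4, GDP per capita EUR 40,332, and a
#' synthetic stratum table generated with a fixed seed (2017) so defaults are
#' identical across sessions. Stratum-level intakes, incidences and
#' populations are synthetic stand-ins with the documented qualitative
#' structure, not survey values.
#'
#' @param seed seed for the synthetic stratum table; fixed by default so that
#'   `default_config()` is reproducible.
#' @return A `fopfl_config`.
#' @export
default_config <- function(seed = 2017) {
  model_config(
    strata = synthetic_strata(synthetic_spec(seed = seed)),
    economics = economic_params(),
    intervention = intervention_params(),
    controls = sim_controls(),
    implementation_cost_range = c(5.29e6, 9.56e6)
  )
}

config_field_names <- list(
  top = c("strata", "economics", "intervention", "controls",
          "implementation_cost_range"),
  stratum = c("sex", "age_band", "sugar_intake", "incidence", "population"),
  economics = c("unit_cost", "discount_rate", "gdp_per_capita", "daly"),
  daly = c("p_symptomatic", "duration", "disability_weight"),
  intervention = c("effect_fraction", "sugar_caries_slope", "dose_response"),
  controls = c("horizon", "n_individuals", "seed", "common_random_numbers")
)

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0)
    stop("unknown key(s) in ", where, ": ", paste(unknown, collapse = ", "))
}

#' Read a model configuration from a YAML file
#'
#' The file is a YAML mapping with keys `strata` (a sequence of 12 mappings
#' with keys `sex`, `age_band`, `sugar_intake`, `incidence`, `population`),
#' `economics`, `intervention`, `controls`, and optionally
#' `implementation_cost_range`. Any key absent from the schema is an error
#' (catching typos); any missing optional field is filled with the documented
#' default. All invariants are checked before the config is returned.
#'
#' @param path path to the YAML file.
#' @return A validated `fopfl_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("config parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (!is.list(raw)) stop("config file must be a YAML mapping")
  check_keys(raw, config_field_names$top, "config")
  if (is.null(raw$strata)) stop("config must contain 'strata'")
  for (s in raw$strata) check_keys(s, config_field_names$stratum, "stratum")
  strata <- do.call(rbind, lapply(raw$strata, function(s) {
    for (f in config_field_names$stratum)
      if (is.null(s[[f]])) stop("stratum entry missing field: ", f)
    data.frame(sex = s$sex, age_band = s$age_band,
               sugar_intake = s$sugar_intake, incidence = s$incidence,
               population = s$population, stringsAsFactors = FALSE)
  }))

  eco <- raw$economics %||% list()
  check_keys(eco, config_field_names$economics, "economics")
  if (!is.null(eco$daly)) check_keys(eco$daly, config_field_names$daly, "daly")
  defaults <- economic_params()
  economics <- economic_params(
    unit_cost = eco$unit_cost %||% defaults$unit_cost,
    discount_rate = eco$discount_rate %||% defaults$discount_rate,
    gdp_per_capita = eco$gdp_per_capita %||% defaults$gdp_per_capita,
    daly = utils::modifyList(defaults$daly, eco$daly %||% list())
  )

  iv <- raw$intervention %||% list()
  check_keys(iv, config_field_names$intervention, "intervention")
  dflt_iv <- intervention_params()
  intervention <- intervention_params(
    effect_fraction = iv$effect_fraction %||% dflt_iv$effect_fraction,
    sugar_caries_slope = iv$sugar_caries_slope %||% dflt_iv$sugar_caries_slope,
    dose_response = iv$dose_response %||% dflt_iv$dose_response
  )

  ct <- raw$controls %||% list()
  check_keys(ct, config_field_names$controls, "controls")
  dflt_ct <- sim_controls()
  controls <- sim_controls(
    horizon = ct$horizon %||% dflt_ct$horizon,
    n_individuals = ct$n_individuals %||% dflt_ct$n_individuals,
    seed = ct$seed %||% dflt_ct$seed,
    common_random_numbers = ct$common_random_numbers %||%
      dflt_ct$common_random_numbers
  )

  model_config(strata = strata_table(strata$sex, strata$age_band,
                                     strata$sugar_intake, strata$incidence,
                                     strata$population),
               economics = economics, intervention = intervention,
               controls = controls,
               implementation_cost_range = raw$implementation_cost_range)
}

#' Write a model configuration to a YAML file
#'
#' Inverse of [read_config()]: numeric fields are written with 17 significant
#' digits so that a write-then-read round trip reproduces every field
#' exactly.
#'
#' @param config a `fopfl_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  strata <- lapply(seq_len(nrow(config$strata)), function(i) {
    s <- config$strata[i, ]
    list(sex = s$sex, age_band = s$age_band, sugar_intake = s$sugar_intake,
         incidence = s$incidence, population = s$population)
  })
  doc <- list(
    strata = strata,
    economics = list(unit_cost = config$economics$unit_cost,
                     discount_rate = config$economics$discount_rate,
                     gdp_per_capita = config$economics$gdp_per_capita,
                     daly = config$economics$daly),
    intervention = list(
      effect_fraction = config$intervention$effect_fraction,
      sugar_caries_slope = config$intervention$sugar_caries_slope,
      dose_response = config$intervention$dose_response),
    controls = list(horizon = config$controls$horizon,
                    n_individuals = config$controls$n_individuals,
                    seed = config$controls$seed,
                    common_random_numbers = config$controls$common_random_numbers)
  )
  if (!is.null(config$implementation_cost_range))
    doc$implementation_cost_range <- as.numeric(config$implementation_cost_range)
  writeLines(yaml::as.yaml(doc, precision = 17), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
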