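# Valuation of lesion trajectories: treatment costs, DALYs, productivity
# losses; discounting and population scaling; incremental (baseline minus
# labeling) results.

#' Present-value discount factor
#'
#' Year 1 is undiscounted (standard convention in health-economic
#' evaluations); year `y` is discounted by `(1 + rate)^-(y - 1)`.
#'
#' @param year 1-based cycle index (>= 1). Vectorised.
#' @param rate annual discount rate (>= 0).
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(year, rate) {
  if (any(year < 1)) stop("year must be >= 1")
  if (any(rate < 0)) stop("rate must be >= 0")
  (1 + rate)^(-(year - 1))
}

#' Discounted treatment costs of a lesion trajectory
#'
#' Each lesion incurs one single-surface restoration in the year it occurs.
#'
#' @param lesions_by_year numeric vector of new-lesion counts, years
#'   `1..horizon`.
#' @param unit_cost euro cost per restoration (> 0).
#' @param rate annual discount rate.
#' @return Total discounted cost in euros.
#' @export
treatment_costs <- function(lesions_by_year, unit_cost, rate = 0) {
  if (unit_cost <= 0) stop("unit_cost must be > 0")
  y <- seq_along(lesions_by_year)
  sum(lesions_by_year * unit_cost * discount_factor(y, rate))
}

#' Discounted DALYs of a lesion trajectory
#'
#' Each lesion contributes `p_symptomatic * duration * disability_weight`
#' DALYs (years lived with disability from severe caries pain) in the year
#' it occurs.
#'
#' @param lesions_by_year numeric vector of new-lesion counts.
#' @param daly_params list with `p_symptomatic`, `duration`,
#'   `disability_weight` (see [economic_params()]).
#' @param rate annual discount rate.
#' @return Total discounted DALYs.
#' @export
dalys_averted <- function(lesions_by_year, daly_params, rate = 0) {
  dpl <- daly_params$p_symptomatic * daly_params$duration *
    daly_params$disability_weight
  y <- seq_along(lesions_by_year)
  sum(lesions_by_year * dpl * discount_factor(y, rate))
}

#' Productivity losses valued from DALYs
#'
#' Commission on Macroeconomics and Health approach: one DALY is valued at
#' one year of GDP per capita.
#'
#' @param dalys DALY total.
#' @param gdp_per_capita euros per DALY (> 0).
#' @return Euros.
#' @export
productivity_loss_avoided <- function(dalys, gdp_per_capita) {
  if (any(gdp_per_capita <= 0)) stop("gdp_per_capita must be > 0")
  dalys * gdp_per_capita
}

#' Scale a simulated per-cohort total to the reference population
#'
#' @param per_simulated_total outcome total among the simulated individuals.
#' @param n_individuals number simulated (> 0).
#' @param population reference population of the stratum.
#' @return `per_simulated_total * population / n_individuals`.
#' @export
scale_to_population <- function(per_simulated_total, n_individuals,
                                population) {
  if (any(n_individuals <= 0)) stop("n_individuals must be > 0")
  per_simulated_total * population / n_individuals
}

incremental_columns <- c(
  "stratum", "lesions_prevented", "costs_avoided_eur", "dalys_averted",
  "productivity_avoided_eur", "lesions_prevented_disc",
  "costs_avoided_disc_eur", "dalys_averted_disc",
  "productivity_avoided_disc_eur"
)

#' Incremental (baseline minus labeling) outcomes for one stratum
#'
#' Differences in yearly lesion counts are population-scaled and fed through
#' the three valuations, in both undiscounted and discounted form. The
#' headline `lesions_prevented` is undiscounted, and undiscounted costs
#' satisfy `costs_avoided_eur == lesions_prevented * unit_cost` exactly by
#' construction; the discounted variants apply [discount_factor()] with the
#' configured rate to every outcome including the lesion count itself.
#'
#' @param baseline,intervention `fopfl_scenario` results for the same
#'   stratum and horizon.
#' @param stratum the one-row strata table both scenarios were simulated
#'   from (supplies the population size).
#' @param economics an [economic_params()].
#' @return One-row `data.frame` with columns `stratum`,
#'   `lesions_prevented`, `costs_avoided_eur`, `dalys_averted`,
#'   `productivity_avoided_eur` and the four `_disc` discounted variants.
#' @export
incremental <- function(baseline, intervention, stratum, economics) {
  if (baseline$stratum_id != intervention$stratum_id)
    stop("baseline and intervention are from different strata")
  if (length(baseline$lesions_by_year) != length(intervention$lesions_by_year))
    stop("horizon mismatch between baseline and intervention")
  if (baseline$n_individuals != intervention$n_individuals)
    stop("n_individuals mismatch between baseline and intervention")
  diff_y <- as.numeric(baseline$lesions_by_year -
                       intervention$lesions_by_year)
  scale <- stratum$population / baseline$n_individuals
  df <- discount_factor(seq_along(diff_y), economics$discount_rate)
  dpl <- daly_per_lesion(economics)

  lesions <- sum(diff_y) * scale
  lesions_disc <- sum(diff_y * df) * scale
  costs <- lesions * economics$unit_cost  # exact identity, undiscounted
  costs_disc <- lesions_disc * economics$unit_cost
  dalys <- lesions * dpl
  dalys_disc <- lesions_disc * dpl
  prod_ <- dalys * economics$gdp_per_capita
  prod_disc <- dalys_disc * economics$gdp_per_capita

  data.frame(
    stratum = baseline$stratum_id,
    lesions_prevented = lesions,
    costs_avoided_eur = costs,
    dalys_averted = dalys,
    productivity_avoided_eur = prod_,
    lesions_prevented_disc = lesions_disc,
    costs_avoided_disc_eur = costs_disc,
    dalys_averted_disc = dalys_disc,
    productivity_avoided_disc_eur = prod_disc,
    stringsAsFactors = FALSE
  )
}

# Total row: exact column sums over the stratum rows.
total_row <- function(results) {
  tot <- results[1, , drop = FALSE]
  tot$stratum <- "total"
  for (col in setdiff(incremental_columns, "stratum"))
    tot[[col]] <- sum(results[[col]])
  tot
}
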