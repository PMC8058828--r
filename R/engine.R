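# Two-state yearly-cycle microsimulation engine and its analytic cohort
# oracle.
#
# Individuals start caries-free; each year each individual develops at most
# one new lesion with the stratum's annual incidence probability, is
# restored, and returns to the no-caries state within the cycle, so the
# yearly cycles are independent Bernoulli trials. No mortality, migration or
# ageing across strata over the horizon; each stratum is a closed cohort.

# Deterministic stream seed derived from the master seed and integer stream
# identifiers, kept inside 32-bit range. Distinct (stratum, scenario, run)
# triples get distinct, reproducible streams so PSA runs are independent and
# any run can be replayed in isolation.
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1
  x <- as.numeric(seed %% m)
  for (k in c(...)) {
    x <- (x * 48271 + as.numeric(k) * 9349 + 12345) %% m
  }
  as.integer(x)
}

# Core simulation: yearly new-lesion counts among n individuals over
# `horizon` years at annual incidence p, under the RNG stream `seed`.
sim_counts <- function(seed, n, horizon, p) {
  with_seed(seed, {
    vapply(seq_len(horizon),
           function(y) sum(stats::runif(n) < p),
           integer(1))
  })
}

scenario_result <- function(stratum, lesions_by_year, n_individuals) {
  out <- list(stratum_id = stratum_id(stratum$sex, stratum$age_band),
              lesions_by_year = as.integer(lesions_by_year),
              n_individuals = as.integer(n_individuals))
  class(out) <- "fopfl_scenario"
  out
}

#' @export
print.fopfl_scenario <- function(x, ...) {
  cat("Scenario result:", x$stratum_id, "|",
      format(x$n_individuals, big.mark = ","), "individuals\n")
  cat("  new lesions by year:", paste(x$lesions_by_year, collapse = " "), "\n")
  invisible(x)
}

#' Simulate one stratum under one scenario
#'
#' Runs `controls$n_individuals` individuals through
#' `controls$horizon` yearly cycles at the given annual incidence. Within a
#' cycle a new lesion is diagnosed and restored, returning the individual to
#' the no-caries state, so at most one lesion per person-year is counted.
#' Fully reproducible given `(controls$seed, stream_id)`.
#'
#' @param stratum one-row strata table.
#' @param incidence annual probability in `[0, 1]` (allows simulating the
#'   stratum under an adjusted incidence).
#' @param controls a [sim_controls()].
#' @param stream_id integer stream identifier separating replicate runs
#'   (e.g. PSA draws) of the same stratum.
#' @return A `fopfl_scenario`: stratum id, integer new-lesion counts for
#'   years `1..horizon`, and the number of individuals simulated.
#' @export
simulate_stratum <- function(stratum, incidence, controls, stream_id = 1L) {
  if (!is.finite(incidence) || incidence < 0 || incidence > 1)
    stop("incidence must be in [0,1]")
  validate_controls(controls)
  key <- stratum_key(stratum$sex, stratum$age_band)
  seed <- derive_seed(controls$seed, key, stream_id, 1L)
  counts <- sim_counts(seed, controls$n_individuals, controls$horizon,
                       incidence)
  scenario_result(stratum, counts, controls$n_individuals)
}

#' Expected total lesions for a closed cohort (analytic oracle)
#'
#' Because cycles are independent and at most one lesion occurs per
#' person-year, the expected total over the horizon is exactly
#' `n_individuals * horizon * incidence`. Used as the closed-form check for
#' the stochastic engine.
#'
#' @param incidence annual probability in `[0, 1]`.
#' @param n_individuals cohort size.
#' @param horizon years.
#' @return Expected total new lesions.
#' @export
cohort_expectation <- function(incidence, n_individuals, horizon) {
  if (any(!is.finite(incidence)) || any(incidence < 0 | incidence > 1))
    stop("incidence must be in [0,1]")
  if (any(n_individuals < 0)) stop("n_individuals must be >= 0")
  if (any(horizon < 0)) stop("horizon must be >= 0")
  n_individuals * horizon * incidence
}

#' Simulate a baseline/labeling scenario pair for one stratum
#'
#' With `controls$common_random_numbers` (the default) the same uniform draw
#' per individual-year is thresholded against both probabilities, so the
#' labeling scenario's lesion count can never exceed the baseline's in any
#' year of any run — incremental effects are noise-free in sign. With CRN
#' off, the two scenarios use independent streams.
#'
#' @param stratum one-row strata table.
#' @param baseline_incidence annual probability under no policy.
#' @param intervention_incidence annual probability under labeling; must not
#'   exceed `baseline_incidence`.
#' @param controls a [sim_controls()].
#' @param stream_id integer stream identifier (see [simulate_stratum()]).
#' @return List with elements `baseline` and `intervention`, both
#'   `fopfl_scenario`.
#' @export
simulate_pair <- function(stratum, baseline_incidence, intervention_incidence,
                          controls, stream_id = 1L) {
  if (intervention_incidence > baseline_incidence)
    stop("intervention_incidence must not exceed baseline_incidence")
  if (baseline_incidence < 0 || baseline_incidence > 1 ||
      intervention_incidence < 0)
    stop("incidences must be probabilities in [0,1]")
  validate_controls(controls)
  key <- stratum_key(stratum$sex, stratum$age_band)
  n <- controls$n_individuals
  horizon <- controls$horizon
  if (controls$common_random_numbers) {
    seed <- derive_seed(controls$seed, key, stream_id, 0L)
    counts <- with_seed(seed, {
      cb <- integer(horizon); ci <- integer(horizon)
      for (y in seq_len(horizon)) {
        u <- stats::runif(n)
        cb[y] <- sum(u < baseline_incidence)
        ci[y] <- sum(u < intervention_incidence)
      }
      list(base = cb, int = ci)
    })
  } else {
    counts <- list(
      base = sim_counts(derive_seed(controls$seed, key, stream_id, 1L),
                        n, horizon, baseline_incidence),
      int = sim_counts(derive_seed(controls$seed, key, stream_id, 2L),
                       n, horizon, intervention_incidence)
    )
  }
  list(baseline = scenario_result(stratum, counts$base, n),
       intervention = scenario_result(stratum, counts$int, n))
}
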