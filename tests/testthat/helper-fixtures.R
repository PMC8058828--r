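# Shared fixtures: small, fast configurations built in code.

small_config <- function(n = 2000L, horizon = 10L, seed = 1L, crn = TRUE) {
  cfg <- default_config()
  cfg$controls <- sim_controls(horizon = horizon, n_individuals = n,
                               seed = seed, common_random_numbers = crn)
  cfg
}

one_stratum <- function(sex = "male", age_band = "15-18",
                        sugar_intake = 100, incidence = 0.2,
                        population = 1e6) {
  df <- default_config()$strata
  st <- df[df$sex == sex & df$age_band == age_band, , drop = FALSE]
  st$sugar_intake <- sugar_intake
  st$incidence <- incidence
  st$population <- population
  st
}
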