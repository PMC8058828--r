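test_that("default configuration carries the canonical parameter values", {
  cfg <- default_config()
  expect_equal(cfg$economics$unit_cost, 74.10)
  expect_equal(cfg$economics$discount_rate, 0.03)
  expect_equal(cfg$economics$gdp_per_capita, 40332)
  expect_equal(cfg$intervention$effect_fraction, 0.066)
  expect_equal(cfg$controls$horizon, 10L)
  expect_equal(cfg$controls$n_individuals, 500000L)
  # per-lesion DALY components multiply to the value implied by the
  # published DALY and lesion totals (677.62 / 2,370,715)
  expect_equal(daly_per_lesion(cfg$economics), 677.62 / 2370715,
               tolerance = 1e-4)
  expect_identical(default_config()$strata, cfg$strata)  # fixed seed
})

test_that("stratum and parameter invariants are enforced with named errors", {
  cfg <- default_config()
  bad <- cfg$strata
  bad$incidence[3] <- 1.2
  expect_error(strata_table(bad$sex, bad$age_band, bad$sugar_intake,
                            bad$incidence, bad$population),
               "incidence must be in \\[0,1\\]")
  expect_error(validate_strata(cfg$strata[-1, ]), "expected 12 strata")
  dup <- cfg$strata
  dup$age_band[2] <- dup$age_band[1]
  expect_error(validate_strata(dup), "exactly once")
  expect_error(economic_params(unit_cost = 0), "unit_cost must be > 0")
  expect_error(economic_params(discount_rate = -0.01), "discount_rate")
  expect_error(economic_params(daly = list(p_symptomatic = 1.5, duration = 1,
                                           disability_weight = 0.1)),
               "p_symptomatic")
  expect_error(intervention_params(effect_fraction = 1.2), "effect_fraction")
  expect_error(intervention_params(sugar_caries_slope = -1), "slope")
  expect_error(sim_controls(horizon = 0), "horizon")
})

test_that("random invalid fields never pass validation", {
  set.seed(99)
  cfg <- default_config()
  for (i in 1:25) {
    bad <- cfg
    field <- sample(c("incidence", "sugar", "population", "effect"), 1)
    if (field == "incidence") {
      bad$strata$incidence[sample(12, 1)] <-
        sample(c(-0.1, 1.01, NA_real_, Inf), 1)
    } else if (field == "sugar") {
      bad$strata$sugar_intake[sample(12, 1)] <- sample(c(0, -5, NA_real_), 1)
    } else if (field == "population") {
      bad$strata$population[sample(12, 1)] <- sample(c(-1, 2.5, NA_real_), 1)
    } else {
      bad$intervention$effect_fraction <- sample(c(-0.2, 1.5, NA_real_), 1)
    }
    expect_error(validate_config(bad))
  }
})

test_that("a config round-trips through write-then-read exactly", {
  cfg <- default_config()
  cfg$strata$sugar_intake[5] <- 1 / 3  # exercise full double precision
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_identical(back$strata$sugar_intake, cfg$strata$sugar_intake)
  expect_identical(back$strata$incidence, cfg$strata$incidence)
  expect_equal(back$economics, cfg$economics)
  expect_equal(back$intervention, cfg$intervention)
  expect_equal(back$controls, cfg$controls)
  expect_equal(back$implementation_cost_range, cfg$implementation_cost_range)
})

test_that("missing optional keys take defaults and unknown keys error", {
  cfg <- default_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  doc <- yaml::read_yaml(path)
  doc$economics$discount_rate <- NULL
  path2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(doc, precision = 17), path2)
  expect_equal(read_config(path2)$economics$discount_rate, 0.03)

  doc$economics$discuont_rate <- 0.05  # typo must be caught
  writeLines(yaml::as.yaml(doc, precision = 17), path2)
  expect_error(read_config(path2), "unknown key")

  doc$economics$discuont_rate <- NULL
  doc$strata <- doc$strata[1:11]
  writeLines(yaml::as.yaml(doc, precision = 17), path2)
  expect_error(read_config(path2), "expected 12 strata")
})

test_that("alternative unit-cost presets reproduce the scenario totals", {
  tot <- reference_totals()
  expect_equal(round(tot$total_lesions *
                       unit_cost_presets[["copayment"]] / 1e6, 2),
               tot$cost_scenarios$copayment_total_million, tolerance = 0.005)
  expect_equal(round(tot$total_lesions *
                       unit_cost_presets[["restoration_failure"]] / 1e6, 2),
               tot$cost_scenarios$restoration_failure_total_million,
               tolerance = 0.005)
})
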