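test_that("discount factors follow the year-1-undiscounted convention", {
  expect_equal(discount_factor(1, 0.03), 1)
  expect_equal(discount_factor(2, 0.03), 1 / 1.03)
  expect_equal(discount_factor(7, 0), 1)
  expect_error(discount_factor(0, 0.03), "year")
  expect_error(discount_factor(2, -0.1), "rate")
})

test_that("valuation operations match hand-computed sums", {
  expect_equal(treatment_costs(c(1, 0), 74.10, 0), 74.10)
  expect_equal(treatment_costs(rep(0, 10), 74.10, 0.03), 0)
  expect_equal(treatment_costs(c(1, 1), 100, 0.03), 100 * (1 + 1 / 1.03))
  dp <- default_config()$economics$daly
  expect_equal(dalys_averted(c(1), dp, 0), daly_per_lesion(economic_params()))
  expect_equal(dalys_averted(rep(0, 5), dp, 0.03), 0)
  dp0 <- dp; dp0$disability_weight <- 0
  expect_equal(dalys_averted(c(10, 20), dp0, 0), 0)
  expect_equal(productivity_loss_avoided(0, 40332), 0)
  expect_equal(productivity_loss_avoided(1, 40332), 40332)
  expect_equal(scale_to_population(500, 1000, 1000), 500)
  expect_equal(scale_to_population(500, 1000, 2e6), 1e6)
  expect_equal(scale_to_population(0, 123, 456), 0)
})

test_that("incremental results satisfy the cost identity and scale linearly", {
  st <- one_stratum(incidence = 0.2, population = 2e6)
  ct <- sim_controls(horizon = 10, n_individuals = 4000, seed = 2)
  pair <- simulate_pair(st, 0.2, 0.17, ct)
  eco <- economic_params()
  inc <- incremental(pair$baseline, pair$intervention, st, eco)
  # undiscounted cost identity, exact
  expect_identical(inc$costs_avoided_eur,
                   inc$lesions_prevented * eco$unit_cost)
  # population scaling
  diff_total <- sum(pair$baseline$lesions_by_year -
                    pair$intervention$lesions_by_year)
  expect_equal(inc$lesions_prevented,
               scale_to_population(diff_total, ct$n_individuals,
                                   st$population))
  # DALY and productivity chains
  expect_equal(inc$dalys_averted, inc$lesions_prevented * daly_per_lesion(eco))
  expect_equal(inc$productivity_avoided_eur,
               inc$dalys_averted * eco$gdp_per_capita)
  # discounted never exceeds undiscounted at a positive rate
  expect_lte(inc$lesions_prevented_disc, inc$lesions_prevented)
  expect_lte(inc$costs_avoided_disc_eur, inc$costs_avoided_eur)
  expect_lte(inc$dalys_averted_disc, inc$dalys_averted)
  expect_lte(inc$productivity_avoided_disc_eur, inc$productivity_avoided_eur)
  # identical scenarios: all-zero incremental result
  inc0 <- incremental(pair$baseline, pair$baseline, st, eco)
  vals <- unlist(inc0[setdiff(names(inc0), "stratum")])
  expect_true(all(vals == 0))
})

test_that("mismatched scenario pairs are rejected", {
  st <- one_stratum()
  ct5 <- sim_controls(horizon = 5, n_individuals = 100, seed = 1)
  ct6 <- sim_controls(horizon = 6, n_individuals = 100, seed = 1)
  a <- simulate_stratum(st, 0.2, ct5)
  b <- simulate_stratum(st, 0.2, ct6)
  expect_error(incremental(a, b, st, economic_params()), "horizon mismatch")
  st2 <- one_stratum(sex = "female")
  c2 <- simulate_stratum(st2, 0.2, ct5)
  expect_error(incremental(a, c2, st, economic_params()), "different strata")
})

test_that("published reference magnitudes follow from the valuation chain", {
  # undiscounted treatment costs at the published unit cost
  expect_equal(round(2370715 * 74.10 / 1e6, 2), 175.67)
  expect_equal(round(89638 * 74.10 / 1e6, 2), 6.64)
  # productivity from published DALY total at the configured GDP per capita
  eco <- economic_params()
  expect_equal(round(productivity_loss_avoided(677.62,
                                               eco$gdp_per_capita) / 1e6, 2),
               27.33)
})
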