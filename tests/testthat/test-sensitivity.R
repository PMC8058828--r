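test_that("DSA outcomes are ordered in the labeling effect under CRN", {
  cfg <- small_config(n = 2000L)
  dsa <- run_dsa(cfg, effect_values = c(0.044, 0.066, 0.088))
  tot <- dsa$totals
  expect_equal(tot$effect_fraction, c(0.044, 0.066, 0.088))
  expect_lt(tot$lesions_prevented[1], tot$lesions_prevented[3])
  # the point estimate is bracketed by the bounds
  expect_gt(tot$lesions_prevented[2], tot$lesions_prevented[1])
  expect_lt(tot$lesions_prevented[2], tot$lesions_prevented[3])
  # null effect: all-zero incremental outcomes
  dsa0 <- run_dsa(cfg, effect_values = 0)
  expect_equal(dsa0$totals$lesions_prevented, 0)
  expect_equal(dsa0$totals$costs_avoided_eur, 0)
  expect_error(run_dsa(cfg, effect_values = c(0.05, 1.2)), "effect_values")
})

test_that("PSA draws are truncated normals centred on the base values", {
  cfg <- default_config()
  spec <- psa_spec(seed = 5)
  # zero sds: degenerate draws return the base config values
  spec0 <- psa_spec(sd_frac = list(incidence = 0, effect_fraction = 0,
                                   sugar_caries_slope = 0, unit_cost = 0))
  drawn0 <- draw_psa_config(cfg, spec0, run_id = 1)
  expect_equal(drawn0$strata$incidence, cfg$strata$incidence)
  expect_equal(drawn0$economics$unit_cost, cfg$economics$unit_cost)
  expect_equal(drawn0$intervention$effect_fraction,
               cfg$intervention$effect_fraction)
  # reproducible per (seed, run_id), distinct across runs
  expect_equal(draw_psa_config(cfg, spec, 3), draw_psa_config(cfg, spec, 3))
  expect_false(identical(draw_psa_config(cfg, spec, 3),
                         draw_psa_config(cfg, spec, 4)))
  # domains respected in every draw
  for (r in 1:50) {
    d <- draw_psa_config(cfg, spec, r)
    expect_true(all(d$strata$incidence >= 0 & d$strata$incidence <= 1))
    expect_gte(d$economics$unit_cost, 0)
    expect_gte(d$intervention$sugar_caries_slope, 0)
    expect_true(d$intervention$effect_fraction >= 0 &
                d$intervention$effect_fraction <= 1)
  }
})

test_that("truncated-normal sampling has the right mean and bounds", {
  mean_uc <- 74.10; sd_uc <- 0.20 * 74.10
  set.seed(101)
  draws <- fopflcaries:::rtrunc_norm(10000, mean_uc, sd_uc, 0, Inf)
  expect_true(all(draws >= 0))
  # truncation at 0 is ~5 sd away, so the sample mean matches the normal mean
  expect_lt(abs(mean(draws) - mean_uc), 3 * sd_uc / sqrt(10000))
  # heavy truncation never yields values outside the domain
  low <- fopflcaries:::rtrunc_norm(1000, -5, 1, 0, Inf)
  expect_true(all(low >= 0))
})

test_that("quadrant classification and fractions are consistent", {
  pts <- data.frame(run = 1:4,
                    effect = c(10, 10, -10, -10),
                    cost = c(-5, 5, 5, -5),
                    quadrant = c("SE", "NE", "NW", "SW"))
  fr <- quadrant_fractions(pts)
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr), rep(0.25, 4))
  # ties go to the positive-effect and cost-saving sides
  expect_equal(fopflcaries:::classify_quadrant(5, 0), "SE")
  expect_equal(fopflcaries:::classify_quadrant(0, -1), "SE")
  expect_equal(fopflcaries:::classify_quadrant(5, -1), "SE")
  expect_equal(fopflcaries:::classify_quadrant(5, 1), "NE")
  expect_equal(fopflcaries:::classify_quadrant(-5, 1), "NW")
  expect_equal(fopflcaries:::classify_quadrant(-5, -1), "SW")
  expect_error(quadrant_fractions(pts[0, ]), "no PSA points")
})

test_that("PSA with zero uncertainty repeats the base case bit-identically", {
  cfg <- small_config(n = 1000L)
  spec0 <- psa_spec(n_runs = 5, n_individuals = 1000,
                    sd_frac = list(incidence = 0, effect_fraction = 0,
                                   sugar_caries_slope = 0, unit_cost = 0),
                    seed = 77)
  psa <- run_psa(cfg, spec0)
  expect_equal(nrow(psa$points), 5)
  # every run draws the identical config; effects differ only via streams
  expect_true(all(psa$points$quadrant == "SE"))
  psa2 <- run_psa(cfg, spec0)
  expect_identical(psa$points, psa2$points)
})

test_that("a zero base effect yields zero incremental effect in every run", {
  cfg <- small_config(n = 500L)
  cfg$intervention$effect_fraction <- 0
  spec <- psa_spec(n_runs = 5, n_individuals = 500, seed = 3,
                   sd_frac = list(incidence = 0.2, effect_fraction = 0,
                                  sugar_caries_slope = 0.2, unit_cost = 0.2))
  psa <- run_psa(cfg, spec)
  expect_true(all(psa$points$effect == 0))
})

test_that("PSA covers the two extreme strata by default, all on request", {
  cfg <- small_config(n = 200L)
  spec <- psa_spec(n_runs = 2, n_individuals = 200, seed = 1)
  psa2 <- run_psa(cfg, spec)
  spec_all <- psa_spec(n_runs = 2, n_individuals = 200, seed = 1,
                       all_strata = TRUE)
  psa12 <- run_psa(cfg, spec_all)
  # the 12-stratum run accumulates strictly more incremental effect
  expect_gt(psa12$points$effect[1], psa2$points$effect[1])
})
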