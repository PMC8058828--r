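# Deterministic and probabilistic sensitivity analysis.

#' Deterministic one-way sensitivity analysis over the labeling effect
#'
#' Re-runs the full pipeline at each supplied labeling-effect fraction with
#' identical random streams, so differences between rows are attributable to
#' the effect size alone. With common random numbers and the linear
#' dose-response, outcomes are monotone non-decreasing in the effect.
#'
#' @param config a `fopfl_config`.
#' @param effect_values labeling-effect fractions in `[0, 1]`, reported in
#'   the order given; default the meta-analytic point estimate bracketed by
#'   its confidence bounds.
#' @return An object of class `fopfl_dsa`: `totals` (one row of total
#'   incremental outcomes per effect value, column `effect_fraction` first)
#'   and `sims` (the full `fopfl_sim` per effect value).
#' @export
run_dsa <- function(config, effect_values = c(0.044, 0.066, 0.088)) {
  validate_config(config)
  if (any(effect_values < 0 | effect_values > 1))
    stop("effect_values must be in [0,1]")
  sims <- lapply(effect_values, function(e) {
    cfg <- config
    cfg$intervention$effect_fraction <- e
    simulate_policy(cfg)
  })
  totals <- do.call(rbind, lapply(sims, function(s) s$total))
  totals$stratum <- NULL
  totals <- cbind(effect_fraction = effect_values, totals)
  out <- list(totals = totals, sims = sims)
  class(out) <- "fopfl_dsa"
  out
}

#' @export
print.fopfl_dsa <- function(x, ...) {
  cat("Deterministic sensitivity analysis over the labeling effect\n")
  show <- data.frame(
    effect_fraction = x$totals$effect_fraction,
    lesions_prevented = round(x$totals$lesions_prevented),
    costs_avoided_Meur = sprintf("%.2f", x$totals$costs_avoided_eur / 1e6),
    dalys_averted = sprintf("%.2f", x$totals$dalys_averted),
    productivity_avoided_Meur =
      sprintf("%.2f", x$totals$productivity_avoided_eur / 1e6)
  )
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
plot.fopfl_dsa <- function(x, ...) {
  graphics::barplot(x$totals$lesions_prevented / 1e6,
                    names.arg = sprintf("%.1f%%",
                                        100 * x$totals$effect_fraction),
                    xlab = "labeling effect on sugar intake",
                    ylab = "caries lesions prevented (millions)", ...)
  invisible(x)
}

#' Probabilistic sensitivity analysis specification
#'
#' Parameter uncertainty is modelled with independent normal distributions
#' centred on the base-case values, truncated to each parameter's domain.
#' The standard deviation of every drawn parameter defaults to 20% of its
#' mean (the stated convention for the restoration cost, applied to all
#' drawn parameters); each is individually overridable.
#'
#' @param n_runs number of PSA draws; default 2000.
#' @param n_individuals persons simulated per stratum within each run;
#'   default 500000.
#' @param sd_frac named list of sd/mean fractions for `incidence`,
#'   `effect_fraction`, `sugar_caries_slope`, `unit_cost`.
#' @param seed PSA master seed.
#' @param all_strata when `FALSE` (default) only the two extreme-consumption
#'   strata are simulated, when `TRUE` all twelve.
#' @return A validated list of class `fopfl_psa_spec`.
#' @export
psa_spec <- function(n_runs = 2000, n_individuals = 500000,
                     sd_frac = list(incidence = 0.20, effect_fraction = 0.20,
                                    sugar_caries_slope = 0.20,
                                    unit_cost = 0.20),
                     seed = 1, all_strata = FALSE) {
  dflt <- list(incidence = 0.20, effect_fraction = 0.20,
               sugar_caries_slope = 0.20, unit_cost = 0.20)
  check_keys(sd_frac, names(dflt), "sd_frac")
  out <- list(n_runs = as.integer(n_runs),
              n_individuals = as.integer(n_individuals),
              sd_frac = utils::modifyList(dflt, sd_frac),
              seed = as.integer(seed),
              all_strata = isTRUE(all_strata))
  class(out) <- "fopfl_psa_spec"
  if (is.na(out$n_runs) || out$n_runs < 1) stop("n_runs must be >= 1")
  if (is.na(out$n_individuals) || out$n_individuals < 1)
    stop("n_individuals must be >= 1")
  if (any(unlist(out$sd_frac) < 0)) stop("sd_frac values must be >= 0")
  out
}

# Truncated normal via rejection; after 1000 rejected rounds (unreachable
# for means inside the domain and moderate sds) the draw is clamped to the
# nearest bound.
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  for (i in seq_len(1000)) {
    need <- n - length(out)
    if (need <= 0) break
    x <- stats::rnorm(need, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  if (length(out) < n) {
    x <- stats::rnorm(n - length(out), mean, sd)
    out <- c(out, pmin(pmax(x, lower), upper))
  }
  out[seq_len(n)]
}

#' Draw one PSA parameter set
#'
#' Returns a copy of the base configuration with the annual caries
#' incidences, the labeling effect, the dose-response slope and the unit
#' restoration cost replaced by independent truncated-normal draws
#' (probabilities to `[0, 1]`, cost and slope to `>= 0`). Reproducible per
#' `(spec$seed, run_id)`.
#'
#' @param base the base `fopfl_config`.
#' @param spec a [psa_spec()].
#' @param run_id integer PSA run index.
#' @return A `fopfl_config` with drawn parameter values.
#' @export
draw_psa_config <- function(base, spec, run_id) {
  validate_config(base)
  seed <- derive_seed(spec$seed, 101L, run_id, 0L)
  with_seed(seed, {
    cfg <- base
    p <- base$strata$incidence
    cfg$strata$incidence <- vapply(p, function(pi) {
      rtrunc_norm(1, pi, spec$sd_frac$incidence * pi, 0, 1)
    }, numeric(1))
    e <- base$intervention$effect_fraction
    cfg$intervention$effect_fraction <-
      rtrunc_norm(1, e, spec$sd_frac$effect_fraction * e, 0, 1)
    s <- base$intervention$sugar_caries_slope
    cfg$intervention$sugar_caries_slope <-
      rtrunc_norm(1, s, spec$sd_frac$sugar_caries_slope * s, 0, Inf)
    u <- base$economics$unit_cost
    cfg$economics$unit_cost <-
      max(rtrunc_norm(1, u, spec$sd_frac$unit_cost * u, 0, Inf),
          .Machine$double.eps)
    cfg
  })
}

classify_quadrant <- function(effect, cost) {
  # Axis conventions of the cost-effectiveness plane: horizontal = incremental
  # effect (lesions prevented), vertical = incremental cost (savings
  # negative). Points exactly on an axis go to the positive-effect side and
  # the cost-saving (bottom) side respectively.
  right <- effect >= 0
  bottom <- cost <= 0
  ifelse(right & bottom, "SE",
         ifelse(right & !bottom, "NE",
                ifelse(!right & !bottom, "NW", "SW")))
}

#' Probabilistic sensitivity analysis
#'
#' For each run: draw a parameter set ([draw_psa_config()]), simulate the
#' selected strata as common-random-number scenario pairs, and record the
#' discounted incremental effect (population-scaled lesions prevented) and
#' incremental cost (negative of treatment costs avoided; savings are
#' negative) as one point on the cost-effectiveness plane, classified by
#' quadrant. Runs are independent and individually reproducible.
#'
#' @param base the base `fopfl_config`.
#' @param spec a [psa_spec()].
#' @return An object of class `fopfl_psa` with `points` (data frame: `run`,
#'   `effect`, `cost`, `quadrant`) and the `spec`.
#' @seealso [quadrant_fractions()]
#' @export
run_psa <- function(base, spec = psa_spec()) {
  validate_config(base)
  strata <- if (spec$all_strata) {
    base$strata
  } else {
    ex <- extreme_strata(base)
    rbind(ex$max, ex$min)
  }
  rows <- vector("list", spec$n_runs)
  for (r in seq_len(spec$n_runs)) {
    cfg <- draw_psa_config(base, spec, r)
    controls <- cfg$controls
    controls$n_individuals <- spec$n_individuals
    controls$seed <- spec$seed
    controls$common_random_numbers <- TRUE
    effect_r <- 0
    cost_r <- 0
    for (i in seq_len(nrow(strata))) {
      st_base <- strata[i, , drop = FALSE]
      st <- cfg$strata[cfg$strata$sex == st_base$sex &
                       cfg$strata$age_band == st_base$age_band, , drop = FALSE]
      delta <- sugar_reduction(st$sugar_intake,
                               cfg$intervention$effect_fraction)
      p_int <- adjusted_incidence(st$incidence, delta,
                                  cfg$intervention$sugar_caries_slope,
                                  form = cfg$intervention$dose_response)
      pair <- simulate_pair(st, st$incidence, p_int, controls, stream_id = r)
      inc <- incremental(pair$baseline, pair$intervention, st, cfg$economics)
      effect_r <- effect_r + inc$lesions_prevented_disc
      cost_r <- cost_r - inc$costs_avoided_disc_eur
    }
    rows[[r]] <- data.frame(run = r, effect = effect_r, cost = cost_r,
                            quadrant = classify_quadrant(effect_r, cost_r),
                            stringsAsFactors = FALSE)
  }
  out <- list(points = do.call(rbind, rows), spec = spec)
  class(out) <- "fopfl_psa"
  out
}

#' Quadrant fractions of a cost-effectiveness plane
#'
#' @param points a `fopfl_psa` or its `points` data frame.
#' @return Named numeric vector with fractions for `NE`, `NW`, `SE`, `SW`,
#'   summing to 1.
#' @export
quadrant_fractions <- function(points) {
  if (inherits(points, "fopfl_psa")) points <- points$points
  if (is.null(points) || nrow(points) == 0)
    stop("no PSA points to classify")
  q <- factor(points$quadrant, levels = c("NE", "NW", "SE", "SW"))
  tab <- table(q) / nrow(points)
  stats::setNames(as.numeric(tab), names(tab))
}

#' @export
print.fopfl_psa <- function(x, ...) {
  fr <- quadrant_fractions(x)
  cat(sprintf("Probabilistic sensitivity analysis: %d runs x %s individuals/stratum\n",
              x$spec$n_runs, format(x$spec$n_individuals, big.mark = ",")))
  cat(sprintf("  quadrants: NE %.1f%% | NW %.1f%% | SE %.1f%% | SW %.1f%%\n",
              100 * fr["NE"], 100 * fr["NW"], 100 * fr["SE"], 100 * fr["SW"]))
  cat(sprintf("  median effect: %s lesions prevented | median cost: EUR %.2fM\n",
              format(round(stats::median(x$points$effect)), big.mark = ","),
              stats::median(x$points$cost) / 1e6))
  invisible(x)
}

#' @export
plot.fopfl_psa <- function(x, ...) {
  pts <- x$points
  graphics::plot(pts$effect / 1e6, pts$cost / 1e6,
                 xlab = "incremental effect (million lesions prevented)",
                 ylab = "incremental cost (million EUR)",
                 pch = 16, cex = 0.5, col = "steelblue", ...)
  graphics::abline(h = 0, v = 0, lty = 2)
  invisible(x)
}
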