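# Dose-response linkage: labeling effect on sugar intake -> adjusted
# annual caries incidence.

#' Absolute sugar-intake reduction under labeling
#'
#' The labeling effect is a single fractional reduction applied identically
#' to every stratum (no heterogeneity by age or sex) and held constant over
#' the whole horizon.
#'
#' @param sugar_intake baseline added-sugar intake, g/person/day (> 0).
#' @param effect_fraction fractional reduction in `[0, 1]`.
#' @return `sugar_intake * effect_fraction`, in g/day. Vectorised.
#' @export
sugar_reduction <- function(sugar_intake, effect_fraction) {
  if (any(!is.finite(sugar_intake)) || any(sugar_intake <= 0))
    stop("sugar_intake must be > 0")
  if (any(!is.finite(effect_fraction)) ||
      any(effect_fraction < 0 | effect_fraction > 1))
    stop("effect_fraction must be in [0,1]")
  sugar_intake * effect_fraction
}

#' Annual incidence adjusted for a sugar-intake reduction
#'
#' Maps a reduction in added-sugar intake to a reduced annual probability of
#' developing a new caries lesion. The default (`"absolute"`) form subtracts
#' `slope * delta_sugar` percentage points from the baseline probability;
#' the `"relative"` form multiplies the baseline by `1 - slope * delta_sugar`.
#' Either way the result is clamped to `[0, baseline]`, so the adjusted
#' incidence never exceeds the baseline and equals it only when
#' `delta_sugar * slope == 0`. The baseline incidence is taken to correspond
#' to baseline intake; only the labeling scenario is adjusted.
#'
#' @param baseline_incidence annual probability in `[0, 1]`.
#' @param delta_sugar sugar-intake reduction, g/day (>= 0).
#' @param slope incidence reduction per g/day (>= 0); units are probability
#'   per g/day for the absolute form, fraction per g/day for the relative
#'   form.
#' @param form `"absolute"` or `"relative"`.
#' @return Adjusted annual incidence probability. Vectorised.
#' @export
adjusted_incidence <- function(baseline_incidence, delta_sugar, slope,
                               form = c("absolute", "relative")) {
  form <- match.arg(form)
  if (any(!is.finite(baseline_incidence)) ||
      any(baseline_incidence < 0 | baseline_incidence > 1))
    stop("baseline_incidence must be in [0,1]")
  if (any(!is.finite(delta_sugar)) || any(delta_sugar < 0))
    stop("delta_sugar must be >= 0")
  if (any(!is.finite(slope)) || any(slope < 0))
    stop("slope must be >= 0")
  adj <- switch(form,
    absolute = baseline_incidence - slope * delta_sugar,
    relative = baseline_incidence * (1 - slope * delta_sugar)
  )
  pmin(pmax(adj, 0), baseline_incidence)
}
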