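#' Specify a mass-media app-promotion intervention
#'
#' Encodes the intervention pathway of a one-off national mass-media campaign
#' promoting physical-activity smartphone apps: of the eligible adult
#' population, a fraction becomes aware of the campaign, a fraction of those
#' downloads an app, a fraction uses it (at least 7 days), and a fraction of
#' users adheres (weighted annual average); adherers gain `effect_met_min`
#' MET-min/week for the duration of the effect.  Defaults are the campaign's
#' central estimates.
#'
#' @param awareness Proportion of eligible adults aware of the campaign
#'   (default 0.779).
#' @param download Proportion of aware adults who download an app (0.31).
#' @param use Proportion of downloaders who use the app (0.16).
#' @param adherence Weighted annual-average proportion of users who adhere
#'   (0.15).
#' @param effect_met_min Increase in weekly MVPA MET-minutes for adherers
#'   (285, from a 1404 steps/day trial effect at 34.5 steps per MET-min).
#' @param cost_total Total one-off campaign cost in 2011 NZ$ (2,883,000).
#' @param eligible_ages Length-2 ages (inclusive) of the target population,
#'   default 15-79.
#' @param effect_duration Years the exposure shift persists (default 1: a
#'   one-off campaign with no effect beyond the first year; the 5-year
#'   maintenance scenario sets 5).
#' @param adherence_mode How adherence enters: `"fraction"` (default) folds it
#'   into the affected population fraction with the full effect size;
#'   `"effect"` applies adherence to the effect size instead, with the
#'   three-step reach as the affected fraction.
#' @return Object of class `intervention_spec`.
#' @export
intervention_spec <- function(awareness = 0.779, download = 0.31, use = 0.16,
                              adherence = 0.15, effect_met_min = 285,
                              cost_total = 2883000,
                              eligible_ages = c(15, 79),
                              effect_duration = 1L,
                              adherence_mode = c("fraction", "effect")) {
  props <- c(awareness = awareness, download = download, use = use,
             adherence = adherence)
  if (any(props < 0 | props > 1))
    stop("pathway proportions must lie in [0, 1]")
  if (effect_met_min < 0) stop("`effect_met_min` must be non-negative")
  if (cost_total < 0) stop("`cost_total` must be non-negative")
  if (effect_duration < 1) stop("`effect_duration` must be at least 1 year")
  if (length(eligible_ages) != 2 || eligible_ages[1] >= eligible_ages[2])
    stop("`eligible_ages` must be an increasing length-2 range")
  structure(list(awareness = awareness, download = download, use = use,
                 adherence = adherence, effect_met_min = effect_met_min,
                 cost_total = cost_total, eligible_ages = eligible_ages,
                 effect_duration = as.integer(effect_duration),
                 adherence_mode = match.arg(adherence_mode)),
            class = "intervention_spec")
}

#' @export
print.intervention_spec <- function(x, ...) {
  cat("Mass-media physical-activity app promotion campaign\n")
  cat(sprintf("  pathway: awareness %.1f%% x download %.1f%% x use %.1f%% x adherence %.1f%%\n",
              100 * x$awareness, 100 * x$download, 100 * x$use, 100 * x$adherence))
  cat(sprintf("  effective reach: %.4f%% of eligible adults (ages %d-%d)\n",
              100 * effective_reach(x), x$eligible_ages[1], x$eligible_ages[2]))
  cat(sprintf("  effect: +%g MET-min/week for %d year(s); cost NZ$%s (year 0)\n",
              x$effect_met_min, x$effect_duration,
              format(x$cost_total, big.mark = ",")))
  invisible(x)
}

#' Effective reach of the intervention pathway
#'
#' The proportion of the eligible population that experiences the physical
#' activity increase: the product of awareness, download, use and adherence.
#'
#' @param spec An [intervention_spec()].
#' @return Proportion in `[0, 1]`.
#' @examples
#' effective_reach(intervention_spec())  # ~0.0058
#' @export
effective_reach <- function(spec) {
  stopifnot(inherits(spec, "intervention_spec"))
  spec$awareness * spec$download * spec$use * spec$adherence
}

#' Counterfactual exposure distribution under the intervention
#'
#' Shifts a BAU exposure distribution by the intervention effect.  Under the
#' default `adherence_mode = "fraction"` the full effect size moves the
#' four-factor effective reach of the population; under `"effect"` the
#' adherence-scaled effect moves the three-factor (aware x download x use)
#' fraction.
#'
#' @param bau An [exposure_distribution()].
#' @param spec An [intervention_spec()].
#' @return The shifted `exposure_dist`.
#' @export
counterfactual_distribution <- function(bau, spec) {
  stopifnot(inherits(spec, "intervention_spec"))
  if (spec$adherence_mode == "fraction")
    shift_distribution(bau, spec$effect_met_min, effective_reach(spec))
  else
    shift_distribution(bau, spec$effect_met_min * spec$adherence,
                       spec$awareness * spec$download * spec$use)
}

#' Year-indexed counterfactual exposures per stratum
#'
#' For each stratum, the exposure distribution in every calendar year of the
#' horizon: the shifted distribution during the effect years (applied to
#' eligible ages by the life-table engine), BAU everywhere else.
#'
#' @param exposure Named list of per-stratum BAU [exposure_distribution()]s.
#' @param spec An [intervention_spec()].
#' @param horizon Years.
#' @param max_age Highest modelled age (eligibility must fit inside).
#' @return Named list per stratum: list of `exposure_dist`s indexed by year
#'   (element 1 = year 0).
#' @export
build_counterfactual_exposures <- function(exposure, spec, horizon = 110L,
                                           max_age = 109L) {
  stopifnot(inherits(spec, "intervention_spec"))
  if (spec$eligible_ages[1] > max_age)
    stop("eligible age range lies outside the modelled population")
  lapply(exposure, function(bau) {
    cf <- counterfactual_distribution(bau, spec)
    lapply(0:(horizon - 1L), function(y)
      if (y < spec$effect_duration) cf else bau)
  })
}

#' Intervention cost stream
#'
#' The one-off campaign cost falls entirely in year 0.
#'
#' @param spec An [intervention_spec()].
#' @param horizon Years.
#' @return Numeric vector by year summing to `cost_total`.
#' @export
intervention_cost_stream <- function(spec, horizon = 110L) {
  stopifnot(inherits(spec, "intervention_spec"))
  c(spec$cost_total, rep(0, horizon - 1L))
}
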