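#' Default weekly MVPA MET-minute exposure bins
#'
#' The categorical grid on which population physical-activity exposure is
#' represented.  The first bin is the truly inactive (0 MET-min/week); the
#' remaining bins double in width so that both the sedentary tail and the
#' highly active tail are resolved.  Relative risks are evaluated at bin
#' midpoints and population impact fractions are exact sums over bins.
#'
#' @return A data frame with columns `lower`, `upper` (half-open
#'   `[lower, upper)` intervals in MET-min/week, the last bin unbounded) and
#'   `midpoint` (the representative exposure for the bin).
#' @export
default_exposure_bins <- function() {
  data.frame(
    lower    = c(0,   1, 150, 300,  600, 1200, 2400, 4800),
    upper    = c(1, 150, 300, 600, 1200, 2400, 4800,  Inf),
    midpoint = c(0,  75, 225, 450,  900, 1800, 3600, 6000)
  )
}

#' Construct a categorical exposure distribution
#'
#' @param proportion Numeric vector of bin proportions (non-negative, must sum
#'   to 1 within `1e-8`).
#' @param bins Data frame of bin edges and midpoints, as
#'   [default_exposure_bins()].
#' @return An object of class `exposure_dist`: the bin data frame with a
#'   `proportion` column.
#' @export
exposure_distribution <- function(proportion, bins = default_exposure_bins()) {
  stopifnot(is.data.frame(bins), all(c("lower", "upper", "midpoint") %in% names(bins)))
  if (length(proportion) != nrow(bins))
    stop("`proportion` must have one entry per bin")
  if (any(proportion < 0))
    stop("bin proportions must be non-negative")
  if (abs(sum(proportion) - 1) > 1e-8)
    stop("bin proportions must sum to 1 (got ", format(sum(proportion)), ")")
  if (is.unsorted(bins$lower, strictly = TRUE) ||
      any(bins$upper[-nrow(bins)] > bins$lower[-1] + 1e-12))
    stop("bins must be ordered and non-overlapping")
  out <- bins
  out$proportion <- as.numeric(proportion)
  class(out) <- c("exposure_dist", "data.frame")
  out
}

#' @export
print.exposure_dist <- function(x, ...) {
  cat("Weekly MVPA MET-minute exposure distribution\n")
  cat(sprintf("  mean exposure: %.1f MET-min/week over %d bins\n",
              mean_exposure(x), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Mean exposure of a categorical distribution
#'
#' @param dist An [exposure_distribution()].
#' @return Mean weekly MET-minutes, evaluated at bin midpoints.
#' @export
mean_exposure <- function(dist) {
  sum(dist$proportion * dist$midpoint)
}

#' Convert daily step counts to weekly MVPA MET-minutes
#'
#' App-effectiveness trials typically report increases in steps/day; the life
#' table model works in MET-min/week.  The conversion divides weekly steps by
#' the number of steps equivalent to one MVPA MET-minute.
#'
#' @param steps_per_day Non-negative steps per day.
#' @param steps_per_met_min Steps equating to 1 MVPA-MET-minute (default 34.5).
#' @return Weekly MVPA MET-minutes.
#' @examples
#' steps_to_met_minutes(1404)  # ~285 MET-min/week
#' @export
steps_to_met_minutes <- function(steps_per_day, steps_per_met_min = 34.5) {
  if (any(steps_per_day < 0)) stop("`steps_per_day` must be non-negative")
  if (any(steps_per_met_min <= 0)) stop("`steps_per_met_min` must be positive")
  steps_per_day * 7 / steps_per_met_min
}

#' Convert weekly MET-minutes to hours of activity at a given intensity
#'
#' @param met_min_per_week Weekly MVPA MET-minutes.
#' @param met_value MET intensity of the activity (brisk walking 3.0, moderate
#'   4.5, vigorous 6.5).
#' @return Hours per week of the activity.
#' @examples
#' met_minutes_to_activity_hours(285, 3.0)  # ~1.6 h/week brisk walking
#' @export
met_minutes_to_activity_hours <- function(met_min_per_week, met_value = 3.0) {
  if (any(met_value <= 0)) stop("`met_value` must be positive")
  met_min_per_week / met_value / 60
}

#' Construct a log-linear relative-risk function
#'
#' Dose-response for the protective association between weekly MVPA
#' MET-minutes and disease incidence: log-linear decline from `RR = 1` at the
#' anchor exposure down to a floor, i.e.
#' `RR(e) = max(floor, exp(-slope * (e - anchor)))` for `e >= anchor` and 1
#' below the anchor.
#'
#' @param disease Disease identifier.
#' @param slope Log-RR decline per MET-min/week (non-negative; 0 gives the
#'   null RR identically 1).
#' @param floor Lower bound on RR (default 0.5); must be in (0, 1].
#' @param anchor Exposure at which RR is anchored to 1 (default 0, the
#'   inactive bin).
#' @return An object of class `rr_function`.
#' @export
relative_risk_function <- function(disease, slope, floor = 0.5, anchor = 0) {
  if (slope < 0) stop("`slope` must be non-negative (protective dose-response)")
  if (floor <= 0 || floor > 1) stop("`floor` must be in (0, 1]")
  structure(list(disease = disease, slope = slope, floor = floor,
                 anchor = anchor),
            class = "rr_function")
}

#' Evaluate a relative-risk function at given exposures
#'
#' @param rr An [relative_risk_function()].
#' @param exposure Numeric vector of MET-min/week.
#' @return Relative risks in `[floor, 1]`.
#' @export
rr_evaluate <- function(rr, exposure) {
  stopifnot(inherits(rr, "rr_function"))
  pmax(rr$floor, exp(-rr$slope * pmax(exposure - rr$anchor, 0)))
}

#' @export
print.rr_function <- function(x, ...) {
  cat(sprintf("Relative-risk function for %s: log-linear slope %.3g per MET-min/week, floor %.2f\n",
              x$disease, x$slope, x$floor))
  invisible(x)
}

#' Shift an exposure distribution under an intervention
#'
#' A fraction of every bin's mass has its exposure increased by `delta`
#' MET-min/week: that mass is reassigned to the bin containing
#' `midpoint + delta` (the top bin absorbs overflow).  The unaffected mass is
#' untouched and total mass is conserved.
#'
#' @param dist An [exposure_distribution()] (business-as-usual).
#' @param delta Increase in weekly MET-minutes (non-negative).
#' @param affected_fraction Proportion of the population receiving the
#'   increase, in `[0, 1]`.
#' @return The counterfactual `exposure_dist` on the same bins.
#' @export
shift_distribution <- function(dist, delta, affected_fraction) {
  stopifnot(inherits(dist, "exposure_dist"))
  if (delta < 0) stop("`delta` must be non-negative; interventions only increase activity")
  if (affected_fraction < 0 || affected_fraction > 1)
    stop("`affected_fraction` must be in [0, 1]")
  if (affected_fraction == 0 || delta == 0) return(dist)
  n <- nrow(dist)
  # destination bin of each bin's shifted midpoint; top bin absorbs overflow
  dest <- findInterval(dist$midpoint + delta, dist$lower)
  dest <- pmin(dest, n)
  p <- dist$proportion * (1 - affected_fraction)
  moved <- dist$proportion * affected_fraction
  for (i in seq_len(n)) p[dest[i]] <- p[dest[i]] + moved[i]
  out <- dist
  out$proportion <- p
  out
}

#' Population impact fraction of an exposure shift
#'
#' The proportional reduction in disease incidence when the population
#' exposure distribution moves from business-as-usual `bau` to the
#' counterfactual `cf`:
#' \deqn{PIF = \frac{\sum_i p_i RR_i - \sum_i p'_i RR_i}{\sum_i p_i RR_i}}
#' with relative risks evaluated at bin midpoints.
#'
#' @param bau,cf [exposure_distribution()]s on identical bins.
#' @param rr An [relative_risk_function()].
#' @return The population impact fraction (at most 1; non-negative when `cf`
#'   stochastically dominates `bau` and RR is non-increasing).
#' @export
compute_pif <- function(bau, cf, rr) {
  stopifnot(inherits(bau, "exposure_dist"), inherits(cf, "exposure_dist"))
  if (nrow(bau) != nrow(cf) || any(bau$midpoint != cf$midpoint))
    stop("`bau` and `cf` must share the same bin structure")
  rrv <- rr_evaluate(rr, bau$midpoint)
  # constant RR (null dose-response): PIF is exactly 0 since both
  # distributions carry unit mass; short-circuit to keep the null exact
  if (all(rrv == rrv[1])) return(0)
  baseline <- sum(bau$proportion * rrv)
  (baseline - sum(cf$proportion * rrv)) / baseline
}

#' Lag window for the delayed effect of exposure change on incidence
#'
#' @param min_years,max_years Integer offsets (inclusive): disease incidence
#'   in a given year responds to the average population impact fraction over
#'   calendar years `year - max_years` to `year - min_years`.  Cardio-metabolic
#'   diseases use (0, 5); cancers use (10, 30).
#' @return An object of class `lag_spec`.
#' @export
lag_window <- function(min_years, max_years) {
  if (min_years < 0 || max_years <= min_years)
    stop("need 0 <= min_years < max_years")
  structure(list(min = as.integer(min_years), max = as.integer(max_years)),
            class = "lag_spec")
}

#' Effective (lagged) population impact fraction
#'
#' Unweighted mean of annual PIFs over the inclusive integer offsets of the
#' lag window, zero-padded before the start of the series: years before the
#' intervention contribute PIF 0.
#'
#' @param annual_pifs Numeric vector of annual PIFs, element 1 being calendar
#'   year 0 (intervention start).
#' @param lag A [lag_window()].
#' @param year Calendar year index (0-based, non-negative) at which the
#'   effective PIF is required; may be a vector.
#' @return Effective PIF(s).
#' @export
lag_pif_series <- function(annual_pifs, lag, year) {
  stopifnot(inherits(lag, "lag_spec"))
  if (any(year < 0)) stop("`year` must be non-negative")
  offsets <- lag$min:lag$max
  vapply(year, function(y) {
    src <- y - offsets
    vals <- ifelse(src >= 0 & src < length(annual_pifs),
                   annual_pifs[pmax(src, 0) + 1], 0)
    mean(vals)
  }, numeric(1))
}

# Lagged-PIF matrix over cohorts: annual (n x T) -> effective (n x T).
# Row-wise moving mean over inclusive offsets [min, max], zero-padded on the
# left, expressed as one banded matrix product.  Exact match with
# lag_pif_series().
.lag_pif_matrix <- function(annual, lag) {
  T <- ncol(annual)
  w <- lag$max - lag$min + 1L
  src <- matrix(seq_len(T) - 1L, T, T, byrow = TRUE) - (seq_len(T) - 1L)
  W <- matrix(0, T, T)
  W[src >= lag$min & src <= lag$max] <- 1 / w   # W[j, t]: year j feeds year t
  annual %*% W
}
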