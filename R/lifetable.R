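# Core disease life-table recursion over a set of cohorts.
#
# inc, cf, rem: rate vectors by single year of age (age 0 at index 1).
# a0: integer start ages (one cohort per element).
# pif_eff: n x T matrix of effective (lagged) PIFs applied to incidence, or
#   NULL for zeros (BAU).
# Transitions per annual cycle, in fixed order: case fatality, then remission,
# then incidence.  States are proportions of the cohort: H (never had or cured
# of the disease), P (prevalent), D (dead from the disease).
.disease_lifetable <- function(inc, cf, rem, a0, pif_eff = NULL,
                               horizon = 110L, max_age = 109L) {
  n <- length(a0)
  T <- as.integer(horizon)
  if (any(inc < 0 | inc > 1 | cf < 0 | cf > 1 | rem < 0 | rem > 1))
    stop("disease rates must lie in [0, 1]")
  # age-indexed rate matrices (cohorts x years), zero once a cohort ages out
  A <- outer(a0, 0:(T - 1L), `+`)
  valid <- A <= max_age
  idx <- pmin(A, max_age) + 1L
  Fm <- matrix(cf[idx], n, T);  Fm[!valid] <- 0
  Rm <- matrix(rem[idx], n, T); Rm[!valid] <- 0
  Im <- matrix(inc[idx], n, T); Im[!valid] <- 0
  if (!is.null(pif_eff)) {
    Im <- Im * (1 - pif_eff)
    if (any(Im > 1))
      stop("incidence x (1 - PIF) exceeds 1: rates are annual probabilities, not hazards")
  }
  H <- matrix(0, n, T + 1L); P <- matrix(0, n, T + 1L); D <- matrix(0, n, T + 1L)
  H[, 1] <- 1
  deaths <- matrix(0, n, T); newinc <- matrix(0, n, T)
  for (t in seq_len(T)) {
    h <- H[, t]; p <- P[, t]
    d_t <- p * Fm[, t]
    p1 <- p - d_t
    rem_t <- p1 * Rm[, t]
    ni <- (h + rem_t) * Im[, t]
    H[, t + 1L] <- h + rem_t - ni
    P[, t + 1L] <- p1 - rem_t + ni
    D[, t + 1L] <- D[, t] + d_t
    deaths[, t] <- d_t
    newinc[, t] <- ni
  }
  alive <- H[, seq_len(T), drop = FALSE] + P[, seq_len(T), drop = FALSE]
  denom <- alive
  denom[denom == 0] <- 1
  list(H = H, P = P, D = D, deaths = deaths, newinc = newinc,
       mort_rate = deaths / denom,
       prev_rate = P[, seq_len(T), drop = FALSE] / denom,
       a0 = a0, horizon = T)
}

#' Run one parallel disease life table
#'
#' Advances cohorts annually through the three-state disease process
#' (healthy/cured, prevalent, dead from the disease).  Within each cycle
#' transitions resolve in fixed order: case fatality, then remission (cancers
#' only), then incidence; incidence is scaled by `1 - PIF` where the effective
#' population impact fraction series is supplied.
#'
#' @param epi Data frame with columns `age` (0-109), `incidence`,
#'   `case_fatality`, `remission` for one disease in one stratum.
#' @param pif_series Optional numeric vector of effective PIFs by year
#'   (recycled over cohorts), or matrix (cohorts x years).
#' @param a0 Integer cohort start ages (default a single birth cohort).
#' @param horizon Number of annual cycles.
#' @return Object of class `disease_lifetable`: state proportion matrices
#'   `H`, `P`, `D` (cohorts x years+1, start-of-cycle), flow matrices
#'   `deaths`, `newinc`, and the per-cycle `mort_rate` and `prev_rate` among
#'   those alive within the disease table.
#' @export
run_disease_lifetable <- function(epi, pif_series = NULL, a0 = 0L,
                                  horizon = 110L) {
  stopifnot(all(c("age", "incidence", "case_fatality", "remission") %in% names(epi)))
  epi <- epi[order(epi$age), ]
  if (!identical(as.integer(epi$age), 0:109))
    stop("`epi` must cover single years of age 0-109")
  pif <- NULL
  if (!is.null(pif_series)) {
    if (is.matrix(pif_series)) pif <- pif_series
    else pif <- matrix(rep(pif_series, length.out = horizon),
                       nrow = length(a0), ncol = horizon, byrow = TRUE)
    if (any(pif > 1)) stop("effective PIFs must not exceed 1")
  }
  out <- .disease_lifetable(epi$incidence, epi$case_fatality, epi$remission,
                            a0 = as.integer(a0), pif_eff = pif,
                            horizon = horizon)
  class(out) <- "disease_lifetable"
  out
}

#' Feed disease flows back into all-cause mortality and morbidity
#'
#' The proportional MSLT adjustment: the intervention's all-cause mortality is
#' the baseline rate minus the summed change (BAU minus intervention) in
#' disease-specific mortality rates; morbidity (pYLD) is adjusted the same way
#' using disease disability weights on prevalence rates.  Adjusted rates are
#' clipped to `[0, 1)` and clip events counted.
#'
#' @param q_base,pyld_base Baseline all-cause mortality and pYLD (vectors or
#'   matrices over cohorts x years).
#' @param tables_bau,tables_int Lists of disease life tables (one per
#'   disease) from [run_disease_lifetable()] under each scenario.
#' @param weights Named disability weights, one per disease, aligned with the
#'   table lists.
#' @return List with `q`, `pyld` (adjusted, same shape as the baselines) and
#'   `clips` (number of clipped cells).
#' @export
recompute_mortality_morbidity <- function(q_base, pyld_base,
                                          tables_bau, tables_int, weights) {
  stopifnot(length(tables_bau) == length(tables_int),
            length(weights) == length(tables_bau))
  dq <- 0; dp <- 0
  for (k in seq_along(tables_bau)) {
    dq <- dq + (tables_bau[[k]]$mort_rate - tables_int[[k]]$mort_rate)
    dp <- dp + weights[[k]] *
      (tables_bau[[k]]$prev_rate - tables_int[[k]]$prev_rate)
  }
  q <- q_base - dq
  pyld <- pyld_base - dp
  clips <- sum(q < 0 | q > 1, na.rm = TRUE) +
    sum(pyld < 0 | pyld >= 1, na.rm = TRUE)
  q <- pmin(pmax(q, 0), 1)
  pyld <- pmin(pmax(pyld, 0), 1 - 1e-12)
  list(q = q, pyld = pyld, clips = clips)
}

#' Present value of an annual series
#'
#' Discrete annual discounting: `sum(v_t / (1 + rate)^(t - base_year))` with
#' `t` starting at 0, so the base year is undiscounted.
#'
#' @param series Numeric vector, element 1 being year 0.
#' @param rate Annual discount rate (non-negative proportion; default 0.03).
#' @param base_year Year to which values are discounted (default 0).
#' @return Present value (scalar).
#' @export
discount <- function(series, rate = 0.03, base_year = 0) {
  if (rate < 0) stop("`rate` must be non-negative")
  t <- seq_along(series) - 1
  sum(series / (1 + rate)^(t - base_year))
}

# Per-stratum scenario sweep: main + parallel disease life tables for every
# 2011 cohort (start ages 0..109) in one stratum.
#
# pop_s: demography rows for the stratum (ordered by age).
# epi_s: list of per-disease epi data frames for the stratum.
# pif_eff: named list of n x T effective-PIF matrices (NULL for BAU).
# adjust_from: for the intervention scenario, the BAU disease tables, so
#   all-cause rates can be recomputed from the flow differences.
.scenario_sweep <- function(pop_s, epi_s, diseases, pif_eff = NULL,
                            adjust_from = NULL, horizon = 110L) {
  a0 <- 0:109
  n <- length(a0); T <- horizon
  A <- outer(a0, 0:(T - 1L), `+`)          # age of cohort c at year t
  valid <- A <= 109L
  idx <- pmin(A, 109L) + 1L

  lts <- lapply(diseases$disease, function(d) {
    e <- epi_s[[d]]
    .disease_lifetable(e$incidence, e$case_fatality, e$remission, a0 = a0,
                       pif_eff = if (is.null(pif_eff)) NULL else pif_eff[[d]],
                       horizon = T)
  })
  names(lts) <- diseases$disease

  q_base <- matrix(pop_s$mortality[idx], n, T)
  pyld_base <- matrix(pop_s$pyld[idx], n, T)
  clips <- 0L
  if (is.null(adjust_from)) {
    q <- q_base; pyld <- pyld_base
  } else {
    w <- stats::setNames(diseases$disability_weight, diseases$disease)
    adj <- recompute_mortality_morbidity(q_base, pyld_base,
                                         adjust_from, lts, w)
    q <- adj$q; pyld <- adj$pyld; clips <- adj$clips
  }
  q[!valid] <- 1   # cohorts extinct beyond age 109

  l <- matrix(0, n, T + 1L)
  l[, 1] <- 1
  for (t in seq_len(T)) l[, t + 1L] <- l[, t] * (1 - q[, t])
  ls <- l[, seq_len(T), drop = FALSE]
  ly <- ls * valid                          # person-years: alive at cycle start
  qaly <- ly * (1 - pyld)

  # Disease event counts in persons: the disease table's rates (among its own
  # alive) applied to the main table's survivors and the stratum counts.
  N <- pop_s$count
  dstreams <- lapply(lts, function(lt) {
    alive <- lt$H[, seq_len(T)] + lt$P[, seq_len(T)]
    alive[alive == 0] <- 1
    case_rate <- lt$newinc / alive
    list(cases  = case_rate * ly * N,
         prevpy = lt$prev_rate * ly * N,
         deaths = lt$mort_rate * ly * N)
  })

  list(l = l, ly = ly, qaly = qaly, q = q, pyld = pyld,
       disease = dstreams, tables = lts, clips = clips)
}

# Effective lagged PIF matrices per disease for one stratum.
#
# The annual PIF is a per-disease scalar (the BAU-vs-counterfactual shift is
# the same for all eligible ages within a stratum), switched on for calendar
# years < effect_duration and cohort ages inside the eligibility window, then
# averaged over the disease's lag window.
.build_pif_matrices <- function(bau_dist, intervention, rr, diseases,
                                horizon = 110L) {
  a0 <- 0:109
  A <- outer(a0, 0:(horizon - 1L), `+`)
  elig <- A >= intervention$eligible_ages[1] & A <= intervention$eligible_ages[2]
  on_years <- matrix(rep(0:(horizon - 1L) < intervention$effect_duration,
                         each = length(a0)), length(a0), horizon)
  cf <- counterfactual_distribution(bau_dist, intervention)
  out <- lapply(seq_len(nrow(diseases)), function(k) {
    d <- diseases$disease[k]
    pif_d <- compute_pif(bau_dist, cf, rr[[d]])
    annual <- pif_d * (elig & on_years)
    .lag_pif_matrix(annual, lag_window(diseases$lag_min[k], diseases$lag_max[k]))
  })
  names(out) <- diseases$disease
  out
}

#' Run the proportional multistate life table under BAU and intervention
#'
#' Advances every 2011 cohort (start ages 0-109) in every stratum annually
#' through the main all-cause life table and the five parallel disease life
#' tables, under business-as-usual and, if an intervention is supplied, under
#' the counterfactual exposure shift.  The BAU scenario never depends on the
#' intervention parameters.
#'
#' @param inputs An [synthetic_inputs()] bundle (or equivalent structure).
#' @param intervention An [intervention_spec()], or `NULL` for BAU only.
#' @param horizon Number of annual cycles (default 110: all cohorts extinct).
#' @return Object of class `mslt_run`: per-stratum cohort-level life-year and
#'   QALY matrices for both scenarios, per-disease annual case / prevalent
#'   person-year / death streams (in persons), cohort counts and clip counts.
#' @export
run_mslt <- function(inputs, intervention = NULL, horizon = 110L) {
  stopifnot(inherits(inputs, "mslt_inputs") || is.list(inputs))
  bau <- .mslt_bau(inputs, horizon)
  int <- if (!is.null(intervention))
    .mslt_intervention(inputs, intervention, bau, horizon)
  structure(list(bau = bau, int = int, intervention = intervention,
                 horizon = horizon, strata = names(bau$strata)),
            class = "mslt_run")
}

.stratum_epi_list <- function(inputs, s) {
  out <- lapply(inputs$diseases$disease, function(d) {
    e <- inputs$epi[inputs$epi$disease == d & inputs$epi$stratum == s, ]
    if (nrow(e) == 0) stop("missing disease epi for stratum ", s, ", disease ", d)
    e[order(e$age), ]
  })
  names(out) <- inputs$diseases$disease
  out
}

.mslt_bau <- function(inputs, horizon = 110L) {
  strata <- unique(inputs$population$stratum)
  res <- lapply(strata, function(s) {
    pop_s <- inputs$population[inputs$population$stratum == s, ]
    pop_s <- pop_s[order(pop_s$age), ]
    if (nrow(pop_s) != 110) stop("missing ages in population for stratum ", s)
    sweep <- .scenario_sweep(pop_s, .stratum_epi_list(inputs, s),
                             inputs$diseases, horizon = horizon)
    sweep$N <- pop_s$count
    sweep
  })
  names(res) <- strata
  list(strata = res)
}

.mslt_intervention <- function(inputs, intervention, bau, horizon = 110L) {
  strata <- names(bau$strata)
  res <- lapply(strata, function(s) {
    if (is.null(inputs$exposure[[s]]))
      stop("missing exposure distribution for stratum ", s)
    pop_s <- inputs$population[inputs$population$stratum == s, ]
    pop_s <- pop_s[order(pop_s$age), ]
    pifs <- .build_pif_matrices(inputs$exposure[[s]], intervention,
                                inputs$costs$rr, inputs$diseases, horizon)
    sweep <- .scenario_sweep(pop_s, .stratum_epi_list(inputs, s),
                             inputs$diseases, pif_eff = pifs,
                             adjust_from = bau$strata[[s]]$tables,
                             horizon = horizon)
    sweep$N <- pop_s$count
    sweep
  })
  names(res) <- strata
  list(strata = res)
}

#' Total annual streams from a run
#'
#' @param run An [run_mslt()] result.
#' @param scenario `"bau"` or `"int"`.
#' @param what `"qaly"` or `"ly"`.
#' @return Numeric vector by calendar year (persons x years).
#' @export
annual_totals <- function(run, scenario = c("bau", "int"),
                          what = c("qaly", "ly")) {
  scenario <- match.arg(scenario); what <- match.arg(what)
  sc <- run[[scenario]]
  if (is.null(sc)) stop("run has no ", scenario, " scenario")
  Reduce(`+`, lapply(sc$strata, function(st) colSums(st[[what]] * st$N)))
}

#' @export
print.mslt_run <- function(x, ...) {
  cat("Proportional multistate life table run\n")
  cat(sprintf("  strata: %s\n", paste(x$strata, collapse = ", ")))
  cat(sprintf("  horizon: %d annual cycles\n", x$horizon))
  if (!is.null(x$int)) {
    gain <- sum(annual_totals(x, "int") - annual_totals(x, "bau"))
    cat(sprintf("  undiscounted lifetime QALY gain: %.2f\n", gain))
    clips <- sum(vapply(x$int$strata, function(s) s$clips, numeric(1)))
    if (clips > 0) cat(sprintf("  WARNING: %d rate cells clipped to [0, 1)\n", clips))
  } else cat("  BAU only\n")
  invisible(x)
}
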