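# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Stratification specification for the modelled population
#'
#' The population is a closed 2011-style cohort stratified by sex, ethnicity
#' (an indigenous group with elevated background mortality, and the rest) and
#' single year of age 0-109; 5-year age bands are used for reporting and for
#' the intervention eligibility window.
#'
#' @param age_band_edges Integer band edges covering `[0, 110)`, default
#'   5-year bands.
#' @param sexes,ethnicities Character vectors of stratum labels.
#' @return An object of class `strata_spec`.
#' @export
strata_spec <- function(age_band_edges = seq(0, 110, by = 5),
                        sexes = c("male", "female"),
                        ethnicities = c("indigenous", "other")) {
  edges <- as.integer(age_band_edges)
  if (length(edges) < 2 || is.unsorted(edges, strictly = TRUE))
    stop("configuration error: age band edges must be strictly increasing")
  if (edges[1] != 0 || edges[length(edges)] != 110)
    stop("configuration error: age bands must cover [0, 110)")
  if (length(sexes) < 1 || length(ethnicities) < 1)
    stop("configuration error: need at least one stratum per sex x ethnicity")
  structure(list(age_band_edges = edges, sexes = sexes,
                 ethnicities = ethnicities, max_age = 109L),
            class = "strata_spec")
}

.strata_ids <- function(spec) {
  g <- expand.grid(sex = spec$sexes, ethnicity = spec$ethnicities,
                   stringsAsFactors = FALSE)
  g$stratum <- paste(g$sex, g$ethnicity, sep = "_")
  g
}

#' Synthetic-data scenario: the generator's parameter set
#'
#' Defines the stated world of the generator: a closed population of 4.4
#' million (2011 New Zealand scale) with Gompertz-Makeham background
#' mortality, an indigenous-vs-other mortality gap, rising morbidity (pYLD),
#' five physical-activity-related diseases, zero-inflated log-normal weekly
#' MVPA MET-minute exposure calibrated so 42% of adults fall below the
#' 150-min/week guideline (450 MET-min at 3.0 MET), log-linear protective
#' relative risks and phase-based disease costs.
#'
#' @param seed Integer RNG seed; identical scenarios produce byte-identical
#'   tables.
#' @param population_size Total persons across all strata and ages.
#' @param mortality_params Gompertz-Makeham parameters: `makeham` (age-free
#'   hazard), `b`, `g` (Gompertz level and log-slope per year), `female_mult`,
#'   `indigenous_mult` (rate multipliers), `cap`.
#' @param morbidity_params Prevalent years-lived-with-disability curve
#'   `pyld(a) = p0 + p2 (a/100)^2`, indigenous multiplier, cap.
#' @param pa_params Exposure distribution parameters: `zero_inflation`,
#'   `sdlog`, additive meanlog offsets by sex/ethnicity, per-stratum jitter
#'   SD, calibration `target` (adult proportion below `threshold`
#'   MET-min/week) and tolerance.
#' @param rr_params Relative risk at `ref_exposure` MET-min/week per disease,
#'   a common `scale` on the log-slopes (0 gives the null RR = 1), and floor.
#' @param cost_params Phase-cost scale multiplier and unrelated-cost curve
#'   `unrelated(a) = base * exp(growth * a)`.
#' @return An object of class `mslt_scenario` (a validated parameter list).
#' @export
synthetic_scenario <- function(seed = 1L,
                               population_size = 4.4e6,
                               mortality_params = list(),
                               morbidity_params = list(),
                               pa_params = list(),
                               rr_params = list(),
                               cost_params = list()) {
  mp <- utils::modifyList(list(makeham = 2e-4, b = 3e-5, g = 0.095,
                               female_mult = 0.8, indigenous_mult = 1.6,
                               cap = 0.95), mortality_params)
  mo <- utils::modifyList(list(p0 = 0.03, p2 = 0.12, indigenous_mult = 1.3,
                               cap = 0.8), morbidity_params)
  pa <- utils::modifyList(list(zero_inflation = 0.10, sdlog = 1.15,
                               male_offset = 0.15, indigenous_offset = -0.12,
                               jitter_sd = 0.04, target = 0.42,
                               threshold = 450, tol = 1e-10),
                          pa_params)
  rr <- utils::modifyList(list(ref_exposure = 600, scale = 1, floor = 0.5,
                               rr_at_ref = c(chd = 0.90, stroke = 0.92,
                                             t2dm = 0.88, colorectal_cancer = 0.94,
                                             breast_cancer = 0.95)),
                          rr_params)
  co <- utils::modifyList(list(scale = 1, stratum_sd = 0.08,
                               unrelated_base = 1200, unrelated_growth = 0.025),
                          cost_params)
  if (population_size <= 0) stop("configuration error: population_size must be positive")
  if (mp$b <= 0 || mp$g <= 0) stop("configuration error: Gompertz parameters must be positive")
  structure(list(seed = as.integer(seed), population_size = population_size,
                 mortality = mp, morbidity = mo, pa = pa, rr = rr, costs = co),
            class = "mslt_scenario")
}

# All-cause annual mortality risk by single year of age for one stratum.
.mortality_curve <- function(ages, sex, ethnicity, mp) {
  mult <- (if (sex == "female") mp$female_mult else 1) *
    (if (ethnicity == "indigenous") mp$indigenous_mult else 1)
  pmin(mp$cap, mult * (mp$makeham + mp$b * exp(mp$g * ages)))
}

.pyld_curve <- function(ages, ethnicity, mo) {
  mult <- if (ethnicity == "indigenous") mo$indigenous_mult else 1
  pmin(mo$cap, mult * (mo$p0 + mo$p2 * (ages / 100)^2))
}

#' Generate the synthetic demography table
#'
#' Per-stratum population counts by single year of age with all-cause
#' mortality and morbidity (pYLD) rates.  Mortality is Gompertz-Makeham with
#' sex and ethnicity multipliers, so it is monotone in age by construction
#' and indigenous strata have mortality at least as high as other strata at
#' every age.
#'
#' @param spec A [strata_spec()].
#' @param scenario A [synthetic_scenario()].
#' @return A data frame with columns `stratum`, `sex`, `ethnicity`, `age`,
#'   `count`, `mortality`, `pyld`.
#' @export
generate_demography <- function(spec = strata_spec(),
                                scenario = synthetic_scenario()) {
  stopifnot(inherits(spec, "strata_spec"), inherits(scenario, "mslt_scenario"))
  ages <- 0:spec$max_age
  g <- .strata_ids(spec)
  indig_share <- 0.15
  rows <- lapply(seq_len(nrow(g)), function(k) {
    sex <- g$sex[k]; eth <- g$ethnicity[k]
    # indigenous population is younger on average (logistic age taper)
    mid <- if (eth == "indigenous") 50 else 65
    w <- 1 / (1 + exp((ages - mid) / 10))
    share <- (if (eth == "indigenous") indig_share else 1 - indig_share) /
      length(spec$sexes)
    data.frame(stratum = g$stratum[k], sex = sex, ethnicity = eth, age = ages,
               count = scenario$population_size * share * w / sum(w),
               mortality = .mortality_curve(ages, sex, eth, scenario$mortality),
               pyld = .pyld_curve(ages, eth, scenario$morbidity))
  })
  do.call(rbind, rows)
}

# Canonical disease metadata for the five active PA-related diseases.
.disease_meta <- function() {
  data.frame(
    disease     = c("chd", "stroke", "t2dm", "colorectal_cancer", "breast_cancer"),
    is_cancer   = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    female_only = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    disability_weight = c(0.08, 0.22, 0.07, 0.12, 0.09),
    lag_min     = c(0L, 0L, 0L, 10L, 10L),
    lag_max     = c(5L, 5L, 5L, 30L, 30L),
    stringsAsFactors = FALSE
  )
}

# Per-disease epi shape parameters: incidence/case-fatality at age 60 with
# exponential age slopes, remission for cancers, sex and ethnicity rate
# multipliers, and the first age of incidence.
.disease_params <- function() {
  list(
    chd        = list(i0 = 0.004,  ik = 0.07, f0 = 0.035, fk = 0.05, rem = 0,
                      start = 20, male_mult = 1.5, indig_mult = 1.3),
    stroke     = list(i0 = 0.0015, ik = 0.08, f0 = 0.05,  fk = 0.05, rem = 0,
                      start = 20, male_mult = 1.2, indig_mult = 1.3),
    t2dm       = list(i0 = 0.006,  ik = 0.03, f0 = 0.008, fk = 0.04, rem = 0,
                      start = 20, male_mult = 1.1, indig_mult = 1.4),
    colorectal_cancer = list(i0 = 0.0008, ik = 0.07, f0 = 0.05, fk = 0.03,
                      rem = 0.08, start = 25, male_mult = 1.2, indig_mult = 1.1),
    breast_cancer     = list(i0 = 0.0018, ik = 0.02, f0 = 0.035, fk = 0.03,
                      rem = 0.10, start = 25, male_mult = 0, indig_mult = 1.1)
  )
}

#' Generate synthetic disease epidemiology
#'
#' Incidence, case fatality and (cancers only) remission rates by stratum and
#' single year of age for CHD, stroke, type 2 diabetes, colorectal cancer and
#' breast cancer (female strata only).  Rates rise exponentially with age from
#' a reference value at age 60.  After generation, each stratum's implied
#' disease-specific mortality (from a birth-cohort sweep of the parallel
#' disease life tables) is audited against all-cause mortality; if the summed
#' disease mortality would exceed 90% of all-cause mortality in any cell the
#' rates are damped by 20% and the audit retried, erroring after five rounds.
#'
#' @inheritParams generate_demography
#' @param population Demography table from [generate_demography()];
#'   regenerated if omitted.
#' @return A list with `epi` (data frame: `disease`, `stratum`, `age`,
#'   `incidence`, `case_fatality`, `remission`) and `diseases` (metadata:
#'   disability weights, lag windows, cancer and sex flags).
#' @export
generate_disease_epi <- function(spec = strata_spec(),
                                 scenario = synthetic_scenario(),
                                 population = generate_demography(spec, scenario)) {
  meta <- .disease_meta()
  pars <- .disease_params()
  ages <- 0:spec$max_age
  g <- .strata_ids(spec)

  build <- function(damp) {
    rows <- list()
    for (d in meta$disease) {
      p <- pars[[d]]
      for (k in seq_len(nrow(g))) {
        sex <- g$sex[k]; eth <- g$ethnicity[k]
        if (meta$female_only[meta$disease == d] && sex != "female") {
          inc <- cf <- rem <- rep(0, length(ages))
        } else {
          mult <- (if (sex == "male") p$male_mult else 1) *
            (if (eth == "indigenous") p$indig_mult else 1)
          inc <- damp * mult * p$i0 * exp(p$ik * (ages - 60))
          inc[ages < p$start] <- 0
          inc <- pmin(inc, 0.25)
          cf <- damp * p$f0 * exp(p$fk * (ages - 60))
          cf <- pmin(cf, 0.45)
          rem <- rep(p$rem, length(ages))
        }
        rows[[length(rows) + 1]] <- data.frame(
          disease = d, stratum = g$stratum[k], age = ages,
          incidence = inc, case_fatality = cf, remission = rem)
      }
    }
    do.call(rbind, rows)
  }

  damp <- 1
  for (round in 1:5) {
    epi <- build(damp)
    if (.audit_disease_mortality(epi, population, meta, margin = 0.9))
      return(list(epi = epi, diseases = meta))
    damp <- damp * 0.8
  }
  stop("disease epi generation failed: implied disease mortality exceeds ",
       "all-cause mortality even after damping")
}

# TRUE iff summed implied disease-specific mortality stays below
# margin * all-cause mortality in every stratum-age cell, assessed on a
# birth cohort (the worst case for accumulated prevalence).
.audit_disease_mortality <- function(epi, population, meta, margin = 0.9) {
  for (s in unique(population$stratum)) {
    pop_s <- population[population$stratum == s, ]
    total_rate <- rep(0, nrow(pop_s))
    for (d in meta$disease) {
      e <- epi[epi$disease == d & epi$stratum == s, ]
      lt <- .disease_lifetable(e$incidence, e$case_fatality, e$remission,
                               a0 = 0L)
      total_rate <- total_rate + as.numeric(lt$mort_rate[1, seq_len(nrow(pop_s))])
    }
    if (any(total_rate > margin * pop_s$mortality)) return(FALSE)
  }
  TRUE
}

# Bin a zero-inflated log-normal exposure onto the categorical grid.
.bin_lognormal <- function(meanlog, sdlog, zero_inflation,
                           bins = default_exposure_bins()) {
  n <- nrow(bins)
  p <- numeric(n)
  cdf <- stats::plnorm(c(bins$lower[-1], Inf), meanlog, sdlog)
  p[1] <- zero_inflation + (1 - zero_inflation) * cdf[1]
  p[2:n] <- (1 - zero_inflation) * diff(cdf)
  p / sum(p)
}

#' Proportion of an exposure distribution below a threshold
#'
#' Bins entirely below the threshold count fully; a bin straddling it counts
#' in proportion to the overlap (uniform-within-bin interpolation, with the
#' unbounded top bin treated as ending at twice its midpoint).
#'
#' @param dist An [exposure_distribution()].
#' @param threshold MET-min/week cut-point (default 450 = 150 min/week at
#'   3.0 MET, the guideline minimum).
#' @return Proportion of mass below `threshold`.
#' @export
prop_below_threshold <- function(dist, threshold = 450) {
  upper <- ifelse(is.finite(dist$upper), dist$upper, 2 * dist$midpoint)
  frac <- pmin(1, pmax(0, (threshold - dist$lower) / (upper - dist$lower)))
  sum(dist$proportion * frac)
}

#' Generate per-stratum physical-activity exposure distributions
#'
#' Weekly MVPA MET-minute distributions per sex-ethnicity stratum:
#' zero-inflated log-normal binned onto the categorical grid, with seeded
#' per-stratum jitter, calibrated by a global location shift so that the
#' population-weighted proportion of adults (15-79) below the guideline
#' threshold hits the scenario target (default 42% below 450 MET-min/week).
#'
#' @inheritParams generate_disease_epi
#' @return Named list of [exposure_distribution()]s, one per stratum.
#' @export
generate_pa_distribution <- function(spec = strata_spec(),
                                     scenario = synthetic_scenario(),
                                     population = generate_demography(spec, scenario)) {
  pa <- scenario$pa
  g <- .strata_ids(spec)
  jit <- .with_seed(scenario$seed + 211L,
                    stats::rnorm(nrow(g), 0, pa$jitter_sd))
  mus <- vapply(seq_len(nrow(g)), function(k) {
    (if (g$sex[k] == "male") pa$male_offset else 0) +
      (if (g$ethnicity[k] == "indigenous") pa$indigenous_offset else 0) +
      jit[k]
  }, numeric(1))
  adult <- population$age >= 15 & population$age <= 79
  w <- vapply(g$stratum, function(s)
    sum(population$count[adult & population$stratum == s]), numeric(1))
  w <- w / sum(w)

  insufficient <- function(shift) {
    ps <- vapply(seq_len(nrow(g)), function(k) {
      p <- .bin_lognormal(mus[k] + shift, pa$sdlog, pa$zero_inflation)
      prop_below_threshold(exposure_distribution(p), pa$threshold)
    }, numeric(1))
    sum(w * ps)
  }
  root <- tryCatch(
    stats::uniroot(function(s) insufficient(s) - pa$target,
                   lower = 0, upper = 14, extendInt = "yes",
                   tol = pa$tol, maxiter = 200),
    error = function(e) stop("exposure calibration failed for strata ",
                             paste(g$stratum, collapse = ", "), ": ",
                             conditionMessage(e)))
  out <- lapply(seq_len(nrow(g)), function(k)
    exposure_distribution(.bin_lognormal(mus[k] + root$root, pa$sdlog,
                                         pa$zero_inflation)))
  names(out) <- g$stratum
  out
}

#' Generate disease costs and relative-risk functions
#'
#' Phase-based disease costs (first year after incidence, subsequent prevalent
#' years, last 6 months of life) per disease and stratum, with a seeded
#' stratum-level multiplier applied to all three phases so the generator's
#' ordering constraint (last-6-months cost at least the subsequent-year cost)
#' holds by construction; a per-capita unrelated annual health-system cost
#' rising exponentially with age; and one log-linear
#' [relative_risk_function()] per disease, anchored at the inactive bin.
#'
#' @inheritParams generate_demography
#' @param diseases Disease metadata from [generate_disease_epi()].
#' @return List with `disease_costs` (data frame: `disease`, `stratum`,
#'   `cost_first_year`, `cost_subsequent_year`, `cost_last6m`), `unrelated`
#'   (data frame: `age`, `cost`), and `rr` (named list of `rr_function`s).
#' @export
generate_costs_and_rr <- function(spec = strata_spec(),
                                  scenario = synthetic_scenario(),
                                  diseases = .disease_meta()) {
  co <- scenario$costs
  base <- data.frame(
    disease = c("chd", "stroke", "t2dm", "colorectal_cancer", "breast_cancer"),
    cost_first_year      = c(12000, 18000, 4000, 32000, 28000),
    cost_subsequent_year = c(2200,  4500,  1600, 4800,  3500),
    cost_last6m          = c(25000, 30000, 15000, 45000, 40000)
  )
  g <- .strata_ids(spec)
  mult <- .with_seed(scenario$seed + 409L,
                     exp(stats::rnorm(nrow(g), 0, co$stratum_sd)))
  rows <- lapply(seq_len(nrow(g)), function(k) {
    b <- base
    b$stratum <- g$stratum[k]
    b[c("cost_first_year", "cost_subsequent_year", "cost_last6m")] <-
      b[c("cost_first_year", "cost_subsequent_year", "cost_last6m")] *
      mult[k] * co$scale
    b
  })
  disease_costs <- do.call(rbind, rows)

  ages <- 0:spec$max_age
  unrelated <- data.frame(age = ages,
                          cost = co$unrelated_base * exp(co$unrelated_growth * ages))

  rrp <- scenario$rr
  rr <- lapply(diseases$disease, function(d) {
    slope <- -log(rrp$rr_at_ref[[d]]) * rrp$scale / rrp$ref_exposure
    relative_risk_function(d, slope = slope, floor = rrp$floor)
  })
  names(rr) <- diseases$disease
  list(disease_costs = disease_costs, unrelated = unrelated, rr = rr)
}

#' Assemble the full synthetic input bundle
#'
#' Runs all four generators under one scenario and returns the inputs the
#' life-table engine consumes.
#'
#' @inheritParams generate_demography
#' @return An object of class `mslt_inputs`: list with `population`, `epi`,
#'   `diseases`, `exposure`, `costs`, `spec`, `scenario`.
#' @examples
#' inputs <- synthetic_inputs(synthetic_scenario(seed = 1))
#' inputs
#' @export
synthetic_inputs <- function(scenario = synthetic_scenario(),
                             spec = strata_spec()) {
  population <- generate_demography(spec, scenario)
  de <- generate_disease_epi(spec, scenario, population)
  exposure <- generate_pa_distribution(spec, scenario, population)
  costs <- generate_costs_and_rr(spec, scenario, de$diseases)
  structure(list(population = population, epi = de$epi,
                 diseases = de$diseases, exposure = exposure,
                 costs = costs, spec = spec, scenario = scenario),
            class = "mslt_inputs")
}

#' @export
print.mslt_inputs <- function(x, ...) {
  adult <- x$population$age >= 15 & x$population$age <= 79
  cat("Multistate life table inputs\n")
  cat(sprintf("  population: %s persons in %d strata, ages 0-%d\n",
              format(round(sum(x$population$count)), big.mark = ","),
              length(unique(x$population$stratum)), max(x$population$age)))
  cat(sprintf("  diseases: %s\n", paste(x$diseases$disease, collapse = ", ")))
  ins <- vapply(names(x$exposure), function(s) prop_below_threshold(x$exposure[[s]]),
                numeric(1))
  w <- vapply(names(x$exposure), function(s)
    sum(x$population$count[adult & x$population$stratum == s]), numeric(1))
  cat(sprintf("  adults below 450 MET-min/week: %.1f%%\n",
              100 * sum(w * ins) / sum(w)))
  invisible(x)
}
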