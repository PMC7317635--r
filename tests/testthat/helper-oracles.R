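# Independent oracles and shared fixtures for the test suite.  Everything
# here is implemented from first principles (explicit sums, matrix powering,
# individual-level simulation) so it never shares code paths with the package
# functions it checks.

# Brute-force expected-risk PIF: explicit elementwise sum over bins.
pif_oracle <- function(p_bau, p_cf, rr_values) {
  num <- 0; den <- 0
  for (i in seq_along(p_bau)) {
    den <- den + p_bau[i] * rr_values[i]
    num <- num + (p_bau[i] - p_cf[i]) * rr_values[i]
  }
  num / den
}

# Exhaustive Markov-chain evaluation of the three-state disease process
# (H healthy/cured, P prevalent, D dead-from-disease) for a single cohort
# starting at age 0, with the package's fixed within-cycle order: case
# fatality, then remission, then incidence (remitted mass can be re-incident
# within the cycle).  Returns start-of-cycle state vectors, rows = years.
markov_disease_oracle <- function(inc, cf, rem, pif_eff, horizon) {
  states <- matrix(0, horizon + 1, 3, dimnames = list(NULL, c("H", "P", "D")))
  states[1, ] <- c(1, 0, 0)
  v <- c(1, 0, 0)
  for (t in seq_len(horizon)) {
    i <- inc[t] * (1 - pif_eff[t]); f <- cf[t]; r <- rem[t]
    M <- rbind(
      H = c(1 - i,                                i,                    0),
      P = c((1 - f) * r * (1 - i), (1 - f) * (1 - r) + (1 - f) * r * i, f),
      D = c(0,                                    0,                    1))
    v <- as.numeric(v %*% M)
    states[t + 1, ] <- v
  }
  states
}

# Individual-level microsimulation of the same process for one cohort of m
# persons over `horizon` cycles, death only through the disease (background
# mortality zero), utility 1 - w * 1{prevalent} accrued by everyone alive at
# the start of a cycle.  Returns per-person QALY totals under BAU and under
# a PIF-modified incidence, using common random numbers so the paired
# difference is a sharp estimate of the health gain.
microsim_oracle <- function(m, inc, cf, rem, pif_eff, w, horizon, seed) {
  set.seed(seed)
  run_one <- function(i_eff, u_f, u_r, u_i) {
    state <- integer(m)                    # 0 = H, 1 = P, 2 = dead
    qaly <- numeric(m)
    for (t in seq_len(horizon)) {
      alive <- state < 2L
      qaly <- qaly + alive * (1 - w * (state == 1L))
      dies <- state == 1L & u_f[, t] < cf[t]
      state[dies] <- 2L
      remits <- state == 1L & !dies & u_r[, t] < rem[t]
      state[remits] <- 0L
      incid <- state == 0L & u_i[, t] < i_eff[t]
      state[incid] <- 1L
    }
    qaly
  }
  u_f <- matrix(runif(m * horizon), m, horizon)
  u_r <- matrix(runif(m * horizon), m, horizon)
  u_i <- matrix(runif(m * horizon), m, horizon)
  bau <- run_one(inc, u_f, u_r, u_i)
  int <- run_one(inc * (1 - pif_eff), u_f, u_r, u_i)
  list(bau = bau, int = int)
}

# One-stratum, one-disease, three-age toy instance on which the proportional
# MSLT is exact: background (non-disease) mortality is zero, baseline
# all-cause mortality is defined as the oracle disease mortality, and
# baseline pYLD as the disability-weighted oracle prevalence, so the additive
# mortality/morbidity feedback introduces no approximation.
toy_instance <- function(inc3 = c(0.30, 0.25, 0.20),
                         cf3 = c(0.10, 0.15, 0.20),
                         rem3 = c(0.05, 0.05, 0.05),
                         w = 0.3) {
  ages <- 0:109
  # disease transitions act in years 0-2; everyone alive at the start of
  # year 3 accrues that final year and dies of background causes in it
  inc4 <- c(inc3, 0); cf4 <- c(cf3, 0); rem4 <- c(rem3, 0)
  inc <- c(inc4, rep(0, 106)); cf <- c(cf4, rep(0, 106))
  rem <- c(rem4, rep(0, 106))
  st <- markov_disease_oracle(inc4, cf4, rem4, rep(0, 4), 4)
  alive <- st[1:4, "H"] + st[1:4, "P"]
  mort_rate <- (st[2:5, "D"] - st[1:4, "D"]) / alive
  prev_rate <- st[1:4, "P"] / alive
  population <- data.frame(
    stratum = "toy_other", sex = "female", ethnicity = "other", age = ages,
    count = c(1, rep(0, 109)),
    mortality = c(mort_rate[1:3], rep(1, 107)),
    pyld = c(w * prev_rate, rep(0, 106)))
  diseases <- data.frame(disease = "toy", is_cancer = FALSE,
                         female_only = FALSE, disability_weight = w,
                         lag_min = 0L, lag_max = 5L)
  epi <- data.frame(disease = "toy", stratum = "toy_other", age = ages,
                    incidence = inc, case_fatality = cf, remission = rem)
  # half the mass inactive, half at 450 MET-min/week; RR halves per 450
  expo <- exposure_distribution(c(0.5, 0, 0, 0.5, 0, 0, 0, 0))
  rr <- list(toy = relative_risk_function("toy", slope = log(2) / 450,
                                          floor = 0.5))
  costs <- list(
    disease_costs = data.frame(disease = "toy", stratum = "toy_other",
                               cost_first_year = 0, cost_subsequent_year = 0,
                               cost_last6m = 0),
    unrelated = data.frame(age = ages, cost = 0), rr = rr)
  inputs <- structure(list(population = population, epi = epi,
                           diseases = diseases,
                           exposure = list(toy_other = expo),
                           costs = costs, spec = strata_spec(),
                           scenario = NULL),
                      class = "mslt_inputs")
  # pathway 1 x 1 x 1 x 0.5, +450 MET-min for 1 year, eligible from age 0:
  # hand-derived PIF = 1/6, lag (0,5) spreads it to 1/36 in years 0-5
  spec <- intervention_spec(awareness = 1, download = 1, use = 1,
                            adherence = 0.5, effect_met_min = 450,
                            cost_total = 1000, eligible_ages = c(0, 79))
  list(inputs = inputs, spec = spec, inc4 = inc4, cf4 = cf4, rem4 = rem4,
       w = w, pif = 1 / 6)
}

# Shared default synthetic world: generating it once keeps the suite fast.
.fixture_cache <- new.env(parent = emptyenv())

default_inputs <- function() {
  if (is.null(.fixture_cache$inputs))
    .fixture_cache$inputs <- synthetic_inputs(synthetic_scenario(seed = 1))
  .fixture_cache$inputs
}

default_fit <- function() {
  if (is.null(.fixture_cache$fit))
    .fixture_cache$fit <- mslt(default_inputs())
  .fixture_cache$fit
}

random_exposure <- function(n_bins = 8) {
  p <- runif(n_bins)
  exposure_distribution(p / sum(p))
}
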