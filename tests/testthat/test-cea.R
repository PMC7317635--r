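# Minimal hand-built run objects for unit-testing the costing arithmetic.
fake_run <- function(dly = matrix(0, 2, 4), cases_diff = matrix(0, 2, 4),
                     prev_diff = matrix(0, 2, 4), death_diff = matrix(0, 2, 4),
                     a0 = c(70L, 30L)) {
  zero <- matrix(0, 2, 4)
  pad <- function(m, n = 110, T = 4) {           # embed cohorts at rows a0+1
    out <- matrix(0, n, T); out[a0 + 1L, ] <- m; out
  }
  mk <- function(cases, prevpy, deaths) list(
    strata = list(s = list(
      N = rep(1, 110), ly = pad(zero), qaly = pad(zero),
      disease = list(toy = list(cases = pad(cases), prevpy = pad(prevpy),
                                deaths = pad(deaths))))))
  run <- structure(list(bau = mk(zero, zero, zero),
                        int = mk(cases_diff, prev_diff, death_diff),
                        intervention = NULL, horizon = 4L, strata = "s"),
                   class = "mslt_run")
  run$int$strata$s$ly <- pad(dly)
  run
}

test_that("disease cost offsets price each phase correctly", {
  costs <- data.frame(disease = "toy", stratum = "s",
                      cost_first_year = 1000, cost_subsequent_year = 0,
                      cost_last6m = 0)
  # one avoided incident case in year 2: -1000 that year
  cases <- matrix(0, 2, 4); cases[1, 2] <- -1
  run <- fake_run(cases_diff = cases)
  expect_equal(disease_cost_offsets(run, costs), c(0, -1000, 0, 0))

  # phase streams are additive
  costs2 <- data.frame(disease = "toy", stratum = "s",
                       cost_first_year = 100, cost_subsequent_year = 10,
                       cost_last6m = 1)
  prev <- matrix(0, 2, 4); prev[2, 3] <- 2
  deaths <- matrix(0, 2, 4); deaths[1, 4] <- -0.5
  run <- fake_run(cases_diff = cases, prev_diff = prev, death_diff = deaths)
  expect_equal(disease_cost_offsets(run, costs2), c(0, -100, 20, -0.5))

  expect_error(disease_cost_offsets(run, costs2[0, ]), "missing phase costs")
})

test_that("unrelated costs value incremental life years at age-specific cost", {
  unrel <- data.frame(age = 0:109, cost = ifelse(0:109 == 70, 5000, 0))
  dly <- matrix(0, 2, 4); dly[1, 1] <- 1      # +1 life year at age 70, year 0
  run <- fake_run(dly = dly)
  expect_equal(unrelated_costs(run, unrel), c(5000, 0, 0, 0))
  expect_equal(unrelated_costs(fake_run(), unrel), rep(0, 4))
})

test_that("ICER flags cover all four cost-effect quadrants", {
  expect_equal(compute_icer(2200000, 28),
               list(icer = 78571.42857142857, flag = "icer"),
               tolerance = 1e-12)
  expect_equal(round(compute_icer(2200000, 28)$icer), 78571)
  expect_equal(compute_icer(-100, 1)$flag, "cost-saving")
  expect_equal(compute_icer(-100, 1)$icer, -100)
  expect_equal(compute_icer(100, -1)$flag, "dominated")
  expect_true(is.na(compute_icer(100, -1)$icer))
  expect_equal(compute_icer(-100, -1)$flag, "less-effective-cheaper")
  expect_equal(compute_icer(0, 1), list(icer = 0, flag = "icer"))
  expect_equal(compute_icer(5, 0)$flag, "undefined")
})

test_that("net cost equals the sum of its discounted components", {
  res <- default_fit()$cea
  expect_equal(res$net_cost,
               res$components$intervention + res$components$offsets +
                 res$components$unrelated,
               tolerance = 1e-6)
})

test_that("with all costs zeroed the net cost is the intervention cost", {
  inputs <- default_inputs()
  inputs$costs$disease_costs[c("cost_first_year", "cost_subsequent_year",
                               "cost_last6m")] <- 0
  inputs$costs$unrelated$cost <- 0
  fit <- mslt(inputs)
  expect_identical(fit$cea$net_cost,
                   discount(intervention_cost_stream(fit$intervention, 110),
                            0.03))
})

test_that("equity adjustment lifts indigenous gains and leaves others alone", {
  inputs <- default_inputs()
  base <- default_fit()$cea$by_group
  adj <- mslt(inputs, equity_adjusted = TRUE)$cea$by_group
  ind <- grepl("indigenous", base$stratum) & base$population > 0 &
    base$qaly_gain > 0
  expect_true(all(adj$qaly_per_1000[ind] > base$qaly_per_1000[ind]))
  oth <- grepl("_other$", base$stratum)
  expect_equal(adj$qaly_gain[oth], base$qaly_gain[oth], tolerance = 1e-12)

  # with no ethnic gap the adjustment is a no-op
  flat_inputs <- synthetic_inputs(synthetic_scenario(
    mortality_params = list(indigenous_mult = 1),
    morbidity_params = list(indigenous_mult = 1)))
  expect_equal(equity_adjust(flat_inputs)$population, flat_inputs$population)

  single <- inputs
  single$population <- single$population[single$population$ethnicity == "other", ]
  expect_error(equity_adjust(single), "both ethnicity groups")
})
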