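toy_epi <- function(inc, cf, rem) {
  data.frame(disease = "toy", stratum = "s", age = 0:109,
             incidence = inc, case_fatality = cf, remission = rem)
}

test_that("disease life table follows the hand recursions", {
  # no inflow: prevalence stays zero
  lt <- run_disease_lifetable(toy_epi(0, 0.2, 0))
  expect_true(all(lt$P == 0))

  # i = 0.1, f = r = 0: prevalent after 2 cycles = 1 - 0.9^2 = 0.19
  lt <- run_disease_lifetable(toy_epi(0.1, 0, 0))
  expect_equal(lt$P[1, 3], 0.19, tolerance = 1e-15)

  # full prevention: PIF = 1 means zero new incidence forever
  lt <- run_disease_lifetable(toy_epi(0.1, 0.05, 0), pif_series = rep(1, 110))
  expect_true(all(lt$newinc == 0))
  expect_true(all(lt$P == 0))

  expect_error(run_disease_lifetable(toy_epi(1.5, 0, 0)), "\\[0, 1\\]")
  # a negative PIF can push incidence x (1 - PIF) above 1
  expect_error(run_disease_lifetable(toy_epi(0.5, 0, 0),
                                     pif_series = rep(-3, 110)),
               "annual probabilities")
})

test_that("disease life table matches exhaustive Markov matrix powering", {
  set.seed(13)
  for (rep in 1:20) {
    inc <- runif(110, 0, 0.3); cf <- runif(110, 0, 0.3)
    rem <- runif(110, 0, 0.2)
    pif <- runif(110, 0, 0.8)
    lt <- run_disease_lifetable(toy_epi(inc, cf, rem), pif_series = pif)
    oracle <- markov_disease_oracle(inc, cf, rem, pif, 110)
    expect_equal(lt$H[1, ], oracle[, "H"], tolerance = 1e-12)
    expect_equal(lt$P[1, ], oracle[, "P"], tolerance = 1e-12)
    expect_equal(lt$D[1, ], oracle[, "D"], tolerance = 1e-12)
    # state conservation at every cycle
    expect_equal(lt$H + lt$P + lt$D, matrix(1, 1, 111), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("state conservation holds across the full default run", {
  run <- default_fit()$run
  for (s in run$strata)
    for (d in names(run$int$strata[[s]]$tables)) {
      lt <- run$int$strata[[s]]$tables[[d]]
      expect_true(max(abs(lt$H + lt$P + lt$D - 1)) < 1e-10,
                  info = paste(s, d))
    }
})

test_that("mortality/morbidity feedback is exact arithmetic", {
  mk <- function(mort, prev) list(mort_rate = mort, prev_rate = prev)
  q0 <- matrix(0.02, 2, 3); p0 <- matrix(0.05, 2, 3)
  bau <- mk(matrix(0.008, 2, 3), matrix(0.3, 2, 3))

  # identical scenario tables: adjusted rates equal baseline exactly
  adj <- recompute_mortality_morbidity(q0, p0, list(bau), list(bau), c(toy = 0.2))
  expect_identical(adj$q, q0)
  expect_identical(adj$pyld, p0)
  expect_equal(adj$clips, 0)

  # halving one disease's mortality flow reduces all-cause by exactly that
  int <- mk(bau$mort_rate / 2, bau$prev_rate)
  adj <- recompute_mortality_morbidity(q0, p0, list(bau), list(int), c(toy = 0.2))
  expect_equal(adj$q, q0 - 0.004, ignore_attr = TRUE)
  expect_equal(adj$pyld, p0, ignore_attr = TRUE)

  # an intervention removing more mortality than the baseline has is clipped
  big <- mk(matrix(0.5, 2, 3), matrix(0, 2, 3))
  zero <- mk(matrix(0, 2, 3), matrix(0, 2, 3))
  adj <- recompute_mortality_morbidity(q0, p0, list(big), list(zero), c(toy = 0))
  expect_true(all(adj$q >= 0))
  expect_equal(adj$clips, 6)
})

test_that("no clipping occurs under the default synthetic scenario", {
  run <- default_fit()$run
  clips <- sum(vapply(run$int$strata, function(s) s$clips, numeric(1)))
  expect_equal(clips, 0)
})

test_that("discounting follows the present-value convention", {
  expect_equal(discount(c(10, 20, 30), 0), 60)
  expect_equal(discount(c(0, 100), 0.03), 97.0874, tolerance = 1e-6)
  expect_equal(discount(42, 0.1), 42)
  expect_error(discount(1:3, -0.01), "non-negative")
})

test_that("BAU output is invariant to the intervention configuration", {
  inputs <- default_inputs()
  run_null <- run_mslt(inputs, NULL)
  run_base <- default_fit()$run
  run_m5 <- run_mslt(inputs, scenario_intervention("maintain5"))
  expect_identical(run_null$bau, run_base$bau)
  expect_identical(run_base$bau, run_m5$bau)
})

test_that("a protective intervention yields a positive QALY gain", {
  fit <- default_fit()
  gain <- annual_totals(fit$run, "int") - annual_totals(fit$run, "bau")
  expect_gt(sum(gain), 0)
})

test_that("missing strata are reported by name", {
  inputs <- default_inputs()
  broken <- inputs
  broken$epi <- broken$epi[broken$epi$stratum != "male_other" |
                             broken$epi$disease != "chd", ]
  expect_error(run_mslt(broken, intervention_spec()), "male_other")
})
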