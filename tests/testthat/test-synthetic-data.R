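test_that("the generator is deterministic and schema-consistent", {
  a <- synthetic_inputs(synthetic_scenario(seed = 5))
  b <- synthetic_inputs(synthetic_scenario(seed = 5))
  expect_identical(a, b)

  # proportions and probability-like quantities stay in range
  expect_true(all(a$population$mortality >= 0 & a$population$mortality <= 1))
  expect_true(all(a$population$pyld >= 0 & a$population$pyld < 1))
  for (d in a$exposure) {
    expect_true(all(d$proportion >= 0))
    expect_equal(sum(d$proportion), 1, tolerance = 1e-12)
  }

  c_ <- synthetic_inputs(synthetic_scenario(seed = 6))
  expect_false(identical(a$exposure, c_$exposure))
})

test_that("mortality is monotone in age and higher for the indigenous group", {
  pop <- default_inputs()$population
  for (s in unique(pop$stratum)) {
    q <- pop$mortality[pop$stratum == s][order(pop$age[pop$stratum == s])]
    expect_true(all(diff(q[36:110]) >= 0), info = s)
  }
  for (sex in c("male", "female")) {
    qi <- pop$mortality[pop$sex == sex & pop$ethnicity == "indigenous"]
    qo <- pop$mortality[pop$sex == sex & pop$ethnicity == "other"]
    expect_true(all(qi >= qo), info = sex)
  }
  # multiplier 1 collapses the ethnic gap entirely
  flat <- generate_demography(
    scenario = synthetic_scenario(mortality_params = list(indigenous_mult = 1),
                                  morbidity_params = list(indigenous_mult = 1)))
  for (sex in c("male", "female"))
    expect_equal(flat$mortality[flat$sex == sex & flat$ethnicity == "indigenous"],
                 flat$mortality[flat$sex == sex & flat$ethnicity == "other"])
})

test_that("disease epi honours the sex, cancer and age-shape rules", {
  inputs <- default_inputs()
  epi <- inputs$epi
  bc_male <- epi[epi$disease == "breast_cancer" & grepl("^male", epi$stratum), ]
  expect_true(all(bc_male$incidence == 0))
  for (d in c("chd", "stroke", "t2dm"))
    expect_true(all(epi$remission[epi$disease == d] == 0), info = d)
  for (d in c("colorectal_cancer", "breast_cancer")) {
    e <- epi[epi$disease == d & epi$stratum == "female_other", ]
    expect_true(any(e$remission > 0), info = d)
  }
  # incidence and case fatality rise with age over the adult range
  e <- epi[epi$disease == "chd" & epi$stratum == "male_other", ]
  e <- e[order(e$age), ]
  adult <- e$age >= 25 & e$age <= 90
  expect_true(all(diff(e$incidence[adult]) >= 0))
  expect_true(all(diff(e$case_fatality[adult]) >= 0))
})

test_that("implied disease mortality never exceeds all-cause mortality", {
  scenario <- synthetic_scenario(seed = 7)
  pop <- generate_demography(scenario = scenario)
  de <- generate_disease_epi(scenario = scenario, population = pop)
  for (s in unique(pop$stratum)) {
    pop_s <- pop[pop$stratum == s, ]
    pop_s <- pop_s[order(pop_s$age), ]
    total <- rep(0, 110)
    for (d in de$diseases$disease) {
      e <- de$epi[de$epi$disease == d & de$epi$stratum == s, ]
      lt <- run_disease_lifetable(e, a0 = 0L)
      total <- total + lt$mort_rate[1, ]
    }
    expect_true(all(total <= pop_s$mortality), info = s)
  }
})

test_that("exposure calibration hits the insufficient-activity target", {
  inputs <- default_inputs()
  pop <- inputs$population
  adult <- pop$age >= 15 & pop$age <= 79
  w <- vapply(names(inputs$exposure), function(s)
    sum(pop$count[adult & pop$stratum == s]), numeric(1))
  below <- vapply(inputs$exposure, prop_below_threshold, numeric(1))
  overall <- sum(w * below) / sum(w)
  expect_gte(overall, 0.40)
  expect_lte(overall, 0.44)
})

test_that("prop_below_threshold handles degenerate distributions", {
  one_bin <- exposure_distribution(c(0, 0, 0, 1, 0, 0, 0, 0))
  expect_equal(sum(one_bin$proportion), 1)
  expect_equal(prop_below_threshold(one_bin, 450), 0.5)  # straddling bin
  expect_equal(prop_below_threshold(one_bin, 600), 1)
  expect_equal(prop_below_threshold(one_bin, 300), 0)
})

test_that("costs and relative risks have the required shapes", {
  scenario <- synthetic_scenario(seed = 11)
  cr <- generate_costs_and_rr(scenario = scenario)
  expect_true(all(cr$disease_costs$cost_first_year >= 0))
  expect_true(all(cr$disease_costs$cost_last6m >=
                    cr$disease_costs$cost_subsequent_year))
  expect_true(all(cr$unrelated$cost >= 0))
  mids <- default_exposure_bins()$midpoint
  for (d in names(cr$rr)) {
    v <- rr_evaluate(cr$rr[[d]], mids)
    expect_true(all(diff(v) <= 0), info = d)
    expect_true(all(v <= 1) && v[1] == 1, info = d)
  }
  null_rr <- generate_costs_and_rr(
    scenario = synthetic_scenario(rr_params = list(scale = 0)))
  for (d in names(null_rr$rr))
    expect_equal(rr_evaluate(null_rr$rr[[d]], mids), rep(1, length(mids)))
})

test_that("CSV round-trip reproduces model results exactly", {
  inputs <- default_inputs()
  dir <- withr::local_tempdir()
  write_inputs(inputs, dir)
  expect_true(all(file.exists(file.path(dir,
    c("population.csv", "disease_epi.csv", "exposure.csv", "costs.csv",
      "unrelated_costs.csv", "rr.csv")))))
  back <- read_inputs(dir)
  fit1 <- mslt(inputs)
  fit2 <- mslt(back)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-12)
})

test_that("invalid configuration is rejected", {
  expect_error(strata_spec(age_band_edges = c(0, 50)), "configuration error")
  expect_error(strata_spec(age_band_edges = c(0, 60, 30, 110)),
               "configuration error")
  expect_error(synthetic_scenario(population_size = -1), "configuration error")
})
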