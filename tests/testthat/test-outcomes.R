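test_that("smoking prevalence percentages are normalised and signed right", {
  b <- inert_bundle(horizon = 1)
  b <- restrict_population(b, ages = 30, sexes = "male")
  i <- b$smoking$sex == "male" & b$smoking$age == 30
  b$smoking$p_never[i] <- 1
  b$smoking$p_current[i] <- 0
  b$smoking$p_former[i] <- 0
  traj <- run_simulation(b)
  sp <- smoking_prevalence(traj, 0)
  expect_equal(sp$percent[sp$smoking == "never"], 100)
  expect_equal(sp$percent[sp$smoking == "current"], 0)

  full <- run_simulation(base_bundle(), price_scenario(20))
  sp <- smoking_prevalence(full)
  sums <- tapply(sp$percent, sp$year, sum)
  expect_true(all(abs(sums - 100) < 1e-9))

  # the intervention still smokes less at the final year
  ref <- run_simulation(base_bundle())
  cur <- function(tr) smoking_prevalence(tr, 40)$percent[2]
  expect_gt(cur(ref), cur(full))
})

test_that("COPD prevalence uses the whole-population denominator", {
  b <- inert_bundle(horizon = 1)
  # two equal cells: one aged 60 with universal COPD, one aged 20 without
  b$population$count <- ifelse(
    b$population$sex == "male" & b$population$age %in% c(20, 60), 1000, 0)
  b$copd$prevalence[b$copd$sex == "male" & b$copd$age == 60] <- 1
  traj <- run_simulation(b)
  expect_equal(copd_prevalence(traj, 0)$percent, 50)

  clean <- inert_bundle(1)
  clean$copd$prevalence <- rep(0, nrow(clean$copd))
  none <- run_simulation(clean)
  expect_equal(copd_prevalence(none, 0)$percent, 0)

  # direct-summation oracle on the seed-1 bundle at year 0
  full <- run_simulation(base_bundle())
  cp <- dplyr::inner_join(base_bundle()$population, base_bundle()$copd,
                          by = c("sex", "age"))
  expect_equal(copd_prevalence(full, 0)$percent,
               100 * sum(cp$count * cp$prevalence) / sum(cp$count))
})

test_that("incidence rates divide cases by mid-year person-years", {
  traj <- run_simulation(base_bundle())
  y <- 5
  cases <- sum(traj$incident[, , y + 1])
  py <- sum(traj$states[[y + 1]]) - sum(traj$deaths[, , y + 1]) / 2
  expect_equal(copd_incidence_rate(traj, y)$rate_per_1000, 1000 * cases / py)

  # a hand-made ratio: 10 cases among 5000 person-years is 2 per 1000
  expect_equal(1000 * 10 / 5000, 2)
  expect_equal(copd_incidence_rate(run_simulation(inert_bundle(2)),
                                   0)$rate_per_1000, 0)

  # no incidence rate exists for the final simulated year
  expect_error(copd_incidence_rate(traj, traj$horizon), "final")
  expect_silent(copd_incidence_rate(traj, traj$horizon - 1))
})

test_that("cumulative cases saved is a reference-minus-intervention sum", {
  ref <- run_simulation(base_bundle())
  expect_equal(cumulative_cases_saved(ref, ref), 0)
  int <- run_simulation(base_bundle(), price_scenario(10))
  expect_equal(cumulative_cases_saved(ref, int),
               sum(ref$incident) - sum(int$incident))
  expect_gt(cumulative_cases_saved(ref, int), 0)

  short <- base_bundle()
  short$horizon_years <- 5L
  short$newborns <- short$newborns[short$newborns$year <= 5, ]
  expect_error(cumulative_cases_saved(ref, run_simulation(short)), "horizon")
})

test_that("life expectancy is exact in the zero-mortality limit", {
  b <- base_bundle()
  b$mortality$rate <- rep(0, nrow(b$mortality))
  for (age in c(0, 20, 60, 90)) {
    expect_equal(cohort_life_expectancy(b, NULL, age, "male", "overall"), 95)
  }
})

test_that("life expectancy matches an explicit survival enumeration", {
  # constant death probability 0.5, no transitions/incidence, start age 90:
  # five annual cycles to age 95, then a 1/m tail for the survivors
  b <- inert_bundle(horizon = 1)
  b$mortality$rate <- rep(0.5, nrow(b$mortality))
  b <- flatten_rr(b)

  alive <- 1
  expected <- 0
  for (cycle in 1:5) {
    d <- alive * 0.5
    expected <- expected + (alive - d / 2)  # half-cycle person-years
    alive <- alive - d
  }
  expected <- expected + alive / 0.5  # terminal tail
  expect_equal(cohort_life_expectancy(b, NULL, 90, "male", "overall"),
               90 + expected)
  expect_equal(90 + expected, 91.515625)
})

test_that("life-expectancy modes are ordered by their COPD weights", {
  b <- base_bundle()
  sc <- price_scenario(10)
  for (age in c(45, 60)) {
    ov <- cohort_life_expectancy(b, sc, age, "female", "overall")
    da <- cohort_life_expectancy(b, sc, age, "female", "disability_adjusted")
    cf <- cohort_life_expectancy(b, sc, age, "female", "copd_free")
    expect_gte(ov, da)
    expect_gte(da, cf)
    expect_gt(ov, cf)  # some COPD years exist at these ages
  }
})

test_that("life-expectancy gains are zero at reference and price-monotone", {
  b <- base_bundle()
  expect_identical(le_gain(b, price_scenario(0), 20, "male", "overall"), 0)
  gains <- vapply(c(5, 10, 20),
                  function(p) le_gain(b, price_scenario(p), 20, "male",
                                      "overall"), numeric(1))
  expect_true(all(gains > 0))
  expect_true(all(diff(gains) > 0))
  # the young have more time to benefit
  expect_gt(gains[3], le_gain(b, price_scenario(20), 60, "male", "overall"))
})

test_that("cost savings multiply cases, unit cost and disease duration", {
  expect_equal(cost_savings(124364, 5700, 10), 7088748000)
  expect_equal(cost_savings(22070, 5700, 10), 1257990000)
  expect_equal(cost_savings(0, 5700, 10), 0)
  expect_equal(cost_savings(100, 1000, 5, productivity_cost = 500), 750000)
  expect_error(cost_savings(-1, 5700, 10), "nonnegative")
})

test_that("the scenario comparison surface stays consistent", {
  b <- base_bundle()
  cmp <- simulate_scenarios(b, prices = c(5, 20))
  expect_named(cmp$trajectories, c("reference", "price+5%", "price+20%"))

  cs <- cases_saved_table(cmp)
  expect_equal(cs$cases_saved[cs$scenario == "reference"], 0)
  expect_true(all(diff(cs$cases_saved) > 0))

  rep <- outcome_report(cmp)
  expect_setequal(unique(rep$scenario), names(cmp$trajectories))
  expect_true("copd_incidence_per_1000py" %in% rep$measure)
  # incidence has no final-year row; prevalence does
  inc_years <- rep$year[rep$measure == "copd_incidence_per_1000py"]
  expect_equal(max(inc_years), b$horizon_years - 1)
  prev_years <- rep$year[rep$measure == "copd_prevalence_percent"]
  expect_equal(max(prev_years), b$horizon_years)

  g <- glance(cmp)
  expect_equal(nrow(g), 3)
  expect_true(all(c("population_start", "cases_saved") %in% names(g)))

  expect_s3_class(autoplot(cmp), "ggplot")
  expect_s3_class(plot_smoking_prevalence(cmp), "ggplot")
  expect_s3_class(autoplot(cmp$trajectories$reference), "ggplot")
})

test_that("the life-expectancy table reports gains per age, sex and mode", {
  b <- base_bundle()
  tab <- life_expectancy_table(b, ages = 20, sexes = "male", prices = c(5, 20),
                               modes = c("overall", "copd_free"))
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$gain > 0))
  expect_true(all(tab$le == tab$le_reference + tab$gain))
  wide <- tidyr::pivot_wider(tab, id_cols = "scenario",
                             names_from = "mode", values_from = "gain")
  expect_true(all(wide$copd_free > wide$overall - 1))  # both present, sane
})
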