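test_that("rate decomposition matches hand arithmetic and recovers totals", {
  # incidence: total 0.0017 over (never .6, current .2, former .2),
  # rr_current 10, rr_former 2 -> denominator .6 + .2*2 + .2*10 = 3.0
  out <- decompose_incidence(0.0017, c(0.6, 0.2, 0.2), 10, 2)
  expect_equal(out$never, 0.0017 / 3)
  expect_equal(out$current, 10 * 0.0017 / 3)
  expect_equal(out$former, 2 * 0.0017 / 3)
  expect_equal(0.6 * out$never + 0.2 * out$current + 0.2 * out$former, 0.0017)

  # mortality: total 0.01 over (never .5, current .2, former .3),
  # rr_current 2.07, rr_former 1.535 -> denominator 1.3745
  out <- decompose_mortality(0.01, c(0.5, 0.2, 0.3), 2.07, 1.535)
  denom <- 0.5 + 0.3 * 1.535 + 0.2 * 2.07
  expect_equal(denom, 1.3745)
  expect_equal(out$never, 0.01 / denom)
  expect_equal(out$current, 2.07 * 0.01 / denom)
  expect_equal(0.5 * out$never + 0.2 * out$current + 0.3 * out$former, 0.01)

  # no-effect and degenerate limits
  flat <- decompose_incidence(0.3, c(0.5, 0.25, 0.25), 1, 1)
  expect_equal(unlist(flat), c(never = 0.3, current = 0.3, former = 0.3))
  pure <- decompose_incidence(0.2, c(1, 0, 0), 8, 4)
  expect_equal(pure$never, 0.2)
  zero <- decompose_incidence(0.5, c(0, 0, 0), 8, 4)
  expect_equal(unlist(zero), c(never = 0, current = 0, former = 0))
})

test_that("frozen state rates aggregate back to the input totals", {
  b <- base_bundle()
  sr <- build_state_rates(b)
  for (si in 1:2) {
    s <- c("male", "female")[si]
    sm <- b$smoking[b$smoking$sex == s, ]
    w <- rbind(sm$p_never, sm$p_current, sm$p_former)
    agg_inc <- colSums(w * t(sr$incidence[si, , ]))
    expect_lt(max(abs(agg_inc - b$copd$incidence[b$copd$sex == s])), 1e-12)
    agg_m <- colSums(w * t(sr$mortality[si, , ]))
    expect_lt(max(abs(agg_m - b$mortality$rate[b$mortality$sex == s])), 1e-12)
  }
})

test_that("with everything switched off the projection is pure ageing", {
  b <- inert_bundle(horizon = 3)
  traj <- run_simulation(b)
  for (t in 1:3) {
    expect_equal(unname(traj$states[[t + 1]][, 2:96, , ]),
                 unname(traj$states[[t]][, 1:95, , ]), tolerance = 1e-15)
    expect_equal(sum(traj$states[[t + 1]][, 1, , ]), 0)
    expect_equal(sum(traj$deaths[, , t]), 0)
    expect_equal(sum(traj$incident[, , t]), 0)
  }
})

test_that("a pure-mortality cohort halves under a 0.5 death probability", {
  b <- inert_bundle(horizon = 1)
  b <- restrict_population(b, ages = 50, sexes = "male", count = 1000)
  i <- b$smoking$sex == "male" & b$smoking$age == 50
  b$smoking$p_never[i] <- 0
  b$smoking$p_current[i] <- 1
  b$smoking$p_former[i] <- 0
  b$mortality$rate[b$mortality$sex == "male" & b$mortality$age == 50] <- 0.5
  b$copd$prevalence <- rep(0, nrow(b$copd))
  b <- flatten_rr(b)

  traj <- run_simulation(b)
  expect_equal(sum(traj$deaths), 500)
  expect_equal(traj$deaths["male", "50", 1], 500)
  st1 <- traj$states[[2]]
  expect_equal(st1["male", "51", "current", "no"], 500)
  expect_equal(sum(st1), 500)
})

test_that("the year-stepper matches an independently built transition matrix", {
  b <- base_bundle()
  b <- restrict_population(b, ages = c(40, 41, 42), sexes = c("male", "female"),
                           count = 1000)
  traj <- run_simulation(b)
  expected <- oracle_final_state(b)
  for (s in c("male", "female")) {
    got <- traj$states[[b$horizon_years + 1]][s, , , ]
    expect_equal(unname(got), expected[[s]], tolerance = 1e-10, label = s)
    expect_gt(sum(got), 0)  # the comparison is not vacuous
  }
})

test_that("population bookkeeping balances each year", {
  traj <- run_simulation(base_bundle())
  for (t in 1:traj$horizon) {
    now <- alive_by_sex_age(traj, t - 1)
    nxt <- alive_by_sex_age(traj, t)
    resid <- nxt[, 2:96] - (now[, 1:95] - traj$deaths[, 1:95, t])
    expect_lt(max(abs(resid) / pmax(now[, 1:95], 1e-9)), 1e-9)
  }
})

test_that("structural zeros persist through the whole projection", {
  traj <- run_simulation(base_bundle(), price_scenario(20))
  for (t in c(0, 1, 20, 40)) {
    st <- traj$states[[t + 1]]
    expect_equal(sum(st[, 1:11, 2, ]), 0)   # no current smokers below 11
    expect_equal(sum(st[, 1:16, 3, ]), 0)   # no former smokers below 16
    expect_equal(sum(st[, 1:40, , 2]), 0)   # no COPD below 40
  }
})

test_that("simulations are deterministic and honour trivial limits", {
  b <- base_bundle()
  t1 <- run_simulation(b, price_scenario(10))
  t2 <- run_simulation(b, price_scenario(10))
  expect_identical(t1, t2)

  ref <- run_simulation(b)
  ref2 <- run_simulation(b, price_scenario(0))
  expect_equal(ref$states, ref2$states)
  expect_equal(ref$incident, ref2$incident)

  b0 <- b
  b0$horizon_years <- 0L
  b0$newborns <- b0$newborns[0, ]
  traj0 <- run_simulation(b0)
  expect_length(traj0$states, 1)
  expect_identical(dim(traj0$incident)[3], 0L)

  # intervention lowers year-0 incidence under frozen rates
  int <- run_simulation(b, price_scenario(20))
  expect_lt(sum(int$incident[, , 1]), sum(ref$incident[, , 1]))
})

test_that("with unit relative risks scenarios cannot change outcomes", {
  b <- flatten_rr(base_bundle())
  ref <- run_simulation(b)
  int <- run_simulation(b, price_scenario(50))
  expect_equal(sum(int$incident), sum(ref$incident), tolerance = 1e-12)
  expect_equal(sum(int$deaths), sum(ref$deaths), tolerance = 1e-12)
  expect_equal(copd_prevalence(int, 40)$percent,
               copd_prevalence(ref, 40)$percent, tolerance = 1e-12)
})
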