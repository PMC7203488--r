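test_that("fracture probabilities combine incidence, risk group and treatment", {
  p <- base_case_parameters()
  st <- state_at(67)
  pr <- annual_fracture_probabilities(st, p)
  expect_equal(unname(pr[1, "hip"]), 0.96 / 1000 * 3.91)   # 0.0037536
  expect_equal(unname(pr[1, "vertebral"]), 5.64 / 1000 * 2.59)

  # treatment relative risk enters multiplicatively
  rr <- matrix(c(0.5, 1, 1, 1), 1)
  expect_equal(unname(annual_fracture_probabilities(st, p, rr)[1, "hip"]),
               0.0037536 * 0.5)

  # a second hip fracture is the last one allowed
  st2 <- state_at(67, hip_count = 2, hip_clock = 3)
  expect_equal(unname(annual_fracture_probabilities(st2, p)[1, "hip"]), 0)

  set.seed(21)
  pz <- synthetic_parameter_set(incidence_scale = 0)
  expect_true(all(annual_fracture_probabilities(state_at(70), pz) == 0))
})

test_that("mortality applies attenuated excess hazards after hip fracture", {
  p <- base_case_parameters()
  expect_equal(annual_mortality_probability(state_at(82), p), 0.06998)
  # within a year of a hip fracture
  expect_equal(annual_mortality_probability(state_at(82, hip_count = 1, hip_clock = 0), p),
               0.06998 * (1 + 0.25 * 1.87))    # 0.102696 (approx)
  # a year or more after
  expect_equal(annual_mortality_probability(state_at(82, hip_count = 1, hip_clock = 4), p),
               0.06998 * (1 + 0.25 * 0.73))
  # attributable fraction 0 collapses the multiplier
  p0 <- p; p0$mortality$attributable_fraction <- 0
  expect_equal(annual_mortality_probability(state_at(82, hip_count = 1, hip_clock = 0), p0),
               0.06998)
})

test_that("within a cycle, death precedes fracture and trackers update once", {
  p <- base_case_parameters()
  st <- state_at(70, hip_count = 1, hip_clock = 2, on_treatment = TRUE,
                 years_on = 1, cycle = 1)

  # forced death: no fracture, trackers unchanged
  res <- advance_one_cycle(st, p, "none", u = forced_u(death = 0, fracture = 0))
  expect_equal(res$event, 5L)
  expect_false(res$state$alive)
  expect_equal(res$state$hip_count, 1L)
  expect_equal(res$state$hip_clock, 2L)   # no tick on the death cycle

  # forced hip on a prior-hip state: count 2, clock reset
  res2 <- advance_one_cycle(st, p, "none", u = forced_u(death = 1, fracture = 0))
  expect_equal(res2$event, 1L)
  expect_equal(res2$state$hip_count, 2L)
  expect_equal(res2$state$hip_clock, 0L)
  expect_equal(res2$state$age, 71L)

  # zero probabilities: event none, age advances, clock ticks
  set.seed(9)
  pz <- synthetic_parameter_set(incidence_scale = 0, mortality = 0)
  res3 <- advance_one_cycle(state_at(70, hip_count = 1, hip_clock = 0), pz,
                            "none", u = forced_u(death = 1, fracture = 0))
  expect_equal(res3$event, 0L)
  expect_equal(res3$state$age, 71L)
  expect_equal(res3$state$hip_clock, 1L)
})

test_that("degenerate inputs pin the trajectory length", {
  set.seed(10)
  pz <- synthetic_parameter_set(incidence_scale = 0, mortality = 0)
  pz$horizon_age <- 105
  tr <- simulate_individual("none", 65, pz, seed = 1)
  expect_equal(nrow(tr), 40)
  expect_true(all(tr$event == "none"))
  expect_equal(tr$age, 65:104)

  set.seed(11)
  pd <- synthetic_parameter_set(incidence_scale = 0, mortality = 1)
  tr2 <- simulate_individual("none", 65, pd, seed = 1)
  expect_equal(nrow(tr2), 1)
  expect_equal(tr2$event, "death")
})

test_that("a fixed seed reproduces trajectories and cohorts bit-for-bit", {
  p <- base_case_parameters()
  t1 <- simulate_individual("zoledronic", 70, p, seed = 33)
  t2 <- simulate_individual("zoledronic", 70, p, seed = 33)
  expect_identical(t1, t2)
  c1 <- simulate_cohort("alendronate", 75, 500, p, seed = 12)
  c2 <- simulate_cohort("alendronate", 75, 500, p, seed = 12)
  expect_identical(c1, c2)
})

test_that("trackers never exceed their caps along whole lifetimes", {
  set.seed(14)
  p <- synthetic_parameter_set(incidence_scale = 2, mortality = 0.02)
  for (k in 1:30) {
    tr <- simulate_individual("alendronate", 65, p, seed = k)
    expect_true(all(tr$hip_count <= 2))
    expect_true(all(diff(tr$hip_count) %in% c(0, 1)))
    # at most one fracture per cycle: counts rise by at most one in total
    tot <- tr$hip_count + tr$vertebral_count + tr$wrist_count + tr$other_count
    expect_true(all(diff(tot) %in% c(0, 1)))
    expect_true(tr$event[nrow(tr)] == "death" || max(tr$age) == p$horizon_age - 1)
  }
})

test_that("with fractures disabled the engine matches the life-table oracle", {
  p <- base_case_parameters()
  for (f in names(p$incidence)) p$incidence[[f]]$value[] <- 0
  res <- simulate_cohort("none", 65, 20000, p, seed = 5)
  oracle <- life_table_expectation(p, 65)
  expect_lt(abs(res$mean_life_years - oracle), 3 * res$se_life_years)
})

test_that("scaling incidence up cannot raise QALYs or lower fracture risk", {
  p <- base_case_parameters()
  hi <- p
  for (f in names(hi$incidence)) hi$incidence[[f]]$value <- hi$incidence[[f]]$value * 2
  a <- simulate_cohort("none", 70, 10000, p, seed = 77)
  b <- simulate_cohort("none", 70, 10000, hi, seed = 77)   # common random numbers
  expect_lte(b$mean_qaly, a$mean_qaly)
  expect_true(all(b$p_fracture >= a$p_fracture))
})

test_that("Monte-Carlo error shrinks like one over the square root of n", {
  p <- base_case_parameters()
  small <- simulate_cohort("none", 65, 1000, p, seed = 8)
  big <- simulate_cohort("none", 65, 100000, p, seed = 8)
  ratio <- small$se_qaly / big$se_qaly
  expect_equal(ratio, sqrt(100), tolerance = 0.15)
})

test_that("identical strategies under common random numbers tie exactly", {
  set.seed(19)
  p <- synthetic_parameter_set(identical_strategies = TRUE)
  a <- simulate_cohort("alendronate", 65, 3000, p, seed = 44)
  b <- simulate_cohort("zoledronic", 65, 3000, p, seed = 44)
  expect_identical(a$mean_cost, b$mean_cost)
  expect_identical(a$mean_qaly, b$mean_qaly)
  expect_identical(a$p_fracture, b$p_fracture)
  expect_identical(a$p_dead, b$p_dead)
})
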