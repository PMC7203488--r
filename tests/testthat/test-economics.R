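test_that("discount factors follow the closed form", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(10, 0), 1)
  expect_equal(discount_factor(7, 0.05), 1.05^-7)
})

test_that("cycle costs add drug, monitoring, fracture and long-term care", {
  p <- base_case_parameters()
  on <- list(on_treatment = TRUE, midyear_stop = FALSE)

  # first on-treatment alendronate year, no event: 761.64 x 0.71 + 167
  st <- state_at(65, on_treatment = TRUE, years_on = 1)
  expect_equal(cycle_cost(st, 0L, "alendronate", on, p),
               761.64 * 0.71 + 10 + 85 + 72)

  # a hip fracture adds its one-time direct cost
  expect_equal(cycle_cost(st, 1L, "alendronate", on, p),
               761.64 * 0.71 + 167 + 7103.25)

  # mid-year first-year discontinuation: half the annual drug charge
  mid <- list(on_treatment = TRUE, midyear_stop = TRUE)
  expect_equal(cycle_cost(st, 0L, "alendronate", mid, p),
               0.5 * 761.64 * 0.71 + 167)

  # zoledronic acid infusion year: full price, compliance 1
  expect_equal(cycle_cost(st, 0L, "zoledronic", on, p), 818.50 + 167)

  # off treatment, never fractured: nothing accrues
  off <- list(on_treatment = FALSE, midyear_stop = FALSE)
  expect_equal(cycle_cost(state_at(70), 0L, "alendronate", off, p), 0)
  expect_equal(cycle_cost(state_at(70), 0L, "none", off, p), 0)

  # post-hip state pays long-term care every year, also with a new event
  post <- state_at(75, hip_count = 1, hip_clock = 3)
  expect_equal(cycle_cost(post, 0L, "none", off, p), 4438.08)
  expect_equal(cycle_cost(post, 2L, "none", off, p), 4438.08 + 1310.11)

  # a death cycle accrues nothing
  expect_equal(cycle_cost(post, 5L, "zoledronic", on, p), 0)
})

test_that("cycle utilities multiply baseline by fracture multipliers", {
  p <- base_case_parameters()
  expect_equal(cycle_utility(state_at(72), 0L, p), 0.747)
  expect_equal(cycle_utility(state_at(72), 1L, p), 0.747 * 0.776)
  # past hip (subsequent-year multiplier), expired wrist multiplier
  st <- state_at(72, hip_count = 1, hip_clock = 3, wrist_count = 1)
  expect_equal(cycle_utility(st, 0L, p), 0.747 * 0.855)
  # event multiplier of one type combines with past multiplier of another
  st2 <- state_at(72, vertebral_count = 1)
  expect_equal(cycle_utility(st2, 1L, p), 0.747 * 0.776 * 0.868)
  # repeat hip in the event year: first-year multiplier only
  st3 <- state_at(72, hip_count = 1, hip_clock = 2)
  expect_equal(cycle_utility(st3, 1L, p), 0.747 * 0.776)
  # death cycle accrues nothing
  expect_equal(cycle_utility(st, 5L, p), 0)
})

test_that("cycle utility never exceeds the age-band baseline nor drops below 0", {
  set.seed(99)
  p <- synthetic_parameter_set()
  for (k in 1:100) {
    st <- state_at(sample(65:85, 1),
                   hip_count = sample(0:2, 1),
                   vertebral_count = sample(0:3, 1),
                   wrist_count = sample(0:2, 1),
                   hip_clock = sample(c(-1L, 0L, 2L), 1))
    if (st$hip_count == 0L) st$hip_clock <- -1L
    u <- cycle_utility(st, sample(0:4, 1), p)
    expect_gte(u, 0)
    expect_lte(u, band_value(p$utilities$baseline, st$age))
  }
})

test_that("lifetime cost decomposes exactly into its four components", {
  p <- base_case_parameters()
  res <- simulate_cohort("zoledronic", 70, 2000, p, seed = 23)
  expect_equal(sum(res$mean_components), res$mean_undisc_cost)
  # discounting can only shrink costs at a positive rate
  expect_lte(res$mean_cost, res$mean_undisc_cost)
  p0 <- p; p0$discount$cost <- 0; p0$discount$effect <- 0
  res0 <- simulate_cohort("zoledronic", 70, 2000, p0, seed = 23)
  expect_equal(res0$mean_cost, res0$mean_undisc_cost)
  expect_equal(res0$mean_qaly, res0$mean_undisc_qaly)
})

test_that("incremental metrics satisfy their algebraic identities", {
  set.seed(7)
  for (k in 1:200) {
    dc <- runif(1, -2000, 2000)
    de <- runif(1, -0.1, 0.1)
    wtp <- runif(1, 1000, 60000)
    m <- osteosim:::ce_metrics(dc, de, wtp)
    expect_equal(m$nhb, m$nmb / wtp)
    if (de > 0 && dc > 0) {
      expect_equal(m$icer, dc / de)
      expect_equal(sign(m$nmb), sign(wtp - m$icer))
    }
    if (de > 0 && dc <= 0) expect_equal(m$label, "dominant")
    if (de <= 0 && dc >= 0 && !(de == 0 && dc == 0)) {
      expect_equal(m$label, "dominated")
    }
  }
  m0 <- osteosim:::ce_metrics(0, 0, 29340)
  expect_equal(m0$label, "indifferent")
  expect_equal(m0$nmb, 0)
  expect_equal(m0$nhb, 0)
})

test_that("strategy comparisons report incremental quantities per the layout", {
  a <- fake_cohort("alendronate", 80, 5800, 5.412)
  b <- fake_cohort("zoledronic", 80, 6518, 5.471)
  cmp <- compare_strategies(a, b, wtp = 29340)
  expect_equal(cmp$delta_cost, 718)
  expect_equal(cmp$delta_effect, 0.059)
  expect_equal(round(cmp$icer), 12169)
  expect_equal(round(cmp$nmb, 2), 1013.06)
  expect_equal(round(cmp$nhb, 3), 0.035)

  dom <- compare_strategies(fake_cohort("a", 80, 1000, 5),
                            fake_cohort("b", 80, 900, 5.01), 29340)
  expect_equal(dom$label, "dominant")
  expect_true(is.na(dom$icer))
  expect_equal(dom$nmb, 29340 * 0.01 + 100)
  expect_error(compare_strategies(fake_cohort("a", 65, 1, 1),
                                  fake_cohort("b", 80, 1, 1), 29340),
               "start age")
})
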