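test_that("the acceptability curve is the NMB sign frequency", {
  # a single draw flips from not-cost-effective to cost-effective at its ICER
  one <- data.frame(delta_cost = 718, delta_effect = 0.059)
  cc <- ceac_from_draws(one, wtp_grid = c(0, 12000, 12169, 12170, 13000, 29340))
  expect_equal(cc$p_cost_effective, c(0, 0, 0, 1, 1, 1))

  # all draws dominant: probability one at every threshold
  dom <- data.frame(delta_cost = runif(20, -500, -1), delta_effect = runif(20))
  expect_true(all(ceac_from_draws(dom)$p_cost_effective == 1))

  # at zero willingness to pay only cost savings count
  set.seed(12)
  mix <- data.frame(delta_cost = rnorm(500), delta_effect = rnorm(500))
  cc0 <- ceac_from_draws(mix, wtp_grid = 0)
  expect_equal(cc0$p_cost_effective, mean(mix$delta_cost < 0))

  # monotone non-decreasing whenever every draw gains QALYs
  pos <- data.frame(delta_cost = rnorm(300, 500, 400),
                    delta_effect = runif(300, 0.001, 0.1))
  cc2 <- ceac_from_draws(pos)
  expect_true(all(diff(cc2$p_cost_effective) >= 0))
})

test_that("varying a cost-only parameter leaves the incremental effect intact", {
  p <- base_case_parameters()
  # restrict the registry to two parameters to keep the run small
  keep <- p$distributions$id %in% c("zol_annual_cost", "zol_rr_hip")
  p$distributions <- p$distributions[keep, ]
  dsa <- one_way_dsa(p, 80, n = 3000, seed = 15)
  tab <- dsa$table
  cost_row <- tab[tab$parameter == "zol_annual_cost", ]
  expect_identical(cost_row$delta_effect_lower, cost_row$delta_effect_upper)
  expect_identical(cost_row$delta_effect_lower, dsa$base$delta_effect)
  # a dearer comparator can only worsen its ICER under common random numbers
  expect_gt(cost_row$icer_upper, dsa$base$icer)
  expect_lt(cost_row$icer_lower, dsa$base$icer)

  # a degenerate range spans nothing
  p$distributions$lower[1] <- p$distributions$central[1]
  p$distributions$upper[1] <- p$distributions$central[1]
  dsa2 <- one_way_dsa(p, 80, n = 1000, seed = 15)
  expect_equal(dsa2$table$span[dsa2$table$parameter == p$distributions$id[1]], 0)
})

test_that("a collapsed PSA reproduces the base case", {
  p <- base_case_parameters()
  p$distributions$lower <- p$distributions$central
  p$distributions$upper <- p$distributions$central
  psa <- probabilistic_sa(p, 80, outer = 4, inner = 4000, seed = 27)
  set.seed(27 + 80)
  U <- osteosim:::make_uniforms(4000, p$horizon_age - 80)
  base <- lapply(c("alendronate", "zoledronic"), function(s) {
    osteosim:::cohort_from_run(osteosim:::run_cohort(s, 80, p, U), s, 80, 4000)
  })
  de_base <- base[[2]]$mean_qaly - base[[1]]$mean_qaly
  dc_base <- base[[2]]$mean_cost - base[[1]]$mean_cost
  # all parameter draws collapse to base values, so only inner Monte-Carlo
  # noise separates the draws from the base pair
  se_de <- sqrt(base[[1]]$se_qaly^2 + base[[2]]$se_qaly^2)
  se_dc <- sqrt(base[[1]]$se_cost^2 + base[[2]]$se_cost^2)
  expect_true(all(abs(psa$draws$delta_effect - de_base) < 3 * se_de))
  expect_true(all(abs(psa$draws$delta_cost - dc_base) < 3 * se_dc))
})

test_that("the PSA draw list is reproducible from its seed", {
  p <- base_case_parameters()
  a <- probabilistic_sa(p, 80, outer = 3, inner = 200, seed = 5)
  b <- probabilistic_sa(p, 80, outer = 3, inner = 200, seed = 5)
  expect_identical(a$draws, b$draws)
})

test_that("scenario overrides touch only persistence and compliance", {
  p <- base_case_parameters()
  pA <- osteosim:::scenario_overrides(p, "A")
  expect_true(all(pA$treatments$alendronate$persistence == 1))
  expect_true(all(pA$treatments$zoledronic$persistence == 1))
  expect_equal(pA$treatments$alendronate$compliance, 0.71)
  pB <- osteosim:::scenario_overrides(p, "B")
  expect_equal(pB$treatments$alendronate$compliance, 1)
  expect_equal(pB$treatments$alendronate$persistence, p$treatments$alendronate$persistence)
  pC <- osteosim:::scenario_overrides(p, "C")
  expect_equal(pC$treatments$alendronate$compliance, 1)
  expect_true(all(pC$treatments$zoledronic$persistence == 1))
  # everything else bit-identical
  a <- parameter_census(p); b <- parameter_census(pC)
  moved <- a$field[a$value != b$value]
  expect_true(all(grepl("persistence|compliance", moved)))
})

test_that("a no-op scenario reproduces the base analysis exactly", {
  p <- base_case_parameters()
  for (nm in names(p$treatments)) {
    p$treatments[[nm]]$persistence[] <- 1
    p$treatments[[nm]]$compliance <- 1
  }
  base <- ce_microsim(p, ages = 70, n = 1500, seed = 31)
  scen <- run_scenario("C", p, ages = 70, n = 1500, seed = 31)
  expect_identical(as.data.frame(base), as.data.frame(scen))
})
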