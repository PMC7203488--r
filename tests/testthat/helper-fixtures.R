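# shared fixtures and independent oracles for the test suite

# closed-form discounted-free life expectancy from the band mortality table:
# E[life years] = sum_t prod_{k<=t} (1 - q(age_k)), ages start_age .. horizon-1
life_table_expectation <- function(p, start_age) {
  ages <- start_age:(p$horizon_age - 1L)
  q <- vapply(ages, function(a) band_value(p$mortality$baseline, a), numeric(1))
  sum(cumprod(1 - q))
}

# closed-form probability of a first fracture of one type before the horizon,
# death drawn before fracture within each cycle, no excess-mortality feedback
first_fracture_probability <- function(p, start_age, type) {
  ages <- start_age:(p$horizon_age - 1L)
  q <- vapply(ages, function(a) band_value(p$mortality$baseline, a), numeric(1))
  pe <- vapply(ages, function(a) {
    band_value(p$incidence[[type]], a) / 1000 * band_value(p$osteo_rr[[type]], a)
  }, numeric(1))
  surv <- 1; no_fx <- 1; tot <- 0
  for (t in seq_along(ages)) {
    tot <- tot + surv * (1 - q[t]) * no_fx * pe[t]
    no_fx <- no_fx * (1 - pe[t])
    surv <- surv * (1 - q[t])
  }
  tot
}

# a minimal cohort_result carrying prescribed means (for metric-identity tests)
fake_cohort <- function(strategy, start_age, mean_cost, mean_qaly, n = 100000) {
  structure(list(strategy = strategy, start_age = start_age, n = n,
                 mean_cost = mean_cost, mean_qaly = mean_qaly,
                 se_cost = 0, se_qaly = 0),
            class = "cohort_result")
}

# single-individual engine state with prescribed history, for unit tests of
# the per-cycle operations
state_at <- function(age, hip_count = 0L, vertebral_count = 0L,
                     wrist_count = 0L, other_count = 0L, hip_clock = -1L,
                     alive = TRUE, on_treatment = FALSE, years_on = 0,
                     off_years = 0, cycle = 0L) {
  structure(list(age = as.integer(age), alive = alive, cycle = as.integer(cycle),
                 hip_count = as.integer(hip_count),
                 vertebral_count = as.integer(vertebral_count),
                 wrist_count = as.integer(wrist_count),
                 other_count = as.integer(other_count),
                 hip_clock = as.integer(hip_clock),
                 on_treatment = on_treatment, years_on = years_on,
                 off_years = off_years),
            class = "osteo_state")
}

# deterministic per-cycle draws for forcing events through advance_one_cycle
forced_u <- function(n = 1L, death = 1, fracture = 1, persistence = 0) {
  list(death = rep(death, n), fracture = rep(fracture, n),
       persistence = rep(persistence, n))
}
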