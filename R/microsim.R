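#' @title Microsimulation engine
#' @description
#' Women are simulated through annual cycles from the start age until death
#' or the horizon age (105). Each cycle evaluates, in order: the persistence
#' draw at the treatment-year boundary, background mortality with
#' hip-fracture excess hazards (death first: a woman who dies in a cycle
#' accrues no fracture, cost or utility for that cycle), then a single
#' categorical draw over the four fracture types and "no fracture". Tracker
#' variables record fracture counts (at most two hip fractures), the time
#' since the most recent hip fracture, and the adherence clocks.
#' @name microsim_engine
NULL

# event codes used throughout the engine
EVENT_LEVELS <- c("none", "hip", "vertebral", "wrist", "other", "death")
FRACTURE_TYPES <- c("hip", "vertebral", "wrist", "other")

# initial state: everyone alive, fracture-free, at the start age; on
# treatment from cycle 1 unless the strategy is "none"
init_state <- function(n, start_age, strategy) {
  structure(list(
    age = rep(as.integer(start_age), n),
    alive = rep(TRUE, n),
    cycle = 0L,
    hip_count = integer(n),
    vertebral_count = integer(n),
    wrist_count = integer(n),
    other_count = integer(n),
    hip_clock = rep(-1L, n),          # -1 = no hip fracture yet
    on_treatment = rep(strategy != "none", n),
    years_on = numeric(n),
    off_years = numeric(n)
  ), class = "osteo_state")
}

#' Annual fracture probabilities for the current cycle
#'
#' For each fracture type the probability is the published general-population
#' incidence at the woman's current age band (per 1,000 person-years, used
#' directly as an annual probability since all rates are far below 0.05)
#' times the osteoporosis relative risk at that band, times the effective
#' treatment relative risk. A woman who has already sustained two hip
#' fractures has her hip probability forced to zero.
#'
#' @param state an engine state (see [simulate_cohort()]); only `age` and
#'   `hip_count` are used.
#' @param p an `osteo_params` object.
#' @param rr_eff matrix of effective treatment relative risks (one column per
#'   fracture type in the order hip, vertebral, wrist, other); defaults to 1.
#' @return Matrix of per-type annual probabilities, columns named by type.
#' @export
annual_fracture_probabilities <- function(state, p, rr_eff = NULL) {
  n <- length(state$age)
  if (is.null(rr_eff)) rr_eff <- matrix(1, n, 4)
  pr <- matrix(0, n, 4, dimnames = list(NULL, FRACTURE_TYPES))
  for (j in seq_along(FRACTURE_TYPES)) {
    f <- FRACTURE_TYPES[j]
    pr[, j] <- band_value(p$incidence[[f]], state$age) / 1000 *
      band_value(p$osteo_rr[[f]], state$age) * rr_eff[, j]
  }
  pr[state$hip_count >= 2L, "hip"] <- 0
  if (any(pr > 1)) {
    stop("a fracture probability exceeds 1; check incidence and relative risks")
  }
  pr
}

#' Annual all-cause mortality probability
#'
#' Background band mortality, multiplied after a hip fracture by
#' `1 + af * (RH - 1)` where `af` is the fraction of the observed excess
#' mortality attributable to the fracture itself and `RH` is the relative
#' hazard within the first year after the (most recent) hip fracture or in
#' later years. Vertebral, wrist and other fractures carry no excess
#' mortality. The result is capped at 1.
#'
#' @param state an engine state; uses `age` and `hip_clock` (years since the
#'   most recent hip fracture; negative = none).
#' @param p an `osteo_params` object.
#' @return Vector of annual death probabilities.
#' @export
annual_mortality_probability <- function(state, p) {
  q <- band_value(p$mortality$baseline, state$age)
  af <- p$mortality$attributable_fraction
  m <- rep(1, length(q))
  m[state$hip_clock == 0L] <- 1 + af * (p$mortality$rh_first_year - 1)
  m[state$hip_clock >= 1L] <- 1 + af * (p$mortality$rh_subsequent - 1)
  pmin(1, q * m)
}

#' Advance a cohort state by one annual cycle
#'
#' Applies the within-cycle event ordering to every individual still alive:
#' persistence update at the treatment-year boundary, death draw, then a
#' single categorical fracture draw over `{hip, vertebral, wrist, other,
#' none}`, and finally the tracker updates (fracture counts, hip-fracture
#' clock, adherence clocks, age). At most one fracture can occur per cycle,
#' and a cycle with a death carries no fracture.
#'
#' @param state an engine state (list of parallel vectors; see
#'   [simulate_cohort()]).
#' @param p an `osteo_params` object.
#' @param strategy `"alendronate"`, `"zoledronic"` or `"none"`.
#' @param u optional list of uniform draws for the cycle, with fields
#'   `death`, `fracture`, `persistence` (one value per individual); defaults
#'   to fresh `runif` draws. Supplying these enables common random numbers.
#' @return A list with the updated `state`, the integer `event` codes
#'   (indices into `c("none", "hip", "vertebral", "wrist", "other",
#'   "death")`, 0 = none), `on_cycle` (on treatment during this cycle) and
#'   `midyear_stop` (stopped a mid-year-stop strategy during this cycle).
#' @export
advance_one_cycle <- function(state, p, strategy, u = NULL) {
  n <- length(state$age)
  if (is.null(u)) {
    u <- list(death = stats::runif(n), fracture = stats::runif(n),
              persistence = stats::runif(n))
  }
  alive0 <- state$alive
  ty <- state$cycle + 1L
  midyear <- rep(FALSE, n)

  if (strategy != "none") {
    trt <- p$treatments[[strategy]]
    if (is.null(trt)) stop(sprintf("unknown strategy '%s'", strategy))
    # course completed at the previous boundary
    done <- state$on_treatment & ty > trt$duration
    if (any(done)) {
      state$on_treatment[done] <- FALSE
      state$off_years[done] <- 0
    }
    if (ty <= trt$duration && any(state$on_treatment & alive0)) {
      adh <- list(on_treatment = state$on_treatment & alive0,
                  years_on = state$years_on,
                  years_since_stop = state$off_years)
      adh <- persistence_update(adh, strategy, ty, p, u$persistence)
      stopped <- (state$on_treatment & alive0) & !adh$on_treatment
      state$on_treatment[stopped] <- FALSE
      state$years_on <- adh$years_on
      state$off_years[stopped] <- 0
      midyear <- adh$midyear_stop
    }
  }
  on_cycle <- (state$on_treatment | midyear) & alive0

  # effective relative risks for the cycle; like age bands and adherence,
  # the offset decay is evaluated from the state at cycle start, so the
  # residual effect spans exactly `years_on` cycles after stopping
  rr_eff <- matrix(1, n, 4, dimnames = list(NULL, FRACTURE_TYPES))
  if (strategy != "none") {
    adh_rr <- list(on_treatment = on_cycle,
                   years_on = state$years_on,
                   years_since_stop = state$off_years)
    for (f in FRACTURE_TYPES) {
      rr_eff[, f] <- effective_rr_for_cycle(f, strategy, adh_rr, p)
    }
  }

  # death first: the dead accrue nothing and cannot fracture this cycle
  q <- annual_mortality_probability(state, p)
  died <- alive0 & u$death < q

  pfr <- annual_fracture_probabilities(state, p, rr_eff)
  psum <- rowSums(pfr)
  if (any(psum[alive0] > 1 + 1e-12)) {
    stop("per-type fracture probabilities sum above 1")
  }
  event <- integer(n)
  surv <- alive0 & !died
  cp <- cbind(pfr[, 1L], pfr[, 1L] + pfr[, 2L],
              pfr[, 1L] + pfr[, 2L] + pfr[, 3L], psum)
  uf <- u$fracture
  event[surv & uf < cp[, 4L]] <- 4L
  event[surv & uf < cp[, 3L]] <- 3L
  event[surv & uf < cp[, 2L]] <- 2L
  event[surv & uf < cp[, 1L]] <- 1L
  event[died] <- 5L

  # tracker updates
  state$hip_count <- state$hip_count + (event == 1L)
  state$vertebral_count <- state$vertebral_count + (event == 2L)
  state$wrist_count <- state$wrist_count + (event == 3L)
  state$other_count <- state$other_count + (event == 4L)
  tick <- surv & event != 1L & state$hip_clock >= 0L
  state$hip_clock[tick] <- state$hip_clock[tick] + 1L
  state$hip_clock[event == 1L] <- 0L
  state$alive[died] <- FALSE
  state$age <- state$age + 1L
  state$cycle <- state$cycle + 1L
  off_now <- !on_cycle & state$years_on > 0 & !midyear
  state$off_years[off_now] <- state$off_years[off_now] + 1
  state$off_years[midyear] <- 0.5

  list(state = state, event = event, on_cycle = on_cycle,
       midyear_stop = midyear)
}

# shared cycle loop for one strategy; U holds pregenerated uniform matrices
# (n x n_cycles) so that strategies and sensitivity-analysis reruns can share
# common random numbers. Returns per-individual accumulators.
run_cohort <- function(strategy, start_age, p, U, keep_trajectory = FALSE) {
  n <- nrow(U$death)
  n_cycles <- ncol(U$death)
  state <- init_state(n, start_age, strategy)
  disc_cost <- disc_qaly <- undisc_cost <- undisc_qaly <- ly <- numeric(n)
  comp_tot <- matrix(0, n, 4,
                     dimnames = list(NULL, c("drug", "monitoring", "acute", "ltc")))
  traj <- if (keep_trajectory) vector("list", n_cycles) else NULL

  for (t in seq_len(n_cycles)) {
    if (!any(state$alive)) break
    pre <- state
    step <- advance_one_cycle(state, p, strategy,
                              u = list(death = U$death[, t],
                                       fracture = U$fracture[, t],
                                       persistence = U$persistence[, t]))
    state <- step$state
    adh <- list(on_treatment = step$on_cycle, midyear_stop = step$midyear_stop)
    comp <- cycle_cost(pre, step$event, strategy, adh, p, breakdown = TRUE)
    cost_t <- rowSums(comp)
    util_t <- cycle_utility(pre, step$event, p)
    dfc <- discount_factor(t - 1L, p$discount$cost)
    dfe <- discount_factor(t - 1L, p$discount$effect)
    disc_cost <- disc_cost + cost_t * dfc
    disc_qaly <- disc_qaly + util_t * dfe
    undisc_cost <- undisc_cost + cost_t
    undisc_qaly <- undisc_qaly + util_t
    ly <- ly + (pre$alive & step$event != 5L)
    comp_tot <- comp_tot + comp
    if (keep_trajectory) {
      traj[[t]] <- data.frame(
        cycle = t - 1L, age = pre$age, alive_at_start = pre$alive,
        event = EVENT_LEVELS[step$event + 1L],
        on_treatment = step$on_cycle,
        hip_count = state$hip_count, vertebral_count = state$vertebral_count,
        wrist_count = state$wrist_count, other_count = state$other_count,
        cost = cost_t, utility = util_t)
    }
  }
  list(state = state, disc_cost = disc_cost, disc_qaly = disc_qaly,
       undisc_cost = undisc_cost, undisc_qaly = undisc_qaly,
       life_years = ly, components = comp_tot, trajectory = traj)
}

make_uniforms <- function(n, n_cycles) {
  list(death = matrix(stats::runif(n * n_cycles), n, n_cycles),
       fracture = matrix(stats::runif(n * n_cycles), n, n_cycles),
       persistence = matrix(stats::runif(n * n_cycles), n, n_cycles))
}

#' Simulate one woman's lifetime trajectory
#'
#' Runs a single individual through annual cycles from the start age until
#' death or the horizon age, recording age, event, on-treatment status,
#' fracture trackers and the undiscounted cycle cost and utility.
#'
#' @param strategy `"alendronate"`, `"zoledronic"` or `"none"`.
#' @param start_age integer starting age (>= the first age-band edge).
#' @param p an `osteo_params` object.
#' @param seed optional integer seed for a reproducible trajectory.
#' @return A data frame with one row per lived cycle, ending with death or at
#'   the horizon.
#' @export
simulate_individual <- function(strategy, start_age, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_cycles <- max(1L, p$horizon_age - start_age)
  U <- make_uniforms(1L, n_cycles)
  res <- run_cohort(strategy, start_age, p, U, keep_trajectory = TRUE)
  traj <- do.call(rbind, res$trajectory)
  traj <- traj[traj$alive_at_start, , drop = FALSE]
  traj$alive_at_start <- NULL
  rownames(traj) <- NULL
  traj
}

#' Simulate a cohort one individual at a time
#'
#' Runs `n` independent lifetime trajectories under one strategy and
#' aggregates discounted costs and QALYs (means with Monte-Carlo standard
#' errors), lifetime probabilities of at least one fracture per type, and the
#' probability of death by the horizon age. All random draws come from
#' uniform streams pregenerated from `seed` and indexed by individual, cycle
#' and purpose, so two strategies simulated with the same seed use common
#' random numbers: with identical treatment parameters they produce
#' bit-identical results.
#'
#' @param strategy `"alendronate"`, `"zoledronic"` or `"none"`.
#' @param start_age integer starting age.
#' @param n number of simulated women (>= 1).
#' @param p an `osteo_params` object.
#' @param seed integer seed (mandatory: no silent nondeterminism).
#' @param keep_individuals keep the per-individual discounted cost and QALY
#'   vectors in the result (needed for paired analyses).
#' @return An object of class `cohort_result`.
#' @examples
#' p <- base_case_parameters()
#' simulate_cohort("none", 80, n = 500, p, seed = 1)
#' @export
simulate_cohort <- function(strategy, start_age, n, p, seed,
                            keep_individuals = FALSE) {
  stopifnot(n >= 1)
  set.seed(seed)
  n_cycles <- max(1L, p$horizon_age - start_age)
  U <- make_uniforms(n, n_cycles)
  cohort_from_run(run_cohort(strategy, start_age, p, U),
                  strategy, start_age, n, keep_individuals)
}

cohort_from_run <- function(res, strategy, start_age, n, keep_individuals = FALSE) {
  st <- res$state
  frac_ever <- c(hip = mean(st$hip_count > 0L),
                 vertebral = mean(st$vertebral_count > 0L),
                 wrist = mean(st$wrist_count > 0L),
                 other = mean(st$other_count > 0L))
  out <- list(
    strategy = strategy,
    start_age = start_age,
    n = n,
    mean_cost = mean(res$disc_cost),
    se_cost = stats::sd(res$disc_cost) / sqrt(n),
    mean_qaly = mean(res$disc_qaly),
    se_qaly = stats::sd(res$disc_qaly) / sqrt(n),
    mean_undisc_cost = mean(res$undisc_cost),
    mean_undisc_qaly = mean(res$undisc_qaly),
    mean_life_years = mean(res$life_years),
    se_life_years = stats::sd(res$life_years) / sqrt(n),
    p_fracture = frac_ever,
    p_dead = mean(!st$alive),
    mean_components = colMeans(res$components)
  )
  if (keep_individuals) {
    out$individuals <- data.frame(cost = res$disc_cost, qaly = res$disc_qaly)
  }
  class(out) <- "cohort_result"
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("Cohort: %s, start age %d, n = %s\n", x$strategy, x$start_age,
              format(x$n, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  discounted cost  %10.2f USD  (se %.2f)\n", x$mean_cost, x$se_cost))
  cat(sprintf("  discounted QALYs %10.3f      (se %.4f)\n", x$mean_qaly, x$se_qaly))
  cat(sprintf("  life years       %10.2f\n", x$mean_life_years))
  cat("  lifetime P(>=1 fracture):",
      paste(sprintf("%s %.1f%%", names(x$p_fracture), 100 * x$p_fracture),
            collapse = ", "), "\n")
  cat(sprintf("  dead by horizon: %.1f%%\n", 100 * x$p_dead))
  invisible(x)
}
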