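#' One-way deterministic sensitivity analysis (tornado)
#'
#' Reruns the paired base-case comparison with each ranged parameter (or
#' age-banded parameter group, moved jointly to its bound vector) set to the
#' lower and then the upper end of its published range, all other inputs held
#' at base values. All runs reuse the same pregenerated uniform streams
#' (common random numbers), so varying a cost-only parameter leaves the
#' incremental effect bit-identical and tornado spans are not blurred by
#' Monte-Carlo noise.
#'
#' @param p an `osteo_params` object.
#' @param start_age therapy initiation age.
#' @param n cohort size per strategy per run.
#' @param seed integer seed.
#' @param strategies length-2 character vector `(reference, comparator)`.
#' @return An object of class `osteo_dsa`: a data frame with one row per
#'   parameter group (ICER at each bound, base-case ICER, and the span
#'   `|ICER_upper - ICER_lower|`), sorted by decreasing span.
#' @export
one_way_dsa <- function(p, start_age, n, seed,
                        strategies = c("alendronate", "zoledronic")) {
  d <- p$distributions
  ranged <- d[!is.na(d$lower), , drop = FALSE]   # degenerate ranges span 0
  groups <- unique(ranged$dsa_group)

  set.seed(seed)
  U <- make_uniforms(n, max(1L, p$horizon_age - start_age))
  pair <- function(param) {
    res <- lapply(strategies, function(s) {
      cohort_from_run(run_cohort(s, start_age, param, U), s, start_age, n)
    })
    compare_strategies(res[[1L]], res[[2L]], p$wtp)
  }
  base_cmp <- pair(p)

  rows <- lapply(groups, function(g) {
    lo <- pair(apply_one_way_bound(p, g, "lower"))
    hi <- pair(apply_one_way_bound(p, g, "upper"))
    data.frame(parameter = g,
               icer_lower = lo$icer, icer_upper = hi$icer,
               delta_effect_lower = lo$delta_effect,
               delta_effect_upper = hi$delta_effect,
               icer_base = base_cmp$icer,
               span = abs(hi$icer - lo$icer))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  structure(list(table = out, base = base_cmp, start_age = start_age,
                 n = n, seed = seed),
            class = "osteo_dsa")
}

#' @export
print.osteo_dsa <- function(x, ...) {
  cat(sprintf("One-way sensitivity analysis, start age %d (n = %s per run)\n",
              x$start_age, format(x$n, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  base-case ICER: %s USD/QALY\n",
              format(round(x$base$icer), big.mark = ",", scientific = FALSE)))
  print(x$table, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
plot.osteo_dsa <- function(x, top = 12, ...) {
  tab <- utils::head(x$table[order(-x$table$span), ], top)
  tab <- tab[nrow(tab):1, ]
  lo <- pmin(tab$icer_lower, tab$icer_upper)
  hi <- pmax(tab$icer_lower, tab$icer_upper)
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = range(c(lo, hi, x$base$icer)),
                 ylim = c(0.5, nrow(tab) + 0.5), yaxt = "n",
                 xlab = "ICER (USD/QALY)", ylab = "",
                 main = sprintf("Tornado diagram, age %d", x$start_age), ...)
  graphics::rect(lo, seq_len(nrow(tab)) - 0.35, hi, seq_len(nrow(tab)) + 0.35,
                 col = "grey80")
  graphics::abline(v = x$base$icer, lty = 2)
  graphics::axis(2, at = seq_len(nrow(tab)), labels = tab$parameter, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' Two-level probabilistic sensitivity analysis
#'
#' Outer loop: draw a parameter set from the declared distributions
#' ([sample_psa_draw()]). Inner loop: run a paired microsimulation of
#' `inner` women per strategy under that set (common random numbers within
#' each draw), yielding one incremental cost/effect pair per draw.
#'
#' @param p an `osteo_params` object.
#' @param start_age therapy initiation age.
#' @param outer number of parameter draws.
#' @param inner number of simulated women per strategy per draw.
#' @param seed integer seed.
#' @param strategies length-2 character vector `(reference, comparator)`.
#' @return An object of class `osteo_psa`; `$draws` holds one row per outer
#'   draw with `delta_cost` and `delta_effect`.
#' @export
probabilistic_sa <- function(p, start_age, outer, inner, seed,
                             strategies = c("alendronate", "zoledronic")) {
  stopifnot(outer >= 1, inner >= 1)
  set.seed(seed)
  n_cycles <- max(1L, p$horizon_age - start_age)
  draws <- vector("list", outer)
  for (i in seq_len(outer)) {
    pi <- sample_psa_draw(p)
    U <- make_uniforms(inner, n_cycles)
    res <- lapply(strategies, function(s) {
      cohort_from_run(run_cohort(s, start_age, pi, U), s, start_age, inner)
    })
    draws[[i]] <- data.frame(
      draw = i,
      cost_reference = res[[1L]]$mean_cost,
      cost_comparator = res[[2L]]$mean_cost,
      qaly_reference = res[[1L]]$mean_qaly,
      qaly_comparator = res[[2L]]$mean_qaly,
      delta_cost = res[[2L]]$mean_cost - res[[1L]]$mean_cost,
      delta_effect = res[[2L]]$mean_qaly - res[[1L]]$mean_qaly)
  }
  structure(list(draws = do.call(rbind, draws), start_age = start_age,
                 outer = outer, inner = inner, seed = seed, wtp = p$wtp,
                 strategies = strategies),
            class = "osteo_psa")
}

#' @export
print.osteo_psa <- function(x, ...) {
  cat(sprintf("PSA: %d parameter draws x %s women per strategy, start age %d\n",
              x$outer, format(x$inner, big.mark = ",", scientific = FALSE), x$start_age))
  pce <- mean(x$wtp * x$draws$delta_effect - x$draws$delta_cost > 0)
  cat(sprintf("  mean dC = %.0f USD, mean dE = %.4f QALYs\n",
              mean(x$draws$delta_cost), mean(x$draws$delta_effect)))
  cat(sprintf("  P(%s cost-effective at WTP %s) = %.1f%%\n",
              x$strategies[2L], format(x$wtp, big.mark = ",", scientific = FALSE), 100 * pce))
  invisible(x)
}

#' @export
plot.osteo_psa <- function(x, ...) {
  graphics::plot(x$draws$delta_effect, x$draws$delta_cost,
                 xlab = "Incremental QALYs", ylab = "Incremental cost (USD)",
                 main = sprintf("Cost-effectiveness plane, age %d", x$start_age),
                 pch = 16, col = "#00000055", ...)
  graphics::abline(h = 0, v = 0, col = "grey60")
  graphics::abline(a = 0, b = x$wtp, lty = 2)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that the comparator is
#' cost-effective is the fraction of PSA draws with positive net monetary
#' benefit (`wtp * dE - dC > 0`).
#'
#' @param draws an `osteo_psa` object or a data frame with columns
#'   `delta_cost` and `delta_effect`.
#' @param wtp_grid willingness-to-pay grid (USD/QALY); the default covers 0
#'   to 60,000 in 1,000 steps and always includes 29,340.
#' @return A data frame of class `osteo_ceac` with columns `wtp` and
#'   `p_cost_effective`.
#' @export
ceac_from_draws <- function(draws,
                            wtp_grid = sort(unique(c(seq(0, 60000, by = 1000),
                                                     29340)))) {
  if (inherits(draws, "osteo_psa")) draws <- draws$draws
  stopifnot(nrow(draws) >= 1)
  prob <- vapply(wtp_grid, function(l) {
    mean(l * draws$delta_effect - draws$delta_cost > 0)
  }, numeric(1))
  structure(data.frame(wtp = wtp_grid, p_cost_effective = prob),
            class = c("osteo_ceac", "data.frame"))
}

#' @export
plot.osteo_ceac <- function(x, ...) {
  graphics::plot(x$wtp, x$p_cost_effective, type = "l", ylim = c(0, 1),
                 xlab = "Willingness to pay (USD/QALY)",
                 ylab = "P(cost-effective)",
                 main = "Cost-effectiveness acceptability curve", ...)
  invisible(x)
}

#' Adherence scenario analysis
#'
#' Scenario A sets every persistence schedule to 1 (nobody discontinues
#' within the treatment course), scenario B sets every compliance to 1 (all
#' prescribed doses taken while persistent), and scenario C applies both.
#' Overrides apply to both strategies; drug costs respond automatically since
#' they are proportional to compliance and persistence. The modified
#' comparison is rerun at each starting age.
#'
#' @param scenario `"A"` (full persistence), `"B"` (full compliance) or
#'   `"C"` (both).
#' @param p an `osteo_params` object.
#' @param ages integer vector of therapy-initiation ages.
#' @param n cohort size per strategy per age.
#' @param seed integer seed.
#' @param strategies length-2 character vector `(reference, comparator)`.
#' @return An `osteo_cea` object with a `scenario` element.
#' @export
run_scenario <- function(scenario = c("A", "B", "C"), p, ages, n, seed,
                         strategies = c("alendronate", "zoledronic")) {
  scenario <- match.arg(scenario)
  p2 <- scenario_overrides(p, scenario)
  fit <- ce_microsim(p2, ages = ages, n = n, seed = seed,
                     strategies = strategies, wtp = p$wtp)
  fit$scenario <- scenario
  fit
}

# apply the scenario's persistence/compliance overrides to every strategy
scenario_overrides <- function(p, scenario) {
  for (nm in names(p$treatments)) {
    if (scenario %in% c("A", "C")) {
      p$treatments[[nm]]$persistence <-
        rep(1, length(p$treatments[[nm]]$persistence))
    }
    if (scenario %in% c("B", "C")) {
      p$treatments[[nm]]$compliance <- 1
    }
  }
  p
}
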