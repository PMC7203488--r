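#' Discount factor for an annual cycle
#'
#' @param cycle zero-based cycle index (the first cycle is undiscounted).
#' @param rate annual discount rate (>= 0).
#' @return `(1 + rate)^(-cycle)`.
#' @examples
#' discount_factor(0, 0.03)  # 1
#' discount_factor(1, 0.03)  # 0.9709
#' @export
discount_factor <- function(cycle, rate) {
  stopifnot(all(rate >= 0), all(cycle >= 0))
  (1 + rate)^(-cycle)
}

#' Cost accrued in one cycle
#'
#' Payer-perspective direct costs, by component:
#' \itemize{
#' \item drug: annual price times compliance while on treatment for the whole
#'   year; a half-year charge (times compliance) for women abandoning a
#'   mid-year-stop strategy within its first year; nothing once off treatment;
#' \item monitoring: one physician visit, DXA scan and blood test per
#'   on-treatment year (not charged after discontinuation);
#' \item acute: the one-time direct cost of a fracture sustained this cycle;
#' \item ltc: annual long-term care for every year lived in the post-hip
#'   fracture state (entered the cycle after a first hip fracture, kept for
#'   life, not double-counted after a second hip fracture).
#' }
#' A cycle in which the woman dies accrues nothing (deaths are drawn before
#' fractures and before any treatment exposure is costed).
#'
#' @param state the engine state at the start of the cycle.
#' @param event integer event codes from [advance_one_cycle()].
#' @param strategy `"alendronate"`, `"zoledronic"` or `"none"`.
#' @param adherence list with logical fields `on_treatment` (on treatment
#'   during this cycle) and `midyear_stop`.
#' @param p an `osteo_params` object.
#' @param breakdown return the n x 4 component matrix instead of row sums.
#' @return Numeric vector of undiscounted cycle costs (2018 USD), or the
#'   component matrix when `breakdown = TRUE`.
#' @export
cycle_cost <- function(state, event, strategy, adherence, p, breakdown = FALSE) {
  n <- length(event)
  comp <- matrix(0, n, 4,
                 dimnames = list(NULL, c("drug", "monitoring", "acute", "ltc")))
  accrue <- state$alive & event != 5L
  if (strategy != "none") {
    trt <- p$treatments[[strategy]]
    on <- adherence$on_treatment & accrue
    full_year <- on & !adherence$midyear_stop
    half_year <- on & adherence$midyear_stop
    comp[full_year, "drug"] <- trt$annual_cost * trt$compliance
    comp[half_year, "drug"] <- 0.5 * trt$annual_cost * trt$compliance
    monitoring <- p$costs$physician_visit + p$costs$dxa + p$costs$blood_test
    comp[on, "monitoring"] <- monitoring
  }
  fx <- accrue & event >= 1L & event <= 4L
  comp[fx, "acute"] <- p$costs$fracture[FRACTURE_TYPES[event[fx]]]
  comp[accrue & state$hip_count >= 1L, "ltc"] <- p$costs$post_hip_annual
  if (breakdown) comp else rowSums(comp)
}

#' Utility weight accrued in one cycle
#'
#' The age-band baseline utility, multiplied by the first-year multiplier of
#' a fracture sustained this cycle and by the subsequent-year multipliers of
#' past hip and clinical vertebral fractures (which persist for life); wrist
#' and other fractures reduce utility in their event year only. Multipliers
#' for different fracture types combine multiplicatively; for a repeat
#' fracture of one type only that type's first-year multiplier applies in the
#' event year. A death cycle accrues zero utility.
#'
#' @inheritParams cycle_cost
#' @return Numeric vector of undiscounted cycle utility weights in \[0, 1\].
#' @export
cycle_utility <- function(state, event, p) {
  n <- length(event)
  util <- numeric(n)
  accrue <- state$alive & event != 5L
  base <- band_value(p$utilities$baseline, state$age)
  mult <- rep(1, n)
  hip_now <- event == 1L
  vert_now <- event == 2L
  mult[hip_now] <- mult[hip_now] * p$utilities$hip_first
  mult[vert_now] <- mult[vert_now] * p$utilities$vertebral_first
  mult[event == 3L] <- mult[event == 3L] * p$utilities$wrist_first
  mult[event == 4L] <- mult[event == 4L] * p$utilities$other_first
  past_hip <- state$hip_count >= 1L & !hip_now
  past_vert <- state$vertebral_count >= 1L & !vert_now
  mult[past_hip] <- mult[past_hip] * p$utilities$hip_subsequent
  mult[past_vert] <- mult[past_vert] * p$utilities$vertebral_subsequent
  util[accrue] <- base[accrue] * mult[accrue]
  util
}

# incremental metrics shared by compare_strategies() and the PSA
ce_metrics <- function(delta_cost, delta_effect, wtp) {
  icer <- ifelse(delta_effect != 0, delta_cost / delta_effect, NA_real_)
  label <- rep("icer", length(delta_cost))
  label[delta_effect >= 0 & delta_cost <= 0] <- "dominant"
  label[delta_effect <= 0 & delta_cost >= 0] <- "dominated"
  label[delta_effect == 0 & delta_cost == 0] <- "indifferent"
  icer[label != "icer"] <- NA_real_
  list(icer = icer, label = label,
       nmb = wtp * delta_effect - delta_cost,
       nhb = delta_effect - delta_cost / wtp)
}

#' Compare two simulated strategies
#'
#' Computes the incremental cost and effectiveness of the comparator over the
#' reference (B minus A means), the incremental cost-effectiveness ratio
#' (ICER = dC/dE, replaced by a dominance label when the sign pattern makes a
#' ratio meaningless), the net monetary benefit (NMB = WTP * dE - dC) and the
#' net health benefit (NHB = dE - dC/WTP).
#'
#' @param a,b `cohort_result` objects for the reference and comparator
#'   strategies; they must share the start age and cohort size.
#' @param wtp willingness-to-pay threshold (USD/QALY).
#' @return An object of class `ce_comparison`.
#' @examples
#' # base-case comparison at age 80 on a small cohort
#' p <- base_case_parameters()
#' a <- simulate_cohort("alendronate", 80, 2000, p, seed = 42)
#' b <- simulate_cohort("zoledronic", 80, 2000, p, seed = 42)
#' compare_strategies(a, b, wtp = p$wtp)
#' @export
compare_strategies <- function(a, b, wtp) {
  stopifnot(inherits(a, "cohort_result"), inherits(b, "cohort_result"))
  if (a$start_age != b$start_age || a$n != b$n) {
    stop("cohorts differ in start age or size; comparison must be paired")
  }
  dc <- b$mean_cost - a$mean_cost
  de <- b$mean_qaly - a$mean_qaly
  m <- ce_metrics(dc, de, wtp)
  structure(list(
    start_age = a$start_age,
    n = a$n,
    reference = a$strategy,
    comparator = b$strategy,
    cost_a = a$mean_cost, cost_b = b$mean_cost,
    qaly_a = a$mean_qaly, qaly_b = b$mean_qaly,
    delta_cost = dc, delta_effect = de,
    icer = m$icer, label = m$label, nmb = m$nmb, nhb = m$nhb,
    wtp = wtp
  ), class = "ce_comparison")
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat(sprintf("Cost-effectiveness, start age %d (%s vs %s, n = %s)\n",
              x$start_age, x$comparator, x$reference,
              format(x$n, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  dC = %.2f USD, dE = %.4f QALYs\n", x$delta_cost, x$delta_effect))
  if (x$label == "icer") {
    cat(sprintf("  ICER = %s USD/QALY (WTP %s)\n",
                format(round(x$icer), big.mark = ",", scientific = FALSE),
                format(x$wtp, big.mark = ",", scientific = FALSE)))
  } else {
    cat(sprintf("  %s is %s\n", x$comparator, x$label))
  }
  cat(sprintf("  NMB = %.2f USD, NHB = %.3f QALYs\n", x$nmb, x$nhb))
  invisible(x)
}

#' Run the base-case cost-effectiveness analysis
#'
#' The package's main entry point: simulates the reference and comparator
#' strategies at each starting age with common random numbers (the same
#' pregenerated uniform streams drive both strategies, so differences between
#' arms are due to the treatments alone) and returns the incremental
#' comparison per age.
#'
#' @param p an `osteo_params` object; defaults to [base_case_parameters()].
#' @param ages integer vector of therapy-initiation ages.
#' @param n number of simulated women per strategy per age.
#' @param seed integer seed.
#' @param strategies length-2 character vector `(reference, comparator)`.
#' @param wtp willingness-to-pay threshold; defaults to `p$wtp`.
#' @return An object of class `osteo_cea`: a list of `ce_comparison` objects
#'   plus the per-arm `cohort_result`s.
#' @examples
#' fit <- ce_microsim(n = 2000, ages = c(65, 80), seed = 1)
#' fit
#' as.data.frame(fit)
#' @export
ce_microsim <- function(p = base_case_parameters(),
                        ages = c(65, 70, 75, 80),
                        n = 10000,
                        seed,
                        strategies = c("alendronate", "zoledronic"),
                        wtp = NULL) {
  stopifnot(length(strategies) == 2L, n >= 1)
  if (is.null(wtp)) wtp <- p$wtp
  viol <- validate_parameters(p)
  if (length(viol)) {
    stop("invalid parameter set:\n  ", paste(viol, collapse = "\n  "))
  }
  comparisons <- list()
  cohorts <- list()
  for (age in ages) {
    set.seed(seed + age)
    U <- make_uniforms(n, max(1L, p$horizon_age - age))
    res <- lapply(strategies, function(s) {
      cohort_from_run(run_cohort(s, age, p, U), s, age, n)
    })
    names(res) <- strategies
    cohorts[[as.character(age)]] <- res
    comparisons[[as.character(age)]] <-
      compare_strategies(res[[1L]], res[[2L]], wtp)
  }
  structure(list(comparisons = comparisons, cohorts = cohorts,
                 ages = ages, n = n, seed = seed, wtp = wtp,
                 strategies = strategies),
            class = "osteo_cea")
}

#' @export
print.osteo_cea <- function(x, ...) {
  cat(sprintf("Microsimulation cost-effectiveness analysis: %s vs %s\n",
              x$strategies[2L], x$strategies[1L]))
  cat(sprintf("  n = %s per strategy per age, WTP = %s USD/QALY\n",
              format(x$n, big.mark = ",", scientific = FALSE), format(x$wtp, big.mark = ",", scientific = FALSE)))
  print(as.data.frame(x), row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
summary.osteo_cea <- function(object, ...) {
  df <- as.data.frame(object)
  decision <- ifelse(df$label == "dominant", "comparator dominates",
              ifelse(df$label == "dominated", "comparator dominated",
              ifelse(!is.na(df$icer) & df$icer < object$wtp,
                     "cost-effective at WTP", "not cost-effective at WTP")))
  df$decision <- decision
  df
}

#' Tabulate an analysis in the standard reporting layout
#'
#' One row per strategy per starting age with discounted cost and
#' effectiveness and (on comparator rows) the incremental columns, mirroring
#' the usual base-case results table of a cost-effectiveness study. ICERs are
#' reported to the nearest dollar, NMB to cents and NHB to three decimals.
#'
#' @param x an `osteo_cea` object.
#' @param row.names,optional,... ignored (data frame method signature).
#' @return A data frame.
#' @export
as.data.frame.osteo_cea <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- lapply(x$comparisons, function(cc) {
    data.frame(
      age = cc$start_age,
      cost_reference = round(cc$cost_a, 2),
      cost_comparator = round(cc$cost_b, 2),
      delta_cost = round(cc$delta_cost, 2),
      qaly_reference = round(cc$qaly_a, 3),
      qaly_comparator = round(cc$qaly_b, 3),
      delta_effect = round(cc$delta_effect, 4),
      icer = round(cc$icer),
      label = cc$label,
      nmb = round(cc$nmb, 2),
      nhb = round(cc$nhb, 3)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
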