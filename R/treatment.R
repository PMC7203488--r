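#' Treatment strategies and adherence
#'
#' Three strategies are recognised: `"alendronate"` (weekly oral),
#' `"zoledronic"` (once-yearly infusion) and `"none"` (no intervention).
#' Adherence has two components. *Persistence* is remaining on therapy:
#' at each treatment-year boundary a Bernoulli draw against the year-indexed
#' continuation schedule decides whether the woman stays on treatment (the
#' last stated rate carries forward to any remaining years). *Compliance* is
#' the fraction of prescribed doses actually taken while persistent; it
#' scales both the realised risk reduction and the drug bill. An annual
#' infusion is all-or-nothing, so zoledronic acid compliance is fixed at 1
#' while persistent; oral alendronate uses the observed real-world 0.71.
#'
#' @name treatment_model
NULL

# continuation probability for treatment year `year` (carry-forward rule)
persistence_prob <- function(trt, year) {
  sched <- trt$persistence
  sched[min(year, length(sched))]
}

#' Scale a trial relative risk by compliance
#'
#' The realised relative risk reduction is assumed linear in compliance:
#' `RRR_eff = compliance * (1 - RR_trial)`, so full compliance recovers the
#' trial relative risk and zero compliance leaves fracture risk unchanged.
#'
#' @param rr_trial trial relative risk under full adherence, in (0, 1\].
#' @param compliance fraction of prescribed doses taken, in \[0, 1\].
#' @return The effective relative risk `1 - compliance * (1 - rr_trial)`.
#' @examples
#' compliance_scaled_rr(0.45, 1)     # trial value
#' compliance_scaled_rr(0.50, 0.71)  # 0.645
#' @export
compliance_scaled_rr <- function(rr_trial, compliance) {
  stopifnot(all(rr_trial > 0 & rr_trial <= 1),
            all(compliance >= 0 & compliance <= 1))
  1 - compliance * (1 - rr_trial)
}

#' Residual treatment effect after discontinuation (offset time)
#'
#' After stopping therapy the anti-fracture effect is assumed to wash out
#' linearly over an offset window equal to the time spent on treatment: the
#' effective relative risk interpolates from the value realised at stopping
#' back to 1 as `years_since_stop` runs from 0 to `years_on`, and stays at 1
#' beyond the window.
#'
#' @param rr_at_stop effective relative risk at the moment of stopping
#'   (already compliance-scaled).
#' @param years_on time on treatment in years (> 0); also the offset window.
#' @param years_since_stop non-negative time since stopping, in years.
#' @return The decayed effective relative risk, non-decreasing in
#'   `years_since_stop`.
#' @examples
#' offset_effective_rr(0.5, 3, 0)    # 0.5
#' offset_effective_rr(0.5, 3, 1.5)  # 0.75
#' offset_effective_rr(0.5, 3, 3)    # 1
#' @export
offset_effective_rr <- function(rr_at_stop, years_on, years_since_stop) {
  stopifnot(all(years_on > 0), all(years_since_stop >= 0))
  frac <- pmin(1, years_since_stop / years_on)
  rr_at_stop + (1 - rr_at_stop) * frac
}

#' Effective relative risk for one cycle
#'
#' Combines the adherence state with the compliance and offset rules:
#' on-treatment cycles use the compliance-scaled trial relative risk;
#' post-discontinuation cycles decay that value linearly over the offset
#' window (anchored at the compliance-scaled value, since residual benefit
#' cannot exceed realised benefit); never-treated individuals and the
#' `"none"` strategy always get 1. Like every other cycle quantity (age
#' bands, adherence status), the decay is evaluated from the state at cycle
#' start, so the residual effect spans exactly `years_on` cycles after
#' stopping, fading linearly.
#'
#' @param type fracture type: `"hip"`, `"vertebral"`, `"wrist"` or `"other"`.
#' @param strategy `"alendronate"`, `"zoledronic"` or `"none"`.
#' @param adherence list with vector fields `on_treatment` (logical: on
#'   treatment for the cycle), `years_on` (years completed on treatment) and
#'   `years_since_stop` (completed years since discontinuation at cycle
#'   start, ignored while on treatment).
#' @param p an `osteo_params` object.
#' @return Vector of effective relative risks, each in
#'   `[compliance_scaled_rr, 1]`.
#' @export
effective_rr_for_cycle <- function(type, strategy, adherence, p) {
  n <- length(adherence$on_treatment)
  if (strategy == "none") return(rep(1, n))
  trt <- p$treatments[[strategy]]
  if (is.null(trt)) stop(sprintf("unknown strategy '%s'", strategy))
  anchor <- compliance_scaled_rr(trt$rr[[type]], trt$compliance)
  out <- rep(1, n)
  out[adherence$on_treatment] <- anchor
  off <- !adherence$on_treatment & adherence$years_on > 0
  if (any(off)) {
    out[off] <- offset_effective_rr(anchor, adherence$years_on[off],
                                    adherence$years_since_stop[off])
  }
  out
}

#' One persistence update at a treatment-year boundary
#'
#' Applies the Bernoulli continuation draw for `year` to an adherence state:
#' continuers advance their treatment clock; discontinuers freeze their time
#' on treatment (half a year for first-year discontinuers of a strategy with
#' mid-year stopping, such as weekly oral alendronate) and start the
#' years-since-discontinuation clock.
#'
#' @param adherence list with vector fields `on_treatment`, `years_on`,
#'   `years_since_stop`.
#' @param strategy `"alendronate"` or `"zoledronic"`.
#' @param year treatment year at whose start the draw happens (1-based,
#'   at most the treatment duration).
#' @param u uniform(0,1) draws, one per individual (defaults to `runif`).
#' @param p an `osteo_params` object.
#' @return The updated adherence state, plus a logical field `midyear_stop`
#'   marking individuals who abandoned a mid-year-stop strategy in year 1
#'   (they accrue half a year of drug exposure and cost in that cycle).
#' @export
persistence_update <- function(adherence, strategy, year, p, u = NULL) {
  trt <- p$treatments[[strategy]]
  if (is.null(trt)) stop(sprintf("unknown strategy '%s'", strategy))
  stopifnot(year >= 1, year <= trt$duration)
  n <- length(adherence$on_treatment)
  if (is.null(u)) u <- stats::runif(n)
  adherence$midyear_stop <- rep(FALSE, n)
  at_risk <- adherence$on_treatment
  stay <- u < persistence_prob(trt, year)
  stopping <- at_risk & !stay
  adherence$on_treatment[stopping] <- FALSE
  if (year == 1 && isTRUE(trt$midyear_first_stop)) {
    adherence$years_on[stopping] <- 0.5
    adherence$years_since_stop[stopping] <- 0
    adherence$midyear_stop[stopping] <- TRUE
  } else {
    adherence$years_on[stopping] <- year - 1
    adherence$years_since_stop[stopping] <- 0
  }
  adherence$years_on[at_risk & stay] <- year
  adherence
}
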