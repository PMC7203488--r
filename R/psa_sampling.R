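#' Triangular distribution sampler
#'
#' Inverse-CDF sampling from a triangular distribution with minimum `lower`,
#' mode `mode` and maximum `upper` (the convention used for cost and
#' discount-rate uncertainty). Degenerate ranges (`lower == upper`) return
#' the mode.
#'
#' @param n number of draws.
#' @param lower,mode,upper distribution minimum, mode and maximum.
#' @return Numeric vector of `n` draws.
#' @export
rtriangular <- function(n, lower, mode, upper) {
  if (!(lower <= mode && mode <= upper)) {
    stop("triangular parameters must satisfy lower <= mode <= upper")
  }
  if (upper == lower) return(rep(mode, n))
  u <- stats::runif(n)
  fc <- (mode - lower) / (upper - lower)
  ifelse(u < fc,
         lower + sqrt(u * (upper - lower) * (mode - lower)),
         upper - sqrt((1 - u) * (upper - lower) * (upper - mode)))
}

# Method-of-moments hyperparameters, reading the published range as an
# approximate 95% interval: mean = central value, sd = (upper - lower)/3.92.
beta_moments <- function(central, lower, upper) {
  s <- (upper - lower) / (2 * stats::qnorm(0.975))
  v <- s^2
  if (v <= 0 || central <= 0 || central >= 1 || v >= central * (1 - central)) {
    stop(sprintf(
      "beta moment matching infeasible for mean %.4g, sd %.4g", central, s))
  }
  nu <- central * (1 - central) / v - 1
  c(shape1 = central * nu, shape2 = (1 - central) * nu)
}

gamma_moments <- function(central, lower, upper) {
  s <- (upper - lower) / (2 * stats::qnorm(0.975))
  if (s <= 0 || central <= 0) {
    stop(sprintf(
      "gamma moment matching infeasible for mean %.4g, sd %.4g", central, s))
  }
  c(shape = (central / s)^2, rate = central / s^2)
}

# one draw from a registry row; zero-width ranges collapse to the central
# value so that degenerate specifications reproduce the base case exactly
draw_one <- function(family, central, lower, upper) {
  if (is.na(lower) || family == "none") return(central)
  if (upper == lower) return(central)
  switch(family,
    beta = {
      m <- beta_moments(central, lower, upper)
      stats::rbeta(1L, m[["shape1"]], m[["shape2"]])
    },
    gamma = {
      m <- gamma_moments(central, lower, upper)
      stats::rgamma(1L, shape = m[["shape"]], rate = m[["rate"]])
    },
    triangular = rtriangular(1L, lower, central, upper),
    stop(sprintf("unknown distribution family '%s'", family))
  )
}

# legal support for re-draws, by parameter id prefix
legal_bounds <- function(id) {
  if (grepl("^(aln|zol)_rr_|^utility_", id)) c(1e-12, 1) else
  if (grepl("^discount_", id)) c(0, 0.05) else
  if (grepl("^osteo_rr_|^mortality_rh_", id)) c(1e-12, Inf) else
  c(0, Inf)
}

#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Every parameter with a declared sampling family is redrawn from that
#' family: beta and gamma parameters are moment-matched so that the mean
#' equals the published central value and the standard deviation equals
#' (upper - lower)/3.92 (ranges read as approximate 95% intervals);
#' triangular parameters use (lower, central, upper) as (min, mode, max).
#' Parameters whose family is `"none"` keep their base values. Draws falling
#' outside a parameter's legal support are re-drawn, and the returned set is
#' guaranteed to pass [validate_parameters()]. Draws are independent across
#' parameters and consume the current R random-number stream.
#'
#' @param p an `osteo_params` object (typically [base_case_parameters()]).
#' @param max_redraws cap on re-draws per parameter before erroring.
#' @return A new `osteo_params` object with sampled values.
#' @export
sample_psa_draw <- function(p, max_redraws = 100L) {
  d <- p$distributions
  for (i in seq_len(nrow(d))) {
    if (d$family[i] == "none" || is.na(d$lower[i])) next
    bounds <- legal_bounds(d$id[i])
    for (k in seq_len(max_redraws)) {
      v <- draw_one(d$family[i], d$central[i], d$lower[i], d$upper[i])
      if (v >= bounds[1L] && v <= bounds[2L]) break
      if (k == max_redraws) {
        stop(sprintf("could not draw a legal value for '%s'", d$id[i]))
      }
    }
    p <- param_set(p, d$path[i], v)
  }
  stopifnot(length(validate_parameters(p)) == 0L)
  p
}
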