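#' Generate a synthetic parameter set
#'
#' Builds a randomly generated but structurally valid parameter set with the
#' same shape as [base_case_parameters()]: age-banded incidence and
#' osteoporosis relative-risk tables, two treatment strategies, cost and
#' utility tables, mortality with hip-fracture excess hazards, and a
#' distribution registry. Intended for property testing: the construction
#' guarantees [validate_parameters()] returns no violations for any random
#' stream and any legal knob setting.
#'
#' Knobs control the stress patterns the tests rely on:
#' `identical_strategies` makes the two treatments exact copies (so paired
#' simulation under common random numbers must produce identical cohorts),
#' `incidence_scale = 0` disables fractures entirely, `mortality` overrides
#' all background mortality (e.g. `0` forces survival to the horizon, `1`
#' kills everyone in the first cycle), and `effect_gap` sets the relative
#' advantage of the second strategy's relative risks over the first's.
#'
#' @param n_bands number of age bands starting at age 65 (5-year spacing).
#' @param incidence_scale multiplier on random fracture incidence
#'   (per 1,000 person-years in (0, 20\] before scaling).
#' @param cost_scale multiplier on random costs.
#' @param effect_gap fraction in \[0, 1): strategy-2 relative risks are
#'   strategy-1 values scaled by `1 - effect_gap`.
#' @param identical_strategies copy strategy 1 into strategy 2.
#' @param mortality optional scalar in \[0, 1\] replacing all band mortality.
#' @return An `osteo_params` object.
#' @examples
#' set.seed(7)
#' p <- synthetic_parameter_set(incidence_scale = 0)
#' validate_parameters(p)
#' @export
synthetic_parameter_set <- function(n_bands = 5L,
                                    incidence_scale = 1,
                                    cost_scale = 1,
                                    effect_gap = 0.1,
                                    identical_strategies = FALSE,
                                    mortality = NULL) {
  stopifnot(n_bands >= 1L, incidence_scale >= 0, cost_scale >= 0,
            effect_gap >= 0, effect_gap < 1)
  bands <- seq(65, by = 5, length.out = n_bands)
  ft <- c("hip", "vertebral", "wrist", "other")

  rinc <- function() {
    age_band_table(bands, incidence_scale * stats::runif(n_bands, 0.5, 20), "rate")
  }
  rrr <- function() {
    age_band_table(bands, sort(stats::runif(n_bands, 1, 4), decreasing = TRUE), "rate")
  }
  mort_values <- if (is.null(mortality)) {
    sort(stats::runif(n_bands, 0.005, 0.2))
  } else {
    rep(mortality, n_bands)
  }

  trt1 <- list(
    label = "alendronate",
    dosing = "synthetic oral weekly",
    rr = stats::setNames(stats::runif(4, 0.3, 0.9), ft),
    persistence = stats::runif(sample(1:3, 1L), 0.4, 1),
    compliance = stats::runif(1, 0.5, 1),
    duration = sample(2:5, 1L),
    annual_cost = cost_scale * stats::runif(1, 200, 1500),
    midyear_first_stop = TRUE
  )
  trt2 <- if (identical_strategies) {
    t2 <- trt1
    t2$label <- "zoledronic"
    t2
  } else {
    list(
      label = "zoledronic",
      dosing = "synthetic yearly infusion",
      rr = pmax(trt1$rr * (1 - effect_gap), 0.05),
      persistence = stats::runif(sample(1:3, 1L), 0.4, 1),
      compliance = 1.0,
      duration = sample(2:5, 1L),
      annual_cost = cost_scale * stats::runif(1, 200, 1500),
      midyear_first_stop = FALSE
    )
  }

  p <- list(
    horizon_age = 65 + 5 * n_bands + 20,
    incidence = stats::setNames(replicate(4, rinc(), simplify = FALSE), ft),
    osteo_rr = stats::setNames(replicate(4, rrr(), simplify = FALSE), ft),
    treatments = list(alendronate = trt1, zoledronic = trt2),
    costs = list(
      fracture = stats::setNames(cost_scale * stats::runif(4, 500, 8000), ft),
      post_hip_annual = cost_scale * stats::runif(1, 1000, 6000),
      dxa = cost_scale * stats::runif(1, 40, 120),
      blood_test = cost_scale * stats::runif(1, 30, 100),
      physician_visit = cost_scale * stats::runif(1, 5, 20)
    ),
    utilities = list(
      baseline = age_band_table(bands,
                                sort(stats::runif(n_bands, 0.55, 0.9),
                                     decreasing = TRUE), "utility"),
      hip_first = stats::runif(1, 0.6, 0.9),
      hip_subsequent = stats::runif(1, 0.7, 0.95),
      vertebral_first = stats::runif(1, 0.6, 0.9),
      vertebral_subsequent = stats::runif(1, 0.7, 0.95),
      wrist_first = stats::runif(1, 0.85, 1),
      other_first = stats::runif(1, 0.85, 1)
    ),
    mortality = list(
      baseline = age_band_table(bands, mort_values, "probability"),
      rh_first_year = stats::runif(1, 1, 4),
      rh_subsequent = stats::runif(1, 1, 2.5),
      attributable_fraction = stats::runif(1)
    ),
    discount = list(cost = stats::runif(1, 0, 0.05),
                    effect = stats::runif(1, 0, 0.05)),
    wtp = stats::runif(1, 5000, 60000)
  )
  p$distributions <- synthetic_distributions(p)
  class(p) <- "osteo_params"
  p
}

# registry with +/-20% ranges (clamped into each parameter's legal support)
synthetic_distributions <- function(p) {
  rows <- list()
  add <- function(id, path, family, central, dsa_group = id) {
    if (family == "beta") {
      lower <- max(1e-6, central * 0.8)
      upper <- central + 0.2 * min(central, 1 - central)
      if (upper <= central) upper <- min(1 - 1e-9, central + 1e-6)
    } else {
      lower <- central * 0.8
      upper <- central * 1.2
      if (upper == lower) upper <- lower + 1e-9
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, path = path, family = family, central = central,
      lower = lower, upper = upper, dsa_group = dsa_group,
      stringsAsFactors = FALSE)
  }
  ft <- c("hip", "vertebral", "wrist", "other")
  for (nm in names(p$treatments)) {
    pre <- if (nm == "alendronate") "aln" else "zol"
    for (f in ft) {
      add(sprintf("%s_rr_%s", pre, f),
          sprintf("treatments/%s/rr/%s", nm, f), "beta",
          p$treatments[[nm]]$rr[[f]])
    }
    add(sprintf("%s_annual_cost", pre),
        sprintf("treatments/%s/annual_cost", nm), "triangular",
        p$treatments[[nm]]$annual_cost)
  }
  for (f in ft) {
    add(sprintf("cost_fracture_%s", f), sprintf("costs/fracture/%s", f),
        "triangular", p$costs$fracture[[f]])
    for (b in seq_along(p$osteo_rr[[f]]$value)) {
      add(sprintf("osteo_rr_%s_band%d", f, b),
          sprintf("osteo_rr/%s/value/%d", f, b), "gamma",
          p$osteo_rr[[f]]$value[b], dsa_group = sprintf("osteo_rr_%s", f))
    }
  }
  add("cost_post_hip_annual", "costs/post_hip_annual", "triangular",
      p$costs$post_hip_annual)
  for (b in seq_along(p$utilities$baseline$value)) {
    add(sprintf("utility_band%d", b),
        sprintf("utilities/baseline/value/%d", b), "beta",
        p$utilities$baseline$value[b], dsa_group = "baseline_utility")
  }
  do.call(rbind, rows)
}
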