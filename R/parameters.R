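#' Base-case model parameters
#'
#' Builds the complete parameter set of the base-case analysis: age-banded
#' annual fracture incidence (per 1,000 person-years, general female
#' population) for hip, clinical vertebral, wrist and other osteoporotic
#' fractures; age-banded relative risks converting those rates to the
#' osteoporotic (T-score <= -2.5) subpopulation; the two drug strategies with
#' their trial relative risks, persistence schedules, compliance, treatment
#' duration and annual price (2018 USD); fracture, long-term-care and
#' monitoring costs; baseline utilities and fracture utility multipliers;
#' background mortality with hip-fracture excess-mortality hazards; discount
#' rates; and the willingness-to-pay threshold (three times China's 2018
#' per-capita GDP, $29,340/QALY).
#'
#' Each parameter with a published uncertainty range also carries a
#' distribution specification (beta, gamma or triangular) in the
#' `distributions` registry, used by [sample_psa_draw()] and
#' [apply_one_way_bound()].
#'
#' Two adherence conventions are encoded per strategy: weekly oral
#' alendronate can be abandoned mid-year (first-year discontinuers accrue
#' half a year of drug exposure and cost), whereas the once-yearly zoledronic
#' acid infusion is all-or-nothing, so its compliance is 1 while persistent
#' and discontinuation can only happen at an infusion boundary. Both
#' treatment courses default to 3 years (three annual infusions for
#' zoledronic acid, and the same intended course length for alendronate so
#' the strategies are compared like for like); durations are plain list
#' fields and can be edited before simulation.
#'
#' @return An object of class `osteo_params`; see [validate_parameters()].
#' @examples
#' p <- base_case_parameters()
#' p$treatments$zoledronic$rr[["hip"]]
#' p$wtp
#' @export
base_case_parameters <- function() {
  bands5 <- c(65, 70, 75, 80, 85)
  bands3 <- c(65, 70, 80)

  p <- list(
    horizon_age = 105,
    incidence = list(
      hip        = age_band_table(bands5, c(0.96, 2.33, 4.08, 6.44, 6.59), "rate"),
      vertebral  = age_band_table(bands5, c(5.64, 8.74, 12.05, 21.19, 26.89), "rate"),
      wrist      = age_band_table(bands5, c(12.95, 13.17, 13.87, 15.01, 15.10), "rate"),
      other      = age_band_table(bands5, c(6.60, 9.84, 14.44, 18.06, 26.06), "rate")
    ),
    osteo_rr = list(
      hip        = age_band_table(bands5, c(3.91, 3.13, 2.60, 2.04, 1.92), "rate"),
      vertebral  = age_band_table(bands3, c(2.59, 2.15, 1.82), "rate"),
      wrist      = age_band_table(bands3, c(1.78, 1.60, 1.45), "rate"),
      other      = age_band_table(bands3, c(2.19, 1.88, 1.64), "rate")
    ),
    treatments = list(
      alendronate = list(
        label = "alendronate",
        dosing = "70 mg oral, once weekly",
        rr = c(hip = 0.45, vertebral = 0.50, wrist = 0.50, other = 0.78),
        # year-indexed conditional continuation probabilities; the last
        # stated rate carries forward to the remaining treatment years
        persistence = c(0.57),
        compliance = 0.71,
        duration = 3,
        annual_cost = 761.64,
        midyear_first_stop = TRUE
      ),
      zoledronic = list(
        label = "zoledronic",
        dosing = "5 mg intravenous infusion, once yearly",
        rr = c(hip = 0.50, vertebral = 0.35, wrist = 0.75, other = 0.69),
        # the first infusion defines entry into the strategy; persistence
        # decisions happen at the year-2 (and later) infusion boundaries
        persistence = c(1.0, 0.73),
        compliance = 1.0,
        duration = 3,
        annual_cost = 818.50,
        midyear_first_stop = FALSE
      )
    ),
    costs = list(
      fracture = c(hip = 7103.25, vertebral = 1310.11, wrist = 967.34,
                   other = 1692.41),
      post_hip_annual = 4438.08,
      dxa = 85,
      blood_test = 72,
      physician_visit = 10
    ),
    utilities = list(
      baseline = age_band_table(bands5, c(0.806, 0.747, 0.731, 0.699, 0.676),
                                "utility"),
      hip_first = 0.776,
      hip_subsequent = 0.855,
      vertebral_first = 0.724,
      vertebral_subsequent = 0.868,
      wrist_first = 0.940,
      other_first = 0.910
    ),
    mortality = list(
      baseline = age_band_table(bands5,
                                c(0.01031, 0.02036, 0.03784, 0.06998, 0.13603),
                                "probability"),
      rh_first_year = 2.87,
      rh_subsequent = 1.73,
      attributable_fraction = 0.25
    ),
    discount = list(cost = 0.03, effect = 0.03),
    wtp = 29340
  )
  p$distributions <- base_case_distributions()
  class(p) <- "osteo_params"
  p
}

# Distribution registry: one row per parameter with a published range.
# `path` addresses the scalar inside the parameter list ("/"-separated;
# numeric components index into vectors), `family` is the PSA sampling family
# ("none" = range published but never sampled), and `dsa_group` collects
# age-banded values that a one-way sensitivity analysis moves jointly.
base_case_distributions <- function() {
  row <- function(id, path, family, central, lower, upper, dsa_group = id) {
    data.frame(id = id, path = path, family = family, central = central,
               lower = lower, upper = upper, dsa_group = dsa_group,
               stringsAsFactors = FALSE)
  }
  rbind(
    row("aln_rr_hip",       "treatments/alendronate/rr/hip",       "beta", 0.45, 0.27, 0.68),
    row("aln_rr_vertebral", "treatments/alendronate/rr/vertebral", "beta", 0.50, 0.33, 0.79),
    row("aln_rr_wrist",     "treatments/alendronate/rr/wrist",     "beta", 0.50, 0.34, 0.73),
    row("aln_rr_other",     "treatments/alendronate/rr/other",     "beta", 0.78, 0.66, 0.92),
    row("zol_rr_hip",       "treatments/zoledronic/rr/hip",        "beta", 0.50, 0.34, 0.73),
    row("zol_rr_vertebral", "treatments/zoledronic/rr/vertebral",  "beta", 0.35, 0.20, 0.64),
    row("zol_rr_wrist",     "treatments/zoledronic/rr/wrist",      "beta", 0.75, 0.64, 0.87),
    row("zol_rr_other",     "treatments/zoledronic/rr/other",      "beta", 0.69, 0.55, 0.84),

    row("aln_annual_cost",  "treatments/alendronate/annual_cost", "triangular", 761.64, 533.15, 990.13),
    row("zol_annual_cost",  "treatments/zoledronic/annual_cost",  "triangular", 818.50, 572.95, 1064.05),
    row("cost_fracture_hip",       "costs/fracture/hip",       "triangular", 7103.25, 4972.28, 9234.23),
    row("cost_fracture_vertebral", "costs/fracture/vertebral", "triangular", 1310.11, 917.08, 1703.14),
    row("cost_fracture_wrist",     "costs/fracture/wrist",     "triangular", 967.34, 677.14, 1257.54),
    row("cost_fracture_other",     "costs/fracture/other",     "triangular", 1692.41, 1184.69, 2200.13),
    row("cost_post_hip_annual",    "costs/post_hip_annual",    "triangular", 4438.08, 3106.66, 5769.50),
    row("cost_dxa",                "costs/dxa",                "triangular", 85, 59.5, 110.5),
    row("cost_blood_test",         "costs/blood_test",         "triangular", 72, 50.4, 93.6),
    row("cost_physician_visit",    "costs/physician_visit",    "triangular", 10, 7, 13),

    row("utility_age_65_69", "utilities/baseline/value/1", "beta", 0.806, 0.765, 0.846, "baseline_utility"),
    row("utility_age_70_74", "utilities/baseline/value/2", "beta", 0.747, 0.709, 0.784, "baseline_utility"),
    row("utility_age_75_79", "utilities/baseline/value/3", "beta", 0.731, 0.694, 0.767, "baseline_utility"),
    row("utility_age_80_84", "utilities/baseline/value/4", "beta", 0.699, 0.664, 0.733, "baseline_utility"),
    row("utility_age_85",    "utilities/baseline/value/5", "beta", 0.676, 0.642, 0.709, "baseline_utility"),

    row("utility_mult_hip_first",            "utilities/hip_first",            "beta", 0.776, 0.720, 0.844),
    row("utility_mult_hip_subsequent",       "utilities/hip_subsequent",       "beta", 0.855, 0.800, 0.909),
    row("utility_mult_vertebral_first",      "utilities/vertebral_first",      "beta", 0.724, 0.667, 0.779),
    row("utility_mult_vertebral_subsequent", "utilities/vertebral_subsequent", "beta", 0.868, 0.827, 0.922),
    row("utility_mult_wrist",                "utilities/wrist_first",          "beta", 0.940, 0.910, 0.960),
    row("utility_mult_other",                "utilities/other_first",          "beta", 0.910, 0.880, 0.940),

    row("osteo_rr_hip_65_69", "osteo_rr/hip/value/1", "gamma", 3.91, 3.28, 4.56, "osteo_rr_hip"),
    row("osteo_rr_hip_70_74", "osteo_rr/hip/value/2", "gamma", 3.13, 2.80, 3.47, "osteo_rr_hip"),
    row("osteo_rr_hip_75_79", "osteo_rr/hip/value/3", "gamma", 2.60, 2.39, 2.82, "osteo_rr_hip"),
    row("osteo_rr_hip_80_84", "osteo_rr/hip/value/4", "gamma", 2.04, 1.91, 2.17, "osteo_rr_hip"),
    row("osteo_rr_hip_85",    "osteo_rr/hip/value/5", "gamma", 1.92, 1.78, 2.05, "osteo_rr_hip"),
    row("osteo_rr_vertebral_65_69", "osteo_rr/vertebral/value/1", "gamma", 2.59, 1.19, 4.27, "osteo_rr_vertebral"),
    row("osteo_rr_vertebral_70_79", "osteo_rr/vertebral/value/2", "gamma", 2.15, 1.15, 3.15, "osteo_rr_vertebral"),
    row("osteo_rr_vertebral_80",    "osteo_rr/vertebral/value/3", "gamma", 1.82, 1.12, 2.41, "osteo_rr_vertebral"),
    row("osteo_rr_wrist_65_69", "osteo_rr/wrist/value/1", "gamma", 1.78, 1.78, 2.19, "osteo_rr_wrist"),
    row("osteo_rr_wrist_70_79", "osteo_rr/wrist/value/2", "gamma", 1.60, 1.60, 1.88, "osteo_rr_wrist"),
    row("osteo_rr_wrist_80",    "osteo_rr/wrist/value/3", "gamma", 1.45, 1.45, 1.64, "osteo_rr_wrist"),
    row("osteo_rr_other_65_69", "osteo_rr/other/value/1", "gamma", 2.19, 1.78, 2.59, "osteo_rr_other"),
    row("osteo_rr_other_70_79", "osteo_rr/other/value/2", "gamma", 1.88, 1.60, 2.15, "osteo_rr_other"),
    row("osteo_rr_other_80",    "osteo_rr/other/value/3", "gamma", 1.64, 1.45, 1.82, "osteo_rr_other"),

    # excess-mortality hazards: a range is published (used in one-way DSA)
    # but no sampling family, so they are held fixed in the PSA
    row("mortality_rh_first_year", "mortality/rh_first_year", "none", 2.87, 2.52, 3.27),
    row("mortality_rh_subsequent", "mortality/rh_subsequent", "none", 1.73, 1.56, 1.90),

    row("discount_cost",   "discount/cost",   "triangular", 0.03, 0, 0.05),
    row("discount_effect", "discount/effect", "triangular", 0.03, 0, 0.05)
  )
}

# ---- path addressing into the nested parameter list ------------------------

param_get <- function(p, path) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1L]]
  x <- p
  for (k in parts) {
    if (grepl("^[0-9]+$", k)) k <- as.integer(k)
    x <- x[[k]]
    if (is.null(x)) stop(sprintf("unknown parameter path '%s'", path))
  }
  x
}

param_set <- function(p, path, value) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1L]]
  rec <- function(x, parts) {
    k <- parts[[1L]]
    if (grepl("^[0-9]+$", k)) k <- as.integer(k)
    if (is.null(x[[k]])) stop(sprintf("unknown parameter path '%s'", path))
    if (length(parts) == 1L) {
      x[[k]] <- value
    } else {
      x[[k]] <- rec(x[[k]], parts[-1L])
    }
    x
  }
  rec(p, parts)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of an `osteo_params` object: age-band
#' tables (contiguity, finiteness, legal value ranges), treatment relative
#' risks in (0, 1], persistence and compliance in \[0, 1\], durations >= 1
#' year, non-negative costs, utility multipliers in (0, 1], excess-mortality
#' hazards >= 1, attributable fraction in \[0, 1\], discount rates in
#' \[0, 0.05\], a positive willingness-to-pay, and ordered
#' lower <= central <= upper distribution ranges. Violations are returned,
#' not raised, so that sampling and perturbation code can re-check candidate
#' sets cheaply.
#'
#' @param p an `osteo_params` object.
#' @return A character vector of violation messages; `character(0)` when the
#'   set satisfies every invariant.
#' @examples
#' length(validate_parameters(base_case_parameters())) == 0
#' @export
validate_parameters <- function(p) {
  out <- character()
  ft <- c("hip", "vertebral", "wrist", "other")

  for (f in ft) {
    out <- c(out, check_age_band_table(p$incidence[[f]], sprintf("incidence/%s", f)))
    out <- c(out, check_age_band_table(p$osteo_rr[[f]], sprintf("osteo_rr/%s", f)))
  }
  for (nm in names(p$treatments)) {
    trt <- p$treatments[[nm]]
    if (any(trt$rr <= 0 | trt$rr > 1)) {
      bad <- ft[trt$rr[ft] <= 0 | trt$rr[ft] > 1]
      out <- c(out, sprintf("treatments/%s/rr/%s: relative risk outside (0, 1]",
                            nm, bad))
    }
    if (any(trt$persistence < 0 | trt$persistence > 1)) {
      out <- c(out, sprintf("treatments/%s/persistence: outside [0, 1]", nm))
    }
    if (trt$compliance < 0 || trt$compliance > 1) {
      out <- c(out, sprintf("treatments/%s/compliance: outside [0, 1]", nm))
    }
    if (trt$duration < 1) {
      out <- c(out, sprintf("treatments/%s/duration: below 1 year", nm))
    }
    if (trt$annual_cost < 0) {
      out <- c(out, sprintf("treatments/%s/annual_cost: negative", nm))
    }
  }
  if (any(p$costs$fracture < 0)) {
    out <- c(out, sprintf("costs/fracture/%s: negative",
                          ft[p$costs$fracture[ft] < 0]))
  }
  for (nm in c("post_hip_annual", "dxa", "blood_test", "physician_visit")) {
    if (p$costs[[nm]] < 0) out <- c(out, sprintf("costs/%s: negative", nm))
  }
  out <- c(out, check_age_band_table(p$utilities$baseline, "utilities/baseline"))
  for (nm in c("hip_first", "hip_subsequent", "vertebral_first",
               "vertebral_subsequent", "wrist_first", "other_first")) {
    v <- p$utilities[[nm]]
    if (v <= 0 || v > 1) {
      out <- c(out, sprintf("utilities/%s: multiplier outside (0, 1]", nm))
    }
  }
  out <- c(out, check_age_band_table(p$mortality$baseline, "mortality/baseline"))
  if (p$mortality$rh_first_year < 1) {
    out <- c(out, "mortality/rh_first_year: relative hazard below 1")
  }
  if (p$mortality$rh_subsequent < 1) {
    out <- c(out, "mortality/rh_subsequent: relative hazard below 1")
  }
  af <- p$mortality$attributable_fraction
  if (af < 0 || af > 1) {
    out <- c(out, "mortality/attributable_fraction: outside [0, 1]")
  }
  for (nm in c("cost", "effect")) {
    r <- p$discount[[nm]]
    if (r < 0 || r > 0.05) {
      out <- c(out, sprintf("discount/%s: outside [0, 0.05]", nm))
    }
  }
  if (p$wtp <= 0) out <- c(out, "wtp: not positive")

  d <- p$distributions
  ranged <- !is.na(d$lower)
  bad <- ranged & !(d$lower <= d$central & d$central <= d$upper)
  if (any(bad)) {
    out <- c(out, sprintf("distributions/%s: range not ordered lower <= central <= upper",
                          d$id[bad]))
  }
  out
}

#' Set one parameter to a bound of its published range
#'
#' Support for one-way deterministic sensitivity analysis: returns a copy of
#' the parameter set in which exactly the named parameter (or, for an
#' age-banded group such as `"osteo_rr_hip"` or `"baseline_utility"`, its
#' whole bound vector) is replaced by the lower or upper end of its published
#' range; every other field is untouched.
#'
#' @param p an `osteo_params` object.
#' @param name a parameter id or DSA group name from `p$distributions`.
#' @param which `"lower"` or `"upper"`.
#' @return The perturbed `osteo_params` object.
#' @examples
#' p <- apply_one_way_bound(base_case_parameters(), "zol_annual_cost", "upper")
#' p$treatments$zoledronic$annual_cost  # 1064.05
#' @export
apply_one_way_bound <- function(p, name, which = c("lower", "upper")) {
  which <- match.arg(which)
  d <- p$distributions
  rows <- which(d$id == name)
  if (length(rows) == 0L) rows <- which(d$dsa_group == name)
  if (length(rows) == 0L) {
    stop(sprintf("unknown parameter or group '%s'", name))
  }
  if (anyNA(d$lower[rows])) {
    stop(sprintf("parameter '%s' has no published range", name))
  }
  for (i in rows) {
    p <- param_set(p, d$path[i], d[[which]][i])
  }
  p
}

#' Enumerate every scalar model input
#'
#' Flattens the parameter set to one row per scalar leaf (each published
#' input appears exactly once), used by the completeness census in the test
#' suite and by the provenance digest.
#'
#' @param p an `osteo_params` object.
#' @return A data frame with columns `field` and `value`.
#' @export
parameter_census <- function(p) {
  ft <- c("hip", "vertebral", "wrist", "other")
  rows <- list()
  add <- function(field, value) {
    rows[[length(rows) + 1L]] <<- data.frame(field = field, value = value,
                                             stringsAsFactors = FALSE)
  }
  for (f in ft) {
    tab <- p$incidence[[f]]
    add(sprintf("incidence/%s/band%d", f, seq_along(tab$value)), tab$value)
    tab <- p$osteo_rr[[f]]
    add(sprintf("osteo_rr/%s/band%d", f, seq_along(tab$value)), tab$value)
  }
  for (nm in names(p$treatments)) {
    trt <- p$treatments[[nm]]
    add(sprintf("treatments/%s/rr/%s", nm, ft), trt$rr[ft])
    add(sprintf("treatments/%s/persistence/year%d", nm,
                seq_along(trt$persistence)), trt$persistence)
    add(sprintf("treatments/%s/compliance", nm), trt$compliance)
    add(sprintf("treatments/%s/duration", nm), trt$duration)
    add(sprintf("treatments/%s/annual_cost", nm), trt$annual_cost)
  }
  add(sprintf("costs/fracture/%s", ft), p$costs$fracture[ft])
  for (nm in c("post_hip_annual", "dxa", "blood_test", "physician_visit")) {
    add(sprintf("costs/%s", nm), p$costs[[nm]])
  }
  tab <- p$utilities$baseline
  add(sprintf("utilities/baseline/band%d", seq_along(tab$value)), tab$value)
  for (nm in c("hip_first", "hip_subsequent", "vertebral_first",
               "vertebral_subsequent", "wrist_first", "other_first")) {
    add(sprintf("utilities/%s", nm), p$utilities[[nm]])
  }
  tab <- p$mortality$baseline
  add(sprintf("mortality/baseline/band%d", seq_along(tab$value)), tab$value)
  add("mortality/rh_first_year", p$mortality$rh_first_year)
  add("mortality/rh_subsequent", p$mortality$rh_subsequent)
  add("mortality/attributable_fraction", p$mortality$attributable_fraction)
  add("discount/cost", p$discount$cost)
  add("discount/effect", p$discount$effect)
  add("wtp", p$wtp)
  do.call(rbind, rows)
}

#' @export
print.osteo_params <- function(x, ...) {
  cen <- parameter_census(x)
  cat("Osteoporosis microsimulation parameter set\n")
  cat(sprintf("  strategies: %s\n",
              paste(vapply(x$treatments, `[[`, "", "label"), collapse = ", ")))
  cat(sprintf("  %d scalar inputs (%d with uncertainty ranges)\n",
              nrow(cen), sum(!is.na(x$distributions$lower))))
  cat(sprintf("  discounting: costs %.1f%%, effects %.1f%%; WTP $%s/QALY\n",
              100 * x$discount$cost, 100 * x$discount$effect,
              format(x$wtp, big.mark = ",")))
  invisible(x)
}

# ---- configuration file I/O -------------------------------------------------

#' Write / read a parameter configuration file
#'
#' Parameter sets are serialised to a human-readable JSON configuration file.
#' Doubles are written with 17 significant digits so that a write/read
#' round-trip reproduces every field bit-exactly.
#'
#' @param p an `osteo_params` object.
#' @param path file path of the configuration file.
#' @return `write_parameters()` returns `path` invisibly; `read_parameters()`
#'   returns the `osteo_params` object.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "osteo_params"))
  x <- unclass(p)
  for (blk in c("incidence", "osteo_rr")) {
    x[[blk]] <- lapply(x[[blk]], unclass)
  }
  # named atomic vectors must go out as JSON objects, not nameless arrays
  for (nm in names(x$treatments)) {
    x$treatments[[nm]]$rr <- as.list(x$treatments[[nm]]$rr)
  }
  x$costs$fracture <- as.list(x$costs$fracture)
  x$utilities$baseline <- unclass(x$utilities$baseline)
  x$mortality$baseline <- unclass(x$mortality$baseline)
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  # every numeric field of the model is a double; JSON re-import turns whole
  # numbers into integers, so coerce them back before comparing bit-for-bit
  dedouble <- function(v) {
    if (is.list(v)) lapply(v, dedouble)
    else if (is.integer(v)) as.double(v)
    else v
  }
  x <- dedouble(x)
  rebuild <- function(tab) {
    age_band_table(tab$lower, tab$value, tab$kind)
  }
  for (blk in c("incidence", "osteo_rr")) {
    x[[blk]] <- lapply(x[[blk]], rebuild)
  }
  x$utilities$baseline <- rebuild(x$utilities$baseline)
  x$mortality$baseline <- rebuild(x$mortality$baseline)
  for (nm in names(x$treatments)) {
    x$treatments[[nm]]$rr <- unlist(x$treatments[[nm]]$rr)
  }
  x$costs$fracture <- unlist(x$costs$fracture)
  x$distributions <- as.data.frame(x$distributions, stringsAsFactors = FALSE)
  class(x) <- "osteo_params"
  x
}
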