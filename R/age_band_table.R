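#' Age-band lookup tables
#'
#' Several model inputs (fracture incidence, osteoporosis relative risks,
#' baseline utilities, background mortality) are published as values per age
#' band rather than per single year of age. An `age_band_table` stores the
#' ascending lower edges of contiguous bands together with one value per
#' band; the last band is open-ended ("85+"). Lookup resolves an individual's
#' integer age at cycle start to the band containing it, with bands read as
#' half-open intervals `[lower, next lower)`.
#'
#' @param lower integer vector of ascending band lower edges (years).
#' @param value numeric vector, one value per band.
#' @param kind one of `"rate"` (non-negative), `"probability"` or
#'   `"utility"` (both restricted to `[0, 1]`); used by
#'   [validate_parameters()].
#' @return An object of class `age_band_table`.
#' @examples
#' mort <- age_band_table(c(65, 70, 75, 80, 85),
#'                        c(0.01031, 0.02036, 0.03784, 0.06998, 0.13603),
#'                        kind = "probability")
#' band_value(mort, 82)
#' @export
age_band_table <- function(lower, value, kind = c("rate", "probability", "utility")) {
  kind <- match.arg(kind)
  if (length(lower) != length(value)) {
    stop("'lower' and 'value' must have the same length")
  }
  if (is.unsorted(lower, strictly = TRUE)) {
    stop("band lower edges must be strictly ascending")
  }
  structure(list(lower = as.numeric(lower), value = as.numeric(value), kind = kind),
            class = "age_band_table")
}

#' Look up the band value for an age
#'
#' @param tab an [age_band_table()].
#' @param age numeric age(s) in years; must be at or above the first band edge.
#' @return The band value(s) at `age`.
#' @export
band_value <- function(tab, age) {
  stopifnot(inherits(tab, "age_band_table"))
  i <- findInterval(age, tab$lower)
  if (any(i == 0L)) {
    stop(sprintf("age %s below the first band edge (%s)",
                 min(age), tab$lower[1L]))
  }
  tab$value[i]
}

#' @export
print.age_band_table <- function(x, ...) {
  hi <- c(x$lower[-1L] - 1, Inf)
  lab <- ifelse(is.finite(hi), sprintf("%g-%g", x$lower, hi), sprintf("%g+", x$lower))
  cat(sprintf("Age-band table (%s):\n", x$kind))
  print(stats::setNames(x$value, lab))
  invisible(x)
}

# internal: invariant check used by validate_parameters; returns character()
# when clean, otherwise messages prefixed with `name`.
check_age_band_table <- function(tab, name) {
  out <- character()
  if (!inherits(tab, "age_band_table")) {
    return(sprintf("%s: not an age_band_table", name))
  }
  if (is.unsorted(tab$lower, strictly = TRUE)) {
    out <- c(out, sprintf("%s: band edges not strictly ascending", name))
  }
  if (!all(is.finite(tab$value))) {
    out <- c(out, sprintf("%s: non-finite values", name))
  }
  bad <- switch(tab$kind,
    rate        = any(tab$value < 0, na.rm = TRUE),
    probability = any(tab$value < 0 | tab$value > 1, na.rm = TRUE),
    utility     = any(tab$value < 0 | tab$value > 1, na.rm = TRUE)
  )
  if (isTRUE(bad)) {
    out <- c(out, sprintf("%s: values outside the legal range for kind '%s'",
                          name, tab$kind))
  }
  out
}
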