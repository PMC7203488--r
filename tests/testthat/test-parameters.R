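test_that("age-band tables resolve integer ages with half-open bands", {
  tab <- age_band_table(c(65, 70, 80), c(1, 2, 3), "rate")
  expect_equal(band_value(tab, 65), 1)
  expect_equal(band_value(tab, 69), 1)
  expect_equal(band_value(tab, 70), 2)
  expect_equal(band_value(tab, 79), 2)
  expect_equal(band_value(tab, 104), 3)
  expect_error(band_value(tab, 64), "below the first band")
  expect_error(age_band_table(c(70, 65), c(1, 2)), "ascending")
})

test_that("the base case carries the published values", {
  p <- base_case_parameters()
  expect_equal(p$treatments$zoledronic$rr[["hip"]], 0.50)
  expect_equal(p$treatments$alendronate$rr[["hip"]], 0.45)
  expect_equal(p$wtp, 29340)
  expect_equal(band_value(p$mortality$baseline, 90), 0.13603)
  expect_equal(band_value(p$utilities$baseline, 72), 0.747)
  expect_equal(band_value(p$incidence$hip, 67), 0.96)
  expect_equal(band_value(p$osteo_rr$hip, 67), 3.91)
  expect_equal(band_value(p$osteo_rr$vertebral, 75), 2.15)
  expect_equal(p$treatments$alendronate$annual_cost, 761.64)
  expect_equal(p$costs$fracture[["hip"]], 7103.25)
  expect_equal(p$mortality$attributable_fraction, 0.25)
  expect_equal(p$discount$cost, 0.03)
  expect_length(validate_parameters(p), 0)
})

test_that("every published input maps to exactly one parameter field", {
  p <- base_case_parameters()
  cen <- parameter_census(p)
  expect_false(any(duplicated(cen$field)))
  # 76 published table rows plus the analysis extras the parameter set owns:
  # zoledronic compliance and year-1 persistence (the infusion defines
  # strategy entry), the two treatment durations, and the WTP threshold
  extras <- c("treatments/zoledronic/compliance",
              "treatments/zoledronic/persistence/year1",
              "treatments/alendronate/duration",
              "treatments/zoledronic/duration", "wtp")
  expect_true(all(extras %in% cen$field))
  expect_equal(nrow(cen), 76 + length(extras))
  # each distribution-registry path resolves to its central value
  d <- p$distributions
  got <- vapply(d$path, function(pt) osteosim:::param_get(p, pt), numeric(1))
  expect_equal(unname(got), d$central)
})

test_that("validation reports violations naming the offending field", {
  p <- base_case_parameters()
  p$treatments$alendronate$rr[["hip"]] <- -0.1
  v <- validate_parameters(p)
  expect_length(v, 1)
  expect_match(v, "treatments/alendronate/rr/hip")

  p2 <- base_case_parameters()
  i <- which(p2$distributions$id == "zol_annual_cost")
  p2$distributions$lower[i] <- p2$distributions$central[i] + 1
  v2 <- validate_parameters(p2)
  expect_length(v2, 1)
  expect_match(v2, "zol_annual_cost")

  p3 <- base_case_parameters()
  p3$discount$cost <- 0.08
  expect_match(validate_parameters(p3), "discount/cost")
})

test_that("one-way bounds move exactly one parameter (or one banded group)", {
  p <- base_case_parameters()
  up <- apply_one_way_bound(p, "zol_annual_cost", "upper")
  expect_equal(up$treatments$zoledronic$annual_cost, 1064.05)
  lo <- apply_one_way_bound(p, "discount_cost", "lower")
  expect_equal(lo$discount$cost, 0)

  # lower then upper from base: the two sets differ in exactly one field
  lo2 <- apply_one_way_bound(p, "aln_rr_hip", "lower")
  up2 <- apply_one_way_bound(p, "aln_rr_hip", "upper")
  a <- parameter_census(lo2); b <- parameter_census(up2)
  expect_equal(sum(a$value != b$value), 1)
  expect_equal(a$field[a$value != b$value], "treatments/alendronate/rr/hip")

  grp <- apply_one_way_bound(p, "osteo_rr_hip", "lower")
  expect_equal(grp$osteo_rr$hip$value, c(3.28, 2.80, 2.39, 1.91, 1.78))

  expect_error(apply_one_way_bound(p, "no_such_parameter", "upper"), "unknown")
  p$distributions$lower[1] <- NA
  p$distributions$upper[1] <- NA
  expect_error(apply_one_way_bound(p, p$distributions$id[1], "upper"),
               "no published range")
})

test_that("configuration files round-trip bit-exactly", {
  p <- base_case_parameters()
  f <- tempfile(fileext = ".json")
  write_parameters(p, f)
  p2 <- read_parameters(f)
  expect_identical(parameter_census(p)$value, parameter_census(p2)$value)
  expect_identical(parameter_census(p)$field, parameter_census(p2)$field)
  expect_equal(unclass(p), unclass(p2))

  set.seed(31)
  ps <- synthetic_parameter_set()
  fs <- tempfile(fileext = ".json")
  write_parameters(ps, fs)
  ps2 <- read_parameters(fs)
  expect_identical(parameter_census(ps)$value, parameter_census(ps2)$value)
})

test_that("the synthetic generator satisfies every invariant by construction", {
  for (seed in 1:10) {
    set.seed(seed)
    p <- synthetic_parameter_set(n_bands = sample(2:6, 1),
                                 incidence_scale = runif(1, 0, 2),
                                 effect_gap = runif(1, 0, 0.5))
    expect_length(validate_parameters(p), 0)
  }
  set.seed(3)
  ident <- synthetic_parameter_set(identical_strategies = TRUE)
  t1 <- ident$treatments$alendronate
  t2 <- ident$treatments$zoledronic
  for (fld in c("rr", "persistence", "compliance", "duration", "annual_cost")) {
    expect_identical(t1[[fld]], t2[[fld]])
  }
  set.seed(4)
  zero <- synthetic_parameter_set(incidence_scale = 0)
  expect_true(all(vapply(zero$incidence, function(t) all(t$value == 0), TRUE)))
})
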