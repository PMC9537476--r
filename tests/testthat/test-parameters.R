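test_that("embedded base case carries the published inputs", {
  p <- bm_parameters()
  expect_equal(c(p$treatments$hifu$p_complete, p$treatments$hifu$p_partial,
                 p$treatments$hifu$p_none), c(0.230, 0.410, 0.350))
  expect_equal(p$treatments$hifu$onset_days, 7L)
  expect_equal(p$treatments$mf_ebrt$p_retreat_monthly, 0.007)
  expect_equal(p$treatments$sf_ebrt$p_retreat_monthly, 0.018)
  expect_equal(p$p_no_response_retreat, 0.420)
  expect_equal(p$mortality$lung$monthly_p_by_year,
               c(0.070, 0.050, 0.050, 0.030, 0.020))
  expect_equal(p$mortality$breast$extrapolation_p, 0.027)
  expect_equal(p$utilities$u_base, 0.039)
  expect_equal(p$costs$c_fracture_total, 21430)
  expect_equal(sum(p$costs$fracture_components), 21430)
  expect_equal(p$costs$c_opioid_monthly, 210)
  expect_equal(unname(p$cancer_mix), rep(1 / 3, 3))
  expect_equal(nrow(validate_parameters(p)), 0L)
})

test_that("every varied parameter has an SD and a distribution family", {
  p <- bm_parameters()
  nms <- parameter_names(p)
  expect_true(length(nms) >= 30)
  for (nm in nms) {
    expect_true(is.numeric(param_get(p, nm)), info = nm)
    expect_true(param_family(nm) %in%
                  c("beta", "gamma", "dirichlet", "tnorm_pos", "tnorm_neg"),
                info = nm)
  }
})

test_that("annual/monthly probability conversion matches compounding", {
  # independent closed form: 1 - exp(log(1 - p) / 12)
  for (pa in c(0, 0.08, 0.20, 0.32, 0.5, 0.9)) {
    expect_equal(annual_to_monthly(pa), 1 - exp(log(1 - pa) / 12), tolerance = 1e-12)
  }
  # the published monthly retreat rates are compounded annual 20% and 8%
  expect_lt(abs(annual_to_monthly(0.20) - 0.01843), 1e-5)
  expect_lt(abs(annual_to_monthly(0.08) - 0.00692), 1e-5)
  # bijection on [0, 1)
  grid <- seq(0, 0.99, by = 0.07)
  expect_equal(monthly_to_annual(annual_to_monthly(grid)), grid, tolerance = 1e-12)
  expect_error(annual_to_monthly(1), "0, 1")
  expect_error(monthly_to_annual(-0.1), "0, 1")
})

test_that("validation flags broken invariants without raising", {
  p <- bm_parameters()
  d <- validate_parameters(param_set(p, "costs.c_opioid_monthly", -5))
  expect_equal(nrow(d), 1L)
  expect_match(d$field, "costs")

  d <- validate_parameters(param_set(p, "cancer_mix",
                                     c(breast = 0.5, prostate = 0.5, lung = 0.5)))
  expect_true(any(grepl("cancer_mix", d$field)))

  bad <- p
  bad$treatments$mf_ebrt$p_complete <- 0.6  # triplet now sums to 1.36
  d <- validate_parameters(bad)
  expect_true(any(grepl("treatments.mf_ebrt", d$field)))

  # published single-fraction-only scenario input remains valid
  expect_equal(nrow(validate_parameters(param_set(p, "strategy.share_sf_ebrt", 1.0))), 0L)

  # mortality-vs-source survival inconsistency surfaces as a note, not an error
  notes <- validate_parameters(p, include_notes = TRUE)
  expect_true(any(notes$severity == "note"))
  expect_false(any(notes$severity == "error"))
})

test_that("config files round-trip losslessly and reject unknown keys", {
  p <- bm_parameters("treatments.hifu.p_retreat_monthly" = 1 / 3,
                     "costs.c_hifu_inpatient" = 5147.25)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, path)
  q <- read_parameters(path)
  fp <- flatten_parameters(p)
  fq <- flatten_parameters(q)
  expect_identical(names(fp), names(fq))
  for (nm in names(fp)) expect_equal(fq[[nm]], fp[[nm]], tolerance = 1e-15, info = nm)

  writeLines(c(readLines(path), "not_a_real_key: 1"), path)
  expect_error(read_parameters(path), "unknown configuration keys")

  writeLines(readLines(path)[-(1:2)][-1], path)  # drop fields
  expect_error(read_parameters(path))
})

test_that("a config with an off-simplex response triplet is rejected by name", {
  p <- bm_parameters()
  p$treatments$sf_ebrt$p_complete <- 0.43  # sum 1.2
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, path)
  expect_error(read_parameters(path), "sf_ebrt")
})

test_that("flat accessors address every leaf", {
  p <- bm_parameters()
  expect_equal(param_get(p, "utilities.gain_partial"), 0.008)
  p2 <- param_set(p, "utilities.gain_partial", 0.011)
  expect_equal(param_get(p2, "utilities.gain_partial"), 0.011)
  expect_equal(param_get(p, "utilities.gain_partial"), 0.008)  # no aliasing
  expect_error(param_get(p, "no.such.leaf"), "unknown parameter")
  expect_error(param_set(p, "costs.nope", 1), "unknown parameter")

  tab <- parameter_table(p)
  expect_true(all(c("name", "value", "sd", "family") %in% names(tab)))
  expect_true(any(tab$family == "dirichlet", na.rm = TRUE))
  expect_equal(tab$value[tab$name == "costs.c_sf_ebrt"], 1486)
})
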