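test_that("discounting follows the annual rate on monthly cycles", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0.03, 12), 1 / 1.03)
  expect_equal(discount_factor(0, 240), 1)
  expect_equal(discount_factor(0.03, 6), 1.03^-0.5)
  expect_error(discount_factor(-0.01, 1), ">= 0")
})

test_that("entry response distributions come from the first-line profiles", {
  p <- bm_parameters()
  wB <- initial_response_distribution("B", "mf_ebrt", p)
  expect_equal(unname(wB[1:3]), c(0.24, 0.38, 0.38))
  expect_equal(attr(wB, "onset_fraction"), 0)
  wA <- initial_response_distribution("A", "hifu", p)
  expect_equal(unname(wA[1:3]), c(0.23, 0.41, 0.35))
  expect_equal(attr(wA, "onset_fraction"), 23 / 30)
  expect_error(initial_response_distribution("B", "hifu", p), "no first-line")
  expect_error(initial_response_distribution("A", "surgery", p), "unknown modality")

  pd <- bm_parameters()
  pd$treatments$mf_ebrt[c("p_complete", "p_partial", "p_none")] <- list(1, 0, 0)
  expect_equal(unname(initial_response_distribution("B", "mf_ebrt", pd)[1:3]),
               c(1, 0, 0))
})

test_that("retreatment response splits the re-irradiation remainder in the first-line ratio", {
  p <- bm_parameters()
  expect_equal(unname(retreat_response_distribution("A", "hifu", p)[1:3]),
               c(0.23, 0.41, 0.35))
  wB <- retreat_response_distribution("B", "mf_ebrt", p)
  expect_equal(unname(wB[1:3]),
               c(0.58 * 0.24 / 0.62, 0.58 * 0.38 / 0.62, 0.42), tolerance = 1e-12)
  expect_equal(unname(wB[1:3]), c(0.2245, 0.3555, 0.42), tolerance = 1e-3)
  p1 <- param_set(p, "p_no_response_retreat", 1)
  expect_equal(unname(retreat_response_distribution("B", "sf_ebrt", p1)[1:3]),
               c(0, 0, 1))
})

test_that("the one-cycle kernel conserves probability mass for arbitrary valid parameters", {
  for (seed in 1:10) {
    p <- perturb_parameters(seed = seed, jitter = 1)
    for (strat in c("A", "B")) {
      kern <- cohort_kernel(p, strat)
      expect_lt(max(abs(rowSums(kern$K) - 1)), 1e-9)
      # iterated occupancy keeps total mass
      occ <- kern$w0 / sum(kern$w0)
      for (i in 1:30) occ <- cycle_update(occ, kern)$occupancy
      expect_equal(sum(occ), 1, tolerance = 1e-9)
      expect_true(all(occ > -1e-12))
    }
  }
})

test_that("an extinct cohort accrues nothing and pain relapse moves the stated mass", {
  p <- bm_parameters()
  kern <- cohort_kernel(p, "B")
  res <- cycle_update(numeric(36), kern)
  expect_equal(res$cost, 0)
  expect_equal(res$qaly, 0)
  expect_equal(res$pain_months, 0)

  # 100% complete responders, direct-to-persistent relapse, no other events
  p2 <- reduced_params(p_relapse = 0.022)
  kern2 <- cohort_kernel(p2, "B")
  occ <- numeric(36)
  occ[which(kern2$state$firstline == "mf_ebrt" & kern2$state$pain == "complete" &
              !kern2$state$retreat_used & !kern2$state$fracture)] <- 1
  new <- cycle_update(occ, kern2)$occupancy
  pers <- sum(new[kern2$state$pain == "persistent"])
  expect_equal(pers, 0.022, tolerance = 1e-12)
})

test_that("single-strategy accruals match a hand computation in a reduced model", {
  # (near-)immortal cohort, no relapse/retreat/fracture, no discounting,
  # 12 cycles, strategy B
  p <- reduced_params(p_death = 1e-12, horizon = 12L)
  a <- expected_outcomes("B", p)
  resp <- 0.9 * 0.62 + 0.1 * 0.61          # responders by EBRT mix
  comp <- 0.9 * 0.24 + 0.1 * 0.23          # complete responders
  entry_cost <- 0.9 * (0.7 * 2411 + 0.3 * 6410) + 0.1 * 1486
  entry_du <- 0.9 * -0.009 + 0.1 * -0.004
  # EBRT onset: no response accrual in the entry cycle, full afterwards
  expect_equal(a$mean_pain_months, resp * 11, tolerance = 1e-6)
  expect_equal(a$mean_cost, entry_cost + 210 * (12 - comp * 11), tolerance = 1e-4)
  # pooled valuation: responder months carry the complete-relief gain
  expect_equal(a$mean_qaly, 12 * 0.039 + resp * 11 * 0.019 + entry_du,
               tolerance = 1e-6)
})

test_that("undiscounted responder months match brute-force enumeration under constant hazards", {
  p_d <- 0.04; p_r <- 0.05
  p <- reduced_params(p_death = p_d, p_relapse = p_r, horizon = 600L)
  a <- expected_outcomes("B", p)
  # independent oracle: month-by-month survival x response retention sum,
  # death applied at the start of each cycle including entry
  resp <- 0.9 * 0.62 + 0.1 * 0.61
  brute <- 0
  for (t in 1:599) brute <- brute + (1 - p_d)^(t + 1) * (1 - p_r)^t
  expect_equal(a$mean_pain_months_undisc, resp * brute, tolerance = 1e-9)
})

test_that("strategy A with no first-line HIFU and no retreatment reproduces strategy B", {
  p <- bm_parameters("strategy.share_hifu_firstline_A" = 0)
  for (tr in names(p$treatments)) p$treatments[[tr]]$p_retreat_monthly <- 0
  armA <- expected_outcomes("A", p)
  armB <- expected_outcomes("B", p)
  expect_equal(arm_vec(armA), arm_vec(armB), tolerance = 1e-12)
})

test_that("outcomes respond monotonically to cost and utility inputs", {
  p <- bm_parameters()
  base <- list(A = expected_outcomes("A", p), B = expected_outcomes("B", p))
  for (nm in c("costs.c_opioid_monthly", "costs.c_hifu_inpatient",
               "costs.c_fracture_total", "costs.c_sf_ebrt")) {
    p2 <- param_set(p, nm, param_get(p, nm) * 1.5)
    if (nm == "costs.c_fracture_total")
      p2$costs$fracture_components <- p$costs$fracture_components * 1.5
    for (s in c("A", "B"))
      expect_gte(expected_outcomes(s, p2)$mean_cost, base[[s]]$mean_cost)
  }
  p3 <- param_set(p, "utilities.gain_complete", 0.03)
  for (s in c("A", "B"))
    expect_gt(expected_outcomes(s, p3)$mean_qaly, base[[s]]$mean_qaly)
})

test_that("the horizon warning fires only for lifetime horizons with survivors", {
  p <- bm_parameters()
  expect_silent(expected_outcomes("B", p))
  p$horizon_months <- 240L
  expect_warning(expected_outcomes("B", p), "still alive")
})
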