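stub_arm <- function(cost, qaly, pain = qaly * 40, strategy = "A") {
  structure(list(mean_cost = cost, mean_qaly = qaly, mean_pain_months = pain,
                 se_cost = 0, se_qaly = 0, se_pain = 0, n = 1L,
                 engine = "stub", strategy = strategy), class = "bm_arm")
}

test_that("ICER and dominance classification is correct on every sign quadrant", {
  # brute-force enumeration of sign patterns against first principles
  for (dc in c(-250, 0, 250)) for (de in c(-0.01, 0, 0.01)) {
    inc <- incremental_analysis(stub_arm(1000 + dc, 0.5 + de),
                                stub_arm(1000, 0.5, strategy = "B"))
    if (de == 0) {
      expect_equal(inc$label_qaly, "undefined")
      expect_true(is.na(inc$icer_qaly))
    } else if (dc >= 0 && de > 0) {
      expect_equal(inc$label_qaly, "ratio")
      expect_equal(inc$icer_qaly, dc / de)
    } else if (dc < 0 && de > 0) {
      expect_equal(inc$label_qaly, "dominant")
    } else if (dc > 0 && de < 0) {
      expect_equal(inc$label_qaly, "dominated")
    } else {
      expect_equal(inc$label_qaly, "ratio")  # SW: less costly, less effective
      expect_equal(inc$icer_qaly, dc / de)
    }
  }
})

test_that("net monetary benefit orders strategies exactly at the ICER threshold", {
  armB <- stub_arm(8000, 0.94, strategy = "B")
  expect_equal(nmb(armB, 0), -8000)
  set.seed(1)
  for (i in 1:25) {
    dc <- runif(1, 50, 900); de <- runif(1, 0.005, 0.05)
    armA <- stub_arm(8000 + dc, 0.94 + de)
    icer <- incremental_analysis(armA, armB)$icer_qaly
    for (wtp in c(icer * 0.8, icer * 1.25))
      expect_equal(nmb(armA, wtp) > nmb(armB, wtp), wtp > icer)
  }
  expect_error(nmb(armB, -1), ">= 0")
})

test_that("deltas and ICERs come from unrounded means", {
  armB <- stub_arm(8115.4, 0.94031, 9.4071, strategy = "B")
  armA <- stub_arm(8514.6, 0.96042, 10.3548)
  inc <- incremental_analysis(armA, armB)
  expect_equal(inc$delta_cost, 399.2, tolerance = 1e-12)
  expect_equal(inc$icer_qaly, 399.2 / 0.02011, tolerance = 1e-9)
  expect_equal(inc$icer_pain, 399.2 / 0.9477, tolerance = 1e-9)
})

test_that("base-case arm means equal the cancer-mix average of the subgroup means", {
  p <- bm_parameters()
  base <- bm_cea(p)
  subs <- lapply(names(p$mortality), function(cc) subgroup_cea(cc, p))
  for (arm in c("arm_A", "arm_B")) {
    mixed <- Reduce(`+`, Map(function(s, w) arm_vec(s[[arm]]) * w,
                             subs, p$cancer_mix))
    expect_equal(mixed, arm_vec(base[[arm]]), tolerance = 1e-9)
  }
  # degenerate subgroup mix identical to setting the mix directly
  fit2 <- bm_cea(param_set(p, "cancer_mix",
                           c(breast = 1, prostate = 0, lung = 0)))
  expect_equal(arm_vec(subgroup_cea("breast", p)$arm_A), arm_vec(fit2$arm_A))
})

test_that("the report table carries both strategies for every cohort", {
  rep <- cea_report()
  expect_equal(nrow(rep), 8L)
  expect_setequal(unique(rep$cohort), c("base case", "breast", "prostate", "lung"))
  expect_true(all(is.finite(rep$mean_cost)))
  base_icer <- rep$icer_qaly[rep$cohort == "base case" & rep$strategy == "A"]
  fit <- bm_cea()
  expect_equal(base_icer, fit$incremental$icer_qaly)
})

test_that("results export with provenance and the shipped config loads", {
  fit <- bm_cea()
  jpath <- withr::local_tempfile(fileext = ".json")
  export_results(fit$arm_A, jpath)
  out <- jsonlite::read_json(jpath)
  expect_equal(out$results[[1]]$mean_cost, fit$arm_A$mean_cost, tolerance = 1e-9)
  expect_match(out$provenance$parameter_hash, "^[0-9a-f]{8}$")

  cfg <- system.file("extdata", "basecase.yaml", package = "hifucea")
  expect_true(nzchar(cfg))
  expect_equal(flatten_parameters(read_parameters(cfg)),
               flatten_parameters(bm_parameters()))

  # plot methods run headless
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  psa <- run_psa(bm_parameters(), 40, seed = 2)
  plot(psa, type = "plane")
  plot(psa, type = "ceac", wtp_grid = c(0, 20000, 40000))
  plot(one_way_dsa(bm_parameters(), n_sd = 0), n_top = 5)
  expect_true(TRUE)
})
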