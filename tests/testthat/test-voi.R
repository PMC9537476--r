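# independent oracle: EVPI of a Normal(m, sigma) incremental net benefit by
# numerical quadrature, E[max(0, X)] - max(0, E[X])
evpi_quadrature <- function(m, sigma) {
  f <- function(x) pmax(0, x) * stats::dnorm(x, m, sigma)
  stats::integrate(f, m - 10 * sigma, m + 10 * sigma, rel.tol = 1e-10)$value -
    max(0, m)
}

boot_se <- function(stat, data_n, B = 200, seed = 1) {
  set.seed(seed)
  sd(vapply(seq_len(B), function(b) stat(sample.int(data_n, replace = TRUE)),
            numeric(1)))
}

test_that("the EVPI estimator matches the Gaussian closed form on an (m, sigma) grid", {
  grid <- list(c(0, 1000), c(500, 1000), c(-500, 1000), c(2000, 500), c(-100, 300))
  for (g in grid) {
    truth <- evpi_quadrature(g[1], g[2])
    expect_equal(gaussian_evpi_truth(g[1], g[2]), truth, tolerance = 1e-6)
    tab <- sim_gaussian_nb(g[1], g[2], n_iter = 6000, seed = round(g[1] + g[2]))
    expect_equal(attr(tab, "ground_truth")$evpi, truth, tolerance = 1e-6)
    est <- evpi(tab, wtp = 20000)
    se <- boot_se(function(idx) evpi(tab[idx, ], wtp = 20000), nrow(tab))
    # 0.05 EUR floor absorbs quadrature truncation when the decision is
    # nearly certain and the bootstrap SE collapses
    expect_lt(abs(est - truth), 3 * se + 0.05)
  }
  # symmetry of the positive-part formula
  expect_equal(gaussian_evpi_truth(-500, 1000), gaussian_evpi_truth(500, 1000),
               tolerance = 1e-12)
})

test_that("EVPI is zero when the decision is certain and errors on tiny tables", {
  sure <- data.frame(cost_A = rep(0, 100), qaly_A = 0.5,
                     cost_B = 0, qaly_B = 0.1)
  expect_equal(evpi(sure, 20000), 0)
  tab <- sim_gaussian_nb(1e6, 1, n_iter = 500, seed = 1)
  expect_lt(evpi(tab, 20000), 1e-6)
  expect_error(evpi(sure[1, , drop = FALSE], 20000), "at least 2")
})

test_that("the EVPI-by-WTP curve is emitted and non-negative", {
  tab <- sim_gaussian_nb(300, 900, n_iter = 1000, seed = 3)
  cv <- evpi_curve(tab, c(0, 20000, 60000))
  expect_equal(nrow(cv), 3L)
  expect_true(all(cv$evpi >= 0))
})

test_that("regression EVPPI recovers the constructed ground truth on linear fixtures", {
  w <- c(300, 400)
  tab <- sim_linear_nb(w, noise_sd = 120, n_iter = 3000, seed = 11)
  gt <- attr(tab, "ground_truth")

  e1 <- evppi(tab, "theta1", wtp = 20000, n_boot = 20)
  expect_lt(abs(e1["evppi"] - gt$evppi("theta1")),
            0.1 * gt$evppi("theta1") + 3 * e1["se"])

  e2 <- evppi(tab, "theta2", wtp = 20000, n_boot = 20)
  expect_lt(abs(e2["evppi"] - gt$evppi("theta2")),
            0.1 * gt$evppi("theta2") + 3 * e2["se"])

  # the full set approaches the EVPI from below
  eb <- evppi(tab, c("theta1", "theta2"), wtp = 20000, n_boot = 10)
  ev <- evpi(tab, 20000)
  expect_lt(abs(eb["evppi"] - gt$evppi(c("theta1", "theta2"))), 0.12 * ev)
  expect_lte(eb[["evppi"]], ev + 2 * eb[["se"]] + 0.02 * ev)
})

test_that("EVPPI of a pure-noise parameter is near zero and monotone in the subset", {
  tab <- sim_linear_nb(c(500, 0, 250), noise_sd = 0, n_iter = 2500, seed = 13)
  ev <- evpi(tab, 20000)
  enoise <- evppi(tab, "theta2", wtp = 20000, n_boot = 0)
  expect_lt(enoise[["evppi"]], 0.06 * ev)

  e1 <- evppi(tab, "theta1", wtp = 20000, n_boot = 10)
  e13 <- evppi(tab, c("theta1", "theta3"), wtp = 20000, n_boot = 10)
  expect_lte(e1[["evppi"]], e13[["evppi"]] + 2 * (e1[["se"]] + e13[["se"]]) + 0.02 * ev)
  # with no residual noise the full set recovers the EVPI
  expect_equal(e13[["evppi"]], ev, tolerance = 0.05)

  expect_error(evppi(tab, character(0), 20000), "empty")
  expect_error(evppi(tab, "not_a_column", 20000), "not in PSA table")
})

test_that("population EVPI is the discounted sum of affected cohorts", {
  expect_equal(population_evpi(434, rep(0, 5)), 0)
  expect_equal(population_evpi(434, 1e5, discount_annual = 0), 43.4e6)
  counts <- c(82020, 82020, 82020, 82020, 82020)
  manual <- 434 * sum(counts / 1.03^(0:4))
  expect_equal(population_evpi(434, counts, 0.03), manual)
  expect_error(population_evpi(434, c(-1, 5)), ">= 0")
})
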