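# Synthetic fixtures: randomized valid parameter sets and PSA tables with
# analytically known value-of-information, used to test every estimator in
# the package without external data.

#' Randomized valid parameter set
#'
#' Draws a perturbed-but-valid parameter set by sampling every varied
#' parameter from its PSA distribution with the standard deviations scaled
#' by `jitter`. With `jitter = 0` the base case is returned unchanged.
#' Used for microsim-vs-cohort oracle-equivalence sweeps.
#'
#' @param params base `bm_parameters`.
#' @param seed RNG seed (fixtures are reproducible from the seed alone).
#' @param jitter scale factor applied to all SDs before drawing.
#' @return A valid `bm_parameters` object.
#' @export
perturb_parameters <- function(params = bm_parameters(), seed = 1L, jitter = 0.5) {
  if (jitter == 0) return(params)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  scaled <- params
  scaled$sd_table <- params$sd_table * jitter
  out <- draw_parameter_set(scaled)
  out$sd_table <- params$sd_table
  out
}

as_synthetic_psa <- function(df, param_cols) {
  attr(df, "param_cols") <- param_cols
  attr(df, "engine") <- "synthetic"
  class(df) <- c("bm_psa", "data.frame")
  df
}

#' Synthetic PSA table with Gaussian incremental net benefit
#'
#' Builds a two-strategy PSA table whose incremental net monetary benefit at
#' any willingness-to-pay is i.i.d. `Normal(m, sigma^2)` (the effect columns
#' are zero and the benefit is carried entirely by `cost_A`). The analytic
#' EVPI, [gaussian_evpi_truth()]`(m, sigma)`, is attached as attribute
#' `ground_truth`.
#'
#' @param m mean incremental net benefit (EUR).
#' @param sigma standard deviation (EUR).
#' @param n_iter number of iterations.
#' @param seed RNG seed.
#' @return A `bm_psa`-compatible data frame with attribute `ground_truth`
#'   (list with `evpi`).
#' @export
sim_gaussian_nb <- function(m, sigma, n_iter = 10000L, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  inb <- stats::rnorm(n_iter, m, sigma)
  df <- data.frame(cost_A = -inb, qaly_A = 0, pain_A = 0,
                   cost_B = 0, qaly_B = 0, pain_B = 0)
  df <- as_synthetic_psa(df, character())
  attr(df, "ground_truth") <- list(evpi = gaussian_evpi_truth(m, sigma))
  df
}

#' Synthetic PSA table with linear-in-parameters net benefit
#'
#' The incremental net benefit is `sum_j w_j theta_j + eps` with
#' `theta_j ~ Normal(0, 1)` i.i.d. and `eps ~ Normal(0, noise_sd^2)`.
#' The EVPPI of any subset `S` then has the Gaussian closed form with
#' `sigma_S^2 = sum_{j in S} w_j^2` and is attached as ground truth, along
#' with the total EVPI (`sigma^2 = sum_j w_j^2 + noise_sd^2`). Used to
#' validate the spline and Gaussian-process EVPPI estimators.
#'
#' @param weights numeric vector of length >= 2: coefficients of the
#'   parameters `theta1, theta2, ...`.
#' @param noise_sd SD of the residual noise (parameter-independent).
#' @inheritParams sim_gaussian_nb
#' @return A `bm_psa`-compatible data frame with parameter columns
#'   `theta1..thetak` and attribute `ground_truth` (list with `evpi` and the
#'   per-subset closed form `evppi(subset)`).
#' @export
sim_linear_nb <- function(weights, noise_sd = 0, n_iter = 10000L, seed = 1L) {
  k <- length(weights)
  if (k < 2) stop("need at least 2 parameters")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  theta <- matrix(stats::rnorm(n_iter * k), n_iter, k,
                  dimnames = list(NULL, paste0("theta", seq_len(k))))
  inb <- as.vector(theta %*% weights) + stats::rnorm(n_iter, 0, noise_sd)
  df <- data.frame(theta, cost_A = -inb, qaly_A = 0, pain_A = 0,
                   cost_B = 0, qaly_B = 0, pain_B = 0)
  df <- as_synthetic_psa(df, paste0("theta", seq_len(k)))
  evppi_truth <- function(subset) {
    j <- match(subset, paste0("theta", seq_len(k)))
    if (anyNA(j)) stop("unknown theta column")
    gaussian_evpi_truth(0, sqrt(sum(weights[j]^2)))
  }
  attr(df, "ground_truth") <- list(
    evpi = gaussian_evpi_truth(0, sqrt(sum(weights^2) + noise_sd^2)),
    evppi = evppi_truth)
  df
}
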