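# Value-of-information estimation from PSA samples.

#' Per-person expected value of perfect information
#'
#' Mean over PSA iterations of the best achievable net monetary benefit
#' minus the net monetary benefit of the strategy that is best on average:
#' `mean_i max_d NMB_{d,i} - max_d mean_i NMB_{d,i}`. Non-negative by
#' construction.
#'
#' @param table a `bm_psa` object (or compatible data frame with columns
#'   `cost_A`, `qaly_A`, `cost_B`, `qaly_B`).
#' @param wtp willingness-to-pay in EUR per QALY.
#' @return Per-person EVPI in EUR.
#' @export
evpi <- function(table, wtp = 20000) {
  if (nrow(table) < 2) stop("need at least 2 PSA iterations")
  nmbA <- wtp * table$qaly_A - table$cost_A
  nmbB <- wtp * table$qaly_B - table$cost_B
  mean(pmax(nmbA, nmbB)) - max(mean(nmbA), mean(nmbB))
}

#' @rdname evpi
#' @param wtp_grid vector of willingness-to-pay values.
#' @return `evpi_curve` returns a data frame with columns `wtp` and `evpi`.
#' @export
evpi_curve <- function(table, wtp_grid = seq(0, 100000, by = 2500)) {
  data.frame(wtp = wtp_grid,
             evpi = vapply(wtp_grid, function(w) evpi(table, w), numeric(1)))
}

#' Closed-form EVPI of a Gaussian incremental net benefit
#'
#' If the incremental net monetary benefit is `Normal(m, sigma^2)`, the
#' per-person EVPI equals `sigma * phi(m/sigma) + m * Phi(m/sigma) - max(0, m)`
#' (the expected positive part minus the positive part of the expectation).
#' Used as the analytic ground truth for the estimator.
#'
#' @param m mean incremental net benefit (EUR).
#' @param sigma standard deviation (EUR), `>= 0`.
#' @return EVPI in EUR.
#' @export
gaussian_evpi_truth <- function(m, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(0)
  z <- m / sigma
  sigma * stats::dnorm(z) + m * stats::pnorm(z) - max(0, m)
}

evppi_fit <- function(table, pars, wtp, method, k = NULL) {
  n <- nrow(table)
  X <- as.data.frame(scale(table[, pars, drop = FALSE]))
  names(X) <- paste0("x", seq_along(pars))
  keep <- vapply(X, function(x) stats::sd(x) > 0 & all(is.finite(x)), logical(1))
  if (!any(keep)) stop("no variation in the requested parameters")
  X <- X[, keep, drop = FALSE]
  if (is.null(k))
    k <- if (length(X) == 1L) min(30L, max(5L, n %/% 20L))
         else min(60L, max(10L, n %/% 25L))
  rhs <- if (method == "spline" && length(X) == 1L) {
    sprintf("s(x1, k = %d)", k)
  } else {
    # isotropic Gaussian-process smooth on standardized inputs
    sprintf("s(%s, bs = \"gp\", k = %d)", paste(names(X), collapse = ", "), k)
  }
  fits <- lapply(c(A = "A", B = "B"), function(d) {
    y <- wtp * table[[paste0("qaly_", d)]] - table[[paste0("cost_", d)]]
    dat <- cbind(y = y, X)
    stats::fitted(mgcv::gam(stats::as.formula(paste("y ~", rhs)), data = dat))
  })
  mean(pmax(fits$A, fits$B)) - max(mean(fits$A), mean(fits$B))
}

#' Regression-based expected value of perfect partial information
#'
#' Estimates the EVPPI of a parameter or parameter set by regressing each
#' strategy's net monetary benefit on the subset with a flexible smoother
#' (penalized spline for a single parameter, an isotropic Gaussian-process
#' smooth on standardized inputs for sets), then applying the EVPI formula
#' to the fitted conditional expectations. The standard error comes from a
#' nonparametric bootstrap over PSA iterations.
#'
#' @inheritParams evpi
#' @param pars character vector of sampled-parameter column names (must have
#'   been varied in the PSA).
#' @param method `"auto"` (spline for one parameter, GP for sets),
#'   `"spline"` or `"gp"`.
#' @param n_boot bootstrap replicates for the SE (0 to skip).
#' @param k basis dimension of the smoother (default scales with n).
#' @return Named numeric vector `c(evppi = ..., se = ...)` in EUR, with the
#'   method used as attribute.
#' @export
evppi <- function(table, pars, wtp = 20000, method = c("auto", "spline", "gp"),
                  n_boot = 30L, k = NULL) {
  method <- match.arg(method)
  if (!length(pars)) stop("parameter subset must not be empty")
  miss <- setdiff(pars, colnames(table))
  if (length(miss)) stop("not in PSA table: ", paste(miss, collapse = ", "))
  const <- vapply(table[, pars, drop = FALSE], function(x) stats::sd(x) == 0,
                  logical(1))
  if (all(const)) {
    out <- c(evppi = 0, se = 0)
    attr(out, "method") <- "constant"
    return(out)
  }
  if (method == "auto") method <- if (length(pars) == 1L) "spline" else "gp"
  est <- evppi_fit(table, pars, wtp, method, k)
  se <- 0
  if (n_boot > 0) {
    bs <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(table), replace = TRUE)
      tryCatch(evppi_fit(table[idx, , drop = FALSE], pars, wtp, method, k),
               error = function(e) NA_real_)
    }, numeric(1))
    se <- stats::sd(bs, na.rm = TRUE)
  }
  out <- c(evppi = est, se = se)
  attr(out, "method") <- method
  out
}

#' Population expected value of perfect information
#'
#' Scales per-person EVPI to the affected population:
#' `evpi_per_person * sum_y counts_y / (1 + r)^y`, with `y = 0` for the
#' first year.
#'
#' @param evpi_per_person per-person EVPI in EUR.
#' @param annual_affected vector of persons affected by the decision per
#'   year (user supplied, e.g. from cancer-registry incidence).
#' @param discount_annual annual discount rate applied to future cohorts.
#' @return Population EVPI in EUR.
#' @export
population_evpi <- function(evpi_per_person, annual_affected,
                            discount_annual = 0.03) {
  if (any(annual_affected < 0)) stop("annual_affected must be >= 0")
  y <- seq_along(annual_affected) - 1
  evpi_per_person * sum(annual_affected / (1 + discount_annual)^y)
}
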