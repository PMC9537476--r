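# Probabilistic sensitivity analysis.
#
# Distribution families (a modelling choice; moment matching to the
# mean/SD table is the contract):
#   * event probabilities and proportions: beta, moment matched;
#   * response triplets: Dirichlet, concentration matched to the SD of the
#     complete-response component;
#   * costs: gamma, moment matched (fracture cost components are scaled
#     with the sampled total so the audit sum stays consistent);
#   * monthly utilities and disutilities: normal truncated to the
#     sign-preserving monthly-scale domain;
#   * cancer-specific mortality is held fixed, mirroring its exclusion from
#     the deterministic sensitivity analysis.

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# mean and sd of a Normal(mu, sig) truncated to [lo, hi]
tnorm_moments <- function(mu, sig, lo, hi) {
  a <- (lo - mu) / sig
  b <- (hi - mu) / sig
  Z <- stats::pnorm(b) - stats::pnorm(a)
  if (Z < 1e-12) return(c(NA_real_, NA_real_))
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sig * (da - db) / Z
  v <- sig^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(m, sqrt(max(v, 0)))
}

.tnorm_cache <- new.env(parent = emptyenv())

# underlying (mu, sig) whose truncation to [lo, hi] reproduces (m, s);
# NULL when the family cannot reach the target moments
tnorm_match <- function(m, s, lo, hi) {
  key <- paste(format(c(m, s, lo, hi), digits = 12), collapse = "|")
  if (!is.null(.tnorm_cache[[key]])) {
    out <- .tnorm_cache[[key]]
    return(if (identical(out, "infeasible")) NULL else out)
  }
  obj <- function(par) {
    mm <- tnorm_moments(par[1], exp(par[2]), lo, hi)
    if (anyNA(mm)) return(1e6)
    ((mm[1] - m) / s)^2 + ((mm[2] - s) / s)^2
  }
  fit <- stats::optim(c(m, log(s)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$value < 1e-6) {
    out <- c(mu = fit$par[1], sig = exp(fit$par[2]))
    .tnorm_cache[[key]] <- out
    out
  } else {
    .tnorm_cache[[key]] <- "infeasible"
    NULL
  }
}

draw_scalar <- function(name, m, s) {
  if (s == 0) return(m)
  fam <- param_family(name)
  dom <- param_domain(name)
  if (fam == "beta") {
    k <- m * (1 - m) / s^2 - 1
    if (k <= 0) {
      warning("SD too large for beta moment match on ", name,
              "; falling back to clipped normal")
      return(min(dom[2], max(dom[1], stats::rnorm(1, m, s))))
    }
    return(stats::rbeta(1, m * k, (1 - m) * k))
  }
  if (fam == "gamma") {
    if (m <= 0) return(m)
    return(stats::rgamma(1, shape = m^2 / s^2, rate = m / s^2))
  }
  # utility increments: sign-preserving, moment-matched to (m, s).
  # A 0-bounded truncated normal cannot reach an SD much above |m|, so the
  # ladder is: truncated normal if feasible, else a scaled beta on the
  # sign-preserving domain (exact moments), else clipped normal (warn once).
  par <- tnorm_match(m, s, dom[1], dom[2])
  if (!is.null(par))
    return(rtrunc_norm(1, par[["mu"]], par[["sig"]], dom[1], dom[2]))
  w <- dom[2] - dom[1]
  m01 <- (m - dom[1]) / w
  s01 <- s / w
  k <- m01 * (1 - m01) / s01^2 - 1
  if (k > 0)
    return(dom[1] + w * stats::rbeta(1, m01 * k, (1 - m01) * k))
  key <- paste0("warned|", name)
  if (is.null(.tnorm_cache[[key]])) {
    .tnorm_cache[[key]] <- TRUE
    warning("SD too large for a sign-preserving moment match on ", name,
            "; falling back to clipped normal")
  }
  min(dom[2], max(dom[1], stats::rnorm(1, m, s)))
}

draw_triplet <- function(tri, sd_complete) {
  tri <- tri / sum(tri)  # printed triplets may be off by rounding
  if (sd_complete == 0) return(tri)
  pc <- tri[1]
  a0 <- pc * (1 - pc) / sd_complete^2 - 1
  if (a0 <= 0) {
    warning("SD too large for Dirichlet moment match; falling back to clipped normal")
    pc2 <- min(1, max(0, stats::rnorm(1, pc, sd_complete)))
    rest <- 1 - pc
    return(c(pc2, tri[2:3] * if (rest > 0) (1 - pc2) / rest else 0.5))
  }
  g <- stats::rgamma(3, shape = a0 * tri, rate = 1)
  g / sum(g)
}

#' Draw one parameter set from the PSA distributions
#'
#' Samples every parameter with a positive SD in `sd_table` from its
#' assigned distribution family (see the family mapping in
#' [parameter_table()]), moment-matched to the stored mean and SD, using the
#' current RNG state. Mortality schedules are never varied. The returned set
#' always satisfies the full parameter validation.
#'
#' @param base a `bm_parameters` object supplying means and SDs.
#' @return A valid `bm_parameters` object.
#' @export
draw_parameter_set <- function(base) {
  p <- base
  for (tr in c("hifu", "mf_ebrt", "sf_ebrt")) {
    t <- base$treatments[[tr]]
    tri <- draw_triplet(c(t$p_complete, t$p_partial, t$p_none),
                        base$sd_table[[paste0("treatments.", tr, ".p_complete")]])
    p$treatments[[tr]]$p_complete <- tri[1]
    p$treatments[[tr]]$p_partial <- tri[2]
    p$treatments[[tr]]$p_none <- tri[3]
  }
  scalars <- setdiff(parameter_names(base),
                     grep("p_(complete|partial|none)$", parameter_names(base),
                          value = TRUE))
  for (nm in scalars) {
    v <- draw_scalar(nm, param_get(base, nm), base$sd_table[[nm]])
    p <- param_set(p, nm, v)
  }
  # keep the fracture component audit consistent with the sampled total
  tot0 <- base$costs$c_fracture_total
  if (tot0 > 0)
    p$costs$fracture_components <- base$costs$fracture_components *
      (p$costs$c_fracture_total / tot0)
  p
}

#' Run a probabilistic sensitivity analysis
#'
#' Draws `n_iter` parameter sets and evaluates both strategies per draw.
#' The default inner evaluator is the deterministic cohort engine, so the
#' only randomness is parameter uncertainty (no inner Monte-Carlo noise).
#'
#' @param params base-case `bm_parameters`.
#' @param n_iter number of PSA iterations (>= 2).
#' @param seed RNG seed; identical seeds reproduce the table exactly.
#' @param engine inner evaluator, `"cohort"` (default) or `"microsim"`.
#' @param n_patients patients per microsim inner evaluation.
#' @return A `bm_psa` object: a data frame with one row per iteration
#'   holding the sampled parameter values (attribute `param_cols`) and the
#'   per-strategy outcomes `cost_A`, `qaly_A`, `pain_A`, `cost_B`,
#'   `qaly_B`, `pain_B`.
#' @export
run_psa <- function(params = bm_parameters(), n_iter = 10000L, seed = 1L,
                    engine = c("cohort", "microsim"), n_patients = 5000L) {
  if (n_iter < 2) stop("n_iter must be >= 2")
  engine <- match.arg(engine)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  pn <- parameter_names(params)
  res <- matrix(NA_real_, n_iter, length(pn) + 6L,
                dimnames = list(NULL, c(pn, "cost_A", "qaly_A", "pain_A",
                                        "cost_B", "qaly_B", "pain_B")))
  for (i in seq_len(n_iter)) {
    ps <- draw_parameter_set(params)
    for (j in seq_along(pn)) res[i, j] <- param_get(ps, pn[j])
    if (engine == "cohort") {
      aA <- expected_outcomes("A", ps)
      aB <- expected_outcomes("B", ps)
    } else {
      aA <- microsim_arm("A", ps, n_patients, seed = seed + i)
      aB <- microsim_arm("B", ps, n_patients, seed = seed + i)
    }
    res[i, length(pn) + 1:6] <- c(aA$mean_cost, aA$mean_qaly, aA$mean_pain_months,
                                  aB$mean_cost, aB$mean_qaly, aB$mean_pain_months)
  }
  out <- as.data.frame(res)
  attr(out, "param_cols") <- pn
  attr(out, "seed") <- seed
  attr(out, "engine") <- engine
  class(out) <- c("bm_psa", "data.frame")
  out
}

psa_inb <- function(table, wtp) {
  wtp * (table$qaly_A - table$qaly_B) - (table$cost_A - table$cost_B)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations in
#' which strategy A has the higher net monetary benefit (ties count 1/2).
#'
#' @param table a `bm_psa` object (or compatible data frame).
#' @param wtp_grid vector of willingness-to-pay values (EUR/QALY).
#' @return Data frame with columns `wtp` and `p_cost_effective`.
#' @export
ceac <- function(table, wtp_grid = seq(0, 100000, by = 2500)) {
  if (!nrow(table)) stop("empty PSA table")
  p <- vapply(wtp_grid, function(w) {
    inb <- psa_inb(table, w)
    mean(inb > 0) + 0.5 * mean(inb == 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, p_cost_effective = p)
}

#' Quadrant shares of the cost-effectiveness plane
#'
#' @param object a `bm_psa` object.
#' @param wtp reference willingness-to-pay for the CEAC/EVPI summary lines.
#' @param ... unused.
#' @return Invisibly, a list with the quadrant fractions (NE: more costly &
#'   more effective, SE: cost saving & more effective, NW, SW), the CEAC
#'   value and per-person EVPI at `wtp`.
#' @export
summary.bm_psa <- function(object, wtp = 20000, ...) {
  dc <- object$cost_A - object$cost_B
  de <- object$qaly_A - object$qaly_B
  quad <- c(NE = mean(dc >= 0 & de > 0), SE = mean(dc < 0 & de > 0),
            NW = mean(dc >= 0 & de <= 0), SW = mean(dc < 0 & de <= 0))
  pce <- ceac(object, wtp)$p_cost_effective
  ev <- evpi(object, wtp)
  cat(sprintf("PSA with %d iterations (%s engine)\n", nrow(object),
              attr(object, "engine")))
  cat(sprintf("  CE-plane quadrants: NE %.1f%%, SE %.1f%%, NW %.1f%%, SW %.1f%%\n",
              100 * quad[1], 100 * quad[2], 100 * quad[3], 100 * quad[4]))
  cat(sprintf("  P(A cost-effective at WTP %.0f): %.1f%%; per-person EVPI: %.0f EUR\n",
              wtp, 100 * pce, ev))
  invisible(list(quadrants = quad, p_ce = pce, evpi = ev, wtp = wtp))
}

#' @export
print.bm_psa <- function(x, ...) {
  cat(sprintf("PSA sample table: %d iterations, %d sampled parameters (%s engine)\n",
              nrow(x), length(attr(x, "param_cols")), attr(x, "engine")))
  invisible(x)
}

#' Plot a PSA: cost-effectiveness plane or acceptability curve
#'
#' @param x a `bm_psa` object.
#' @param type `"plane"` (incremental cost vs incremental QALYs with a 95%
#'   confidence ellipse from a bivariate normal fit) or `"ceac"`.
#' @param wtp_grid grid for the CEAC.
#' @param ... passed to the underlying plot call.
#' @export
plot.bm_psa <- function(x, type = c("plane", "ceac"),
                        wtp_grid = seq(0, 100000, by = 2500), ...) {
  type <- match.arg(type)
  if (type == "plane") {
    de <- x$qaly_A - x$qaly_B
    dc <- x$cost_A - x$cost_B
    graphics::plot(de, dc, pch = 16, cex = 0.3,
                   col = grDevices::adjustcolor("steelblue", 0.4),
                   xlab = "incremental QALYs", ylab = "incremental cost (EUR)",
                   main = "Cost-effectiveness plane", ...)
    graphics::abline(h = 0, v = 0, col = "grey50")
    # 95% ellipse from bivariate normal fit
    S <- stats::cov(cbind(de, dc))
    mu <- c(mean(de), mean(dc))
    th <- seq(0, 2 * pi, length.out = 181)
    circ <- cbind(cos(th), sin(th)) * sqrt(stats::qchisq(0.95, 2))
    ell <- t(mu + t(circ %*% chol(S)))
    graphics::lines(ell, col = "red", lwd = 2)
  } else {
    cv <- ceac(x, wtp_grid)
    graphics::plot(cv$wtp, cv$p_cost_effective, type = "l", lwd = 2,
                   ylim = c(0, 1), xlab = "willingness-to-pay (EUR/QALY)",
                   ylab = "P(strategy A cost-effective)",
                   main = "Cost-effectiveness acceptability curve", ...)
    graphics::abline(h = 0.5, lty = 3)
  }
  invisible(x)
}
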