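# One-way deterministic sensitivity analysis and structural scenarios.

# domain for a flat parameter, used to clip DSA bounds and PSA fallbacks
param_domain <- function(name) {
  fam <- param_family(name)
  switch(fam,
    beta = c(0, 1),
    dirichlet = c(0, 1),
    gamma = c(0, Inf),
    tnorm_pos = c(1e-9, 0.089),
    tnorm_neg = c(-0.089, 0)
  )
}

# set one member of a response triplet, renormalizing the other two so the
# simplex constraint keeps holding
set_triplet_member <- function(p, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  tr <- parts[2]
  field <- parts[3]
  others <- setdiff(c("p_complete", "p_partial", "p_none"), field)
  old <- p$treatments[[tr]][[field]]
  tot <- old + sum(unlist(p$treatments[[tr]][others]))  # printed sums may be 0.99
  value <- min(value, tot)
  rest <- tot - old
  p$treatments[[tr]][[field]] <- value
  if (rest > 0) {
    scale <- (tot - value) / rest
    for (f in others)
      p$treatments[[tr]][[f]] <- p$treatments[[tr]][[f]] * scale
  } else {
    for (f in others) p$treatments[[tr]][[f]] <- (tot - value) / 2
  }
  p
}

set_param_checked <- function(p, name, value) {
  if (param_family(name) == "dirichlet") return(set_triplet_member(p, name, value))
  p2 <- param_set(p, name, value)
  if (name == "costs.c_fracture_total" && p$costs$c_fracture_total > 0)
    p2$costs$fracture_components <- p$costs$fracture_components *
      (value / p$costs$c_fracture_total)
  p2
}

#' One-way deterministic sensitivity analysis
#'
#' Varies every parameter with an entry in the SD table (all model inputs
#' except the cancer-specific mortality schedules) one at a time between
#' mean - 1 SD and mean + 1 SD, clipped to the parameter's valid domain.
#' Response-triplet members are shifted individually with the complement
#' renormalized. The tornado is ranked by the spread of the incremental net
#' monetary benefit at the reference willingness-to-pay; ICERs at both
#' bounds are reported alongside.
#'
#' @param params a `bm_parameters` object.
#' @param wtp reference willingness-to-pay (EUR/QALY) for the INMB outcome.
#' @param n_sd half-width of the variation range in standard deviations.
#' @return A `bm_dsa` data frame (parameter, low/high input values, INMB and
#'   ICER at each bound, spread), sorted by decreasing spread.
#' @export
one_way_dsa <- function(params = bm_parameters(), wtp = 20000, n_sd = 1) {
  base_fit <- bm_cea(params)
  rows <- lapply(parameter_names(params), function(nm) {
    m <- param_get(params, nm)
    s <- params$sd_table[[nm]]
    dom <- param_domain(nm)
    lo <- max(dom[1], m - n_sd * s)
    hi <- min(dom[2], m + n_sd * s)
    outcome <- function(v) {
      if (s == 0) {
        fit <- base_fit
      } else {
        fit <- bm_cea(set_param_checked(params, nm, v))
      }
      inc <- fit$incremental
      c(inmb = wtp * inc$delta_qaly - inc$delta_cost, icer = inc$icer_qaly)
    }
    o_lo <- outcome(lo)
    o_hi <- outcome(hi)
    data.frame(parameter = nm, low = lo, high = hi,
               inmb_low = o_lo[["inmb"]], inmb_high = o_hi[["inmb"]],
               icer_low = o_lo[["icer"]], icer_high = o_hi[["icer"]],
               spread = abs(o_hi[["inmb"]] - o_lo[["inmb"]]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  attr(out, "wtp") <- wtp
  attr(out, "base_inmb") <- wtp * base_fit$incremental$delta_qaly -
    base_fit$incremental$delta_cost
  class(out) <- c("bm_dsa", "data.frame")
  out
}

#' @export
plot.bm_dsa <- function(x, n_top = 12, ...) {
  d <- utils::head(x, n_top)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "base_inmb")
  lo <- pmin(d$inmb_low, d$inmb_high)
  hi <- pmax(d$inmb_low, d$inmb_high)
  op <- graphics::par(mar = c(4, 14, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = range(c(lo, hi, base)), ylim = c(0.5, nrow(d) + 0.5),
                 yaxt = "n", xlab = sprintf("incremental NMB at WTP %.0f (EUR)",
                                            attr(x, "wtp")),
                 ylab = "", main = "One-way sensitivity (tornado)")
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1,
                 cex.axis = 0.7)
  graphics::rect(lo, seq_len(nrow(d)) - 0.35, hi, seq_len(nrow(d)) + 0.35,
                 col = "steelblue", border = NA)
  graphics::abline(v = base, lty = 2)
  invisible(x)
}

.scenario_names <- c("retreat_a_8pct", "retreat_a_32pct", "all_hifu_firstline",
                     "hifu_lumpsum", "all_sf_ebrt", "all_outpatient_ebrt")

scenario_overrides <- function(name, params) {
  switch(name,
    retreat_a_8pct = list("strategy.retreat_rate_A_override" = 0.007),
    retreat_a_32pct = list("strategy.retreat_rate_A_override" = 1 - 0.68^(1 / 12)),
    all_hifu_firstline = list("strategy.share_hifu_firstline_A" = 1.0),
    hifu_lumpsum = list("costs.c_hifu_inpatient" = params$costs$c_hifu_lumpsum),
    all_sf_ebrt = list("strategy.share_sf_ebrt" = 1.0),
    all_outpatient_ebrt = list("strategy.share_ebrt_outpatient" = 1.0),
    stop("unknown scenario: ", name)
  )
}

#' Structural sensitivity scenarios
#'
#' Runs one of the named structural scenarios (alternative strategy-A
#' retreatment rates of 8%/32% per year, MR-HIFU as first-line treatment for
#' everyone, a cost-covering lump sum replacing the DRG reimbursement for
#' MR-HIFU, 100% single-fraction EBRT, 100% out-patient EBRT) or an
#' arbitrary set of sparse overrides.
#'
#' @param scenario a scenario name (see `scenario_names()`) or a named list
#'   of flat-parameter overrides; an empty list reproduces the base case.
#' @inheritParams one_way_dsa
#' @return A `bm_cea` object for the modified parameter set.
#' @export
run_scenario <- function(scenario, params = bm_parameters()) {
  ov <- if (is.character(scenario)) scenario_overrides(scenario, params)
        else scenario
  p <- params
  for (nm in names(ov)) p <- set_param_checked(p, nm, ov[[nm]])
  bm_cea(p)
}

#' @rdname run_scenario
#' @export
scenario_names <- function() .scenario_names

#' @rdname run_scenario
#' @return `scenario_table` returns a data frame with one row per named
#'   scenario (incremental cost, QALYs, ICER).
#' @export
scenario_table <- function(params = bm_parameters()) {
  rows <- lapply(.scenario_names, function(nm) {
    inc <- run_scenario(nm, params)$incremental
    data.frame(scenario = nm, delta_cost = inc$delta_cost,
               delta_qaly = inc$delta_qaly,
               delta_pain_months = inc$delta_pain_months,
               icer_qaly = inc$icer_qaly)
  })
  do.call(rbind, rows)
}
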