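# Incremental cost-effectiveness analysis.

dominance_label <- function(delta_cost, delta_effect, eps = 1e-12) {
  if (abs(delta_effect) < eps) return("undefined")
  if (delta_cost >= 0 && delta_effect > 0) return("ratio")
  if (delta_cost < 0 && delta_effect > 0) return("dominant")
  if (delta_cost > 0 && delta_effect < 0) return("dominated")
  "ratio"  # SW quadrant: less costly, less effective -> ratio is informative
}

icer_value <- function(delta_cost, delta_effect, eps = 1e-12) {
  lab <- dominance_label(delta_cost, delta_effect, eps)
  if (lab == "ratio") delta_cost / delta_effect else NA_real_
}

#' Incremental analysis of two strategy arms
#'
#' Computes incremental discounted cost, QALYs and pain-response months of
#' arm A over arm B, and the two ICERs (EUR/QALY, EUR per pain-response
#' month) from the unrounded deltas. When the cost and effect deltas have
#' opposite signs the ratio is replaced by a dominance label; effect deltas
#' below `eps` yield `"undefined"` rather than an infinite ratio.
#'
#' @param armA,armB `bm_arm` objects (same parameter set, different strategy).
#' @param eps smallest effect delta for which a ratio is reported.
#' @return A `bm_incremental` object with `delta_cost`, `delta_qaly`,
#'   `delta_pain_months`, `icer_qaly`, `icer_pain` and the labels
#'   `label_qaly`, `label_pain` (`"ratio"`, `"dominant"`, `"dominated"` or
#'   `"undefined"`).
#' @export
incremental_analysis <- function(armA, armB, eps = 1e-12) {
  dc <- armA$mean_cost - armB$mean_cost
  dq <- armA$mean_qaly - armB$mean_qaly
  dp <- armA$mean_pain_months - armB$mean_pain_months
  out <- list(
    delta_cost = dc, delta_qaly = dq, delta_pain_months = dp,
    icer_qaly = icer_value(dc, dq, eps), icer_pain = icer_value(dc, dp, eps),
    label_qaly = dominance_label(dc, dq, eps),
    label_pain = dominance_label(dc, dp, eps)
  )
  class(out) <- "bm_incremental"
  out
}

#' @export
print.bm_incremental <- function(x, ...) {
  fmt <- function(v, lab) if (lab == "ratio") sprintf("%.0f", v) else lab
  cat(sprintf("  incremental cost: %8.2f EUR   incremental QALY: %.4f   incremental pain months: %.3f\n",
              x$delta_cost, x$delta_qaly, x$delta_pain_months))
  cat(sprintf("  ICER: %s EUR/QALY; %s EUR per pain-response month\n",
              fmt(x$icer_qaly, x$label_qaly), fmt(x$icer_pain, x$label_pain)))
  invisible(x)
}

#' Net monetary benefit of an arm
#'
#' @param arm a `bm_arm` object.
#' @param wtp willingness-to-pay threshold in EUR per QALY.
#' @return `wtp * mean_qaly - mean_cost` in EUR.
#' @export
nmb <- function(arm, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0")
  wtp * arm$mean_qaly - arm$mean_cost
}

#' Cost-effectiveness comparison of the two treatment strategies
#'
#' The package's main entry point: evaluates strategy A (MR-HIFU as
#' first-line treatment for a share of patients, or as retreatment after
#' EBRT) and strategy B (EBRT with re-irradiation) on one parameter set and
#' returns both arms plus the incremental analysis.
#'
#' @param params a `bm_parameters` object (default: embedded base case).
#' @inheritParams run_strategy
#' @return A `bm_cea` object: `arm_A`, `arm_B` (class `bm_arm`),
#'   `incremental` (class `bm_incremental`), and the call settings.
#' @examples
#' fit <- bm_cea(bm_parameters())
#' fit
#' @export
bm_cea <- function(params = bm_parameters(), engine = c("cohort", "microsim"),
                   n_patients = 200000L, seed = 1L, crn = TRUE) {
  engine <- match.arg(engine)
  armA <- run_strategy("A", params, engine, n_patients, seed, crn)
  armB <- run_strategy("B", params, engine, n_patients, seed, crn)
  out <- list(arm_A = armA, arm_B = armB,
              incremental = incremental_analysis(armA, armB),
              engine = engine, params = params)
  class(out) <- "bm_cea"
  out
}

#' @export
print.bm_cea <- function(x, ...) {
  cat("Cost-effectiveness of MR-HIFU-based strategy (A) vs EBRT alone (B)\n")
  for (arm in list(x$arm_B, x$arm_A))
    cat(sprintf("  strategy %s: cost %8.0f EUR, %6.3f QALY, %6.2f pain-response months\n",
                arm$strategy, arm$mean_cost, arm$mean_qaly, arm$mean_pain_months))
  print(x$incremental)
  invisible(x)
}

#' @export
summary.bm_cea <- function(object, wtp = 20000, ...) {
  inc <- object$incremental
  out <- list(cea = object, wtp = wtp,
              inmb = wtp * inc$delta_qaly - inc$delta_cost)
  class(out) <- "summary.bm_cea"
  out
}

#' @export
print.summary.bm_cea <- function(x, ...) {
  print(x$cea)
  cat(sprintf("  incremental net monetary benefit at WTP %0.f EUR/QALY: %.0f EUR\n",
              x$wtp, x$inmb))
  invisible(x)
}

#' @export
as.data.frame.bm_cea <- function(x, ...) {
  inc <- x$incremental
  rbind(
    cbind(as.data.frame(x$arm_B),
          delta_cost = NA, delta_qaly = NA, delta_pain = NA,
          icer_qaly = NA, icer_pain = NA),
    cbind(as.data.frame(x$arm_A),
          delta_cost = inc$delta_cost, delta_qaly = inc$delta_qaly,
          delta_pain = inc$delta_pain_months,
          icer_qaly = inc$icer_qaly, icer_pain = inc$icer_pain)
  )
}

#' Subgroup analysis by primary cancer
#'
#' Restricts the cohort to a single primary cancer (the cancer mix becomes
#' degenerate) and reruns both strategies.
#'
#' @param cancer `"breast"`, `"prostate"` or `"lung"`.
#' @inheritParams bm_cea
#' @return A `bm_cea` object for the pure subgroup.
#' @export
subgroup_cea <- function(cancer, params = bm_parameters(),
                         engine = c("cohort", "microsim"), ...) {
  cancer <- match.arg(cancer, names(params$mortality))
  mix <- stats::setNames(as.numeric(names(params$cancer_mix) == cancer),
                         names(params$cancer_mix))
  bm_cea(param_set(params, "cancer_mix", mix), engine = engine, ...)
}

#' Base case and subgroup report
#'
#' Runs the mixed base-case cohort and the three pure-cancer subgroups and
#' assembles a table of costs, effects, incremental values and ICERs.
#'
#' @inheritParams bm_cea
#' @return A data frame with one row per strategy per cohort.
#' @export
cea_report <- function(params = bm_parameters(), engine = "cohort", ...) {
  blocks <- c("base case", names(params$mortality))
  rows <- lapply(blocks, function(b) {
    fit <- if (b == "base case") bm_cea(params, engine = engine, ...)
           else subgroup_cea(b, params, engine = engine, ...)
    cbind(cohort = b, as.data.frame(fit))
  })
  do.call(rbind, rows)
}
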