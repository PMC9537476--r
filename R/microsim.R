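# Patient-level Monte-Carlo engine.
#
# Simulates the identical model as the cohort engine, one patient at a time
# (vectorized across patients), with counter-based substreams: the uniforms
# for each (event type, cycle) pair are drawn from a seed derived
# arithmetically from the master seed, for all patient slots at once.
# Consequences, both tested:
#   * patient i's draws do not change when n_patients changes;
#   * with common random numbers (CRN), the same patient index consumes the
#     same uniforms for cancer assignment, death, relapse, retreat uptake and
#     fracture in both strategies, while response-category draws come from a
#     strategy-specific stream.

# event tags for substream derivation
.EV <- c(cancer = 1L, firstline = 2L, death = 3L, relapse = 4L,
         uptake = 5L, fracture = 6L)

substream_seed <- function(master, tag, cycle) {
  x <- (as.double(master) %% 2147483647) * 69621 +
    as.double(tag) * 268435399 + as.double(cycle) * 99824435
  as.integer(x %% 2147483562) + 1L
}

draw_u <- function(master, tag, cycle, n) {
  set.seed(substream_seed(master, tag, cycle))
  stats::runif(n)
}

#' Simulate one strategy arm patient by patient
#'
#' Runs `n_patients` independent patient trajectories through the model
#' under the given strategy, using the same event order and accrual rules as
#' the cohort engine; means converge to [expected_outcomes()] as
#' `n_patients` grows.
#'
#' @inheritParams run_strategy
#' @param params a `bm_parameters` object.
#' @param strategy `"A"` or `"B"`.
#' @param keep_patients if `TRUE`, attach the per-patient accumulator table
#'   as attribute `"patients"` (audit/trajectory export).
#' @return A `bm_arm` object with Monte-Carlo standard errors.
#' @export
microsim_arm <- function(strategy, params, n_patients = 200000L, seed = 1L,
                         crn = TRUE, keep_patients = FALSE) {
  stopifnot_valid(params)
  if (n_patients < 1) stop("n_patients must be >= 1")
  strategy <- match.arg(strategy, c("A", "B"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }

  sp <- strategy_spec(params, strategy)
  n <- as.integer(n_patients)
  H <- params$horizon_months
  u <- params$utilities
  co <- params$costs
  gp <- if (params$response_gain_mode == "pooled") u$gain_complete else u$gain_partial
  r_u <- u$u_base + c(u$gain_complete, gp, 0)
  c_op <- co$c_opioid_monthly
  p_rel <- params$p_relapse_monthly
  cascade <- params$relapse_structure == "cascade"
  pd <- vapply(params$mortality, mortality_by_cycle, numeric(H), n_cycles = H)
  disc <- discount_factor(params$discount_annual, 0:(H - 1))
  mix_cum <- cumsum(params$cancer_mix)
  sh_cum <- cumsum(sp$shares)
  prof_cum <- t(apply(sp$prof, 1, cumsum))
  ret_cum <- t(apply(sp$ret_prof, 1, cumsum))

  # CRN: shared-event streams use the master seed; without CRN they are
  # offset per strategy. Response draws are always strategy-specific.
  soff <- if (crn) 0L else 1000L * (1L + (strategy == "B"))
  rtag <- 50L + (strategy == "B")

  # entry (cycle 0)
  uc <- draw_u(seed, .EV["cancer"] + soff, 0L, n)
  cancer <- 1L + (uc > mix_cum[1]) + (uc > mix_cum[2])
  ufl <- draw_u(seed, .EV["firstline"] + soff, 0L, n)
  fl <- 1L + (ufl > sh_cum[1]) + (ufl > sh_cum[2])
  ur <- draw_u(seed, rtag, 0L, n)
  pain <- 1L + (ur > prof_cum[cbind(fl, 1L)]) + (ur > prof_cum[cbind(fl, 2L)])

  acc_cost <- sp$entry_cost[fl]
  acc_qaly <- acc_pain <- acc_pain_u <- numeric(n)
  alive <- draw_u(seed, .EV["death"] + soff, 0L, n) >= pd[cbind(1L, cancer)]
  fx <- alive & draw_u(seed, .EV["fracture"] + soff, 0L, n) < sp$pfx_first[fl]
  rt <- rep(FALSE, n)

  of <- sp$of[fl]
  a <- alive
  acc_cost[a] <- acc_cost[a] + fx[a] * co$c_fracture_total +
    c_op * (1 - of[a] * (pain[a] == 1L))
  acc_qaly[a] <- acc_qaly[a] + of[a] * r_u[pain[a]] + (1 - of[a]) * r_u[3] +
    sp$entry_du[fl[a]] + fx[a] * u$du_fracture
  p0 <- of[a] * (pain[a] <= 2L)
  acc_pain[a] <- acc_pain[a] + p0
  acc_pain_u[a] <- acc_pain_u[a] + p0

  elig_partial <- vapply(sp$elig_pain, function(e) 2L %in% e, logical(1))
  t <- 1L
  while (any(alive) && t < H) {
    ud <- draw_u(seed, .EV["death"] + soff, t, n)
    alive <- alive & ud >= pd[cbind(t + 1L, cancer)]
    a <- which(alive)
    if (!length(a)) break
    d <- disc[t + 1L]

    urel <- draw_u(seed, .EV["relapse"] + soff, t, n)
    rel <- alive & pain <= 2L & urel < p_rel
    pain[rel] <- if (cascade) pain[rel] + 1L else 3L

    uup <- draw_u(seed, .EV["uptake"] + soff, t, n)
    elig <- alive & !rt & (pain == 3L | (elig_partial[fl] & pain == 2L))
    retr <- elig & uup < sp$uptake[fl]
    w <- which(retr)
    old_pain <- pain
    if (length(w)) {
      rt[w] <- TRUE
      urs <- draw_u(seed, rtag, t, n)[w]
      pain[w] <- 1L + (urs > ret_cum[cbind(fl[w], 1L)]) +
        (urs > ret_cum[cbind(fl[w], 2L)])
      acc_cost[w] <- acc_cost[w] + d * sp$ret_cost[fl[w]]
      acc_qaly[w] <- acc_qaly[w] + d * sp$ret_du[fl[w]]
    }

    ufx <- draw_u(seed, .EV["fracture"] + soff, t, n)
    pfx_now <- ifelse(rt, sp$pfx_ret[fl], sp$pfx_first[fl])
    newfx <- alive & !fx & ufx < pfx_now
    fx <- fx | newfx
    wf <- which(newfx)
    if (length(wf)) {
      acc_cost[wf] <- acc_cost[wf] + d * co$c_fracture_total
      acc_qaly[wf] <- acc_qaly[wf] + d * u$du_fracture
    }

    # accrual; freshly retreated patients blend old/new state until onset
    ofr <- numeric(n)
    ofr[w] <- sp$ret_of[fl[w]]
    wt_new <- ifelse(retr, ofr, 1)
    util_t <- wt_new[a] * r_u[pain[a]] + (1 - wt_new[a]) * r_u[old_pain[a]]
    op_t <- c_op * (wt_new[a] * (pain[a] != 1L) + (1 - wt_new[a]) * (old_pain[a] != 1L))
    pain_t <- wt_new[a] * (pain[a] <= 2L) + (1 - wt_new[a]) * (old_pain[a] <= 2L)
    acc_qaly[a] <- acc_qaly[a] + d * util_t
    acc_cost[a] <- acc_cost[a] + d * op_t
    acc_pain[a] <- acc_pain[a] + d * pain_t
    acc_pain_u[a] <- acc_pain_u[a] + pain_t
    t <- t + 1L
  }
  if (H > 120 && any(alive))
    warning(sprintf("horizon reached with %.2f%% of patients still alive",
                    100 * mean(alive)))

  se <- function(x) if (n > 1) stats::sd(x) / sqrt(n) else 0
  out <- list(
    mean_cost = mean(acc_cost), mean_qaly = mean(acc_qaly),
    mean_pain_months = mean(acc_pain),
    mean_pain_months_undisc = mean(acc_pain_u),
    se_cost = se(acc_cost), se_qaly = se(acc_qaly), se_pain = se(acc_pain),
    n = n, engine = "microsim", strategy = strategy, seed = seed, crn = crn
  )
  class(out) <- "bm_arm"
  if (keep_patients)
    attr(out, "patients") <- data.frame(
      cancer = names(params$mortality)[cancer],
      firstline = c("hifu", "mf_ebrt", "sf_ebrt")[fl],
      retreat_used = rt, fracture = fx,
      cost = acc_cost, qaly = acc_qaly, pain_months = acc_pain)
  out
}
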