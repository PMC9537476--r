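# Deterministic cohort engine.
#
# The model is a monthly-cycle state-transition process over
#   (first-line modality) x (pain state) x (retreatment used) x (fracture yet)
# with cancer-specific background mortality. Because death strikes every
# alive state with the same cancer/year-specific probability, the joint
# distribution factorizes into a cancer-specific survival curve S_c(t) and a
# conditional-on-survival occupancy chain w_t that is time-homogeneous. The
# engine propagates w_t once per (strategy, parameter set) and reuses it for
# all three cancers, which makes a full arm evaluation a few milliseconds --
# fast enough to serve as the inner evaluator for PSA and VOI.
#
# Event order within a cycle (documented design choice; tested):
#   death -> pain relapse -> retreatment uptake -> pathological fracture
#   -> accrual of utility, pain-response months and costs.

# state space: 36 alive states, dims (firstline 3, pain 3, retreat 2, fracture 2)
# firstline: 1 = MR-HIFU, 2 = multi-fraction EBRT, 3 = single-fraction EBRT
# pain: 1 = complete, 2 = partial, 3 = persistent
# retreat: 1 = not yet used, 2 = used; fracture: 1 = none yet, 2 = occurred
.NS <- 36L
.FL <- rep(1:3, 12L)
.PAIN <- rep(rep(1:3, each = 3L), 4L)
.RT <- rep(rep(1:2, each = 9L), 2L)
.FX <- rep(1:2, each = 18L)
.sidx <- function(fl, pain, rt, fx) fl + 3L * (pain - 1L) + 9L * (rt - 1L) + 18L * (fx - 1L)

#' Discount factor for a monthly cycle index
#'
#' @param annual_rate annual discount rate (e.g. 0.03).
#' @param cycle month index, 0 for the entry cycle.
#' @return `(1 + annual_rate)^(-cycle / 12)`.
#' @export
discount_factor <- function(annual_rate, cycle) {
  if (any(annual_rate < 0)) stop("annual_rate must be >= 0")
  if (any(cycle < 0)) stop("cycle must be >= 0")
  (1 + annual_rate)^(-cycle / 12)
}

entry_onset_fraction <- function(onset_days) {
  # responders to a day-7 onset treatment enjoy the response for 23/30 of the
  # entry cycle; a 4-week onset contributes nothing until the next cycle
  ifelse(onset_days == 7L, 23 / 30, 0)
}

#' First-line response distribution at model entry
#'
#' @param strategy `"A"` (MR-HIFU-based) or `"B"` (EBRT alone).
#' @param firstline `"hifu"`, `"mf_ebrt"` or `"sf_ebrt"`.
#' @param params a `bm_parameters` object.
#' @return Named weights over `complete`, `partial`, `persistent` with an
#'   `onset_fraction` attribute (share of the entry cycle spent in response).
#' @export
initial_response_distribution <- function(strategy, firstline, params) {
  strategy <- match.arg(strategy, c("A", "B"))
  if (!firstline %in% names(params$treatments)) stop("unknown modality: ", firstline)
  if (strategy == "B" && firstline == "hifu")
    stop("strategy B has no first-line MR-HIFU")
  t <- params$treatments[[firstline]]
  w <- c(complete = t$p_complete, partial = t$p_partial, persistent = t$p_none)
  attr(w, "onset_fraction") <- entry_onset_fraction(t$onset_days)
  w
}

#' Response distribution after retreatment
#'
#' Strategy A retreats EBRT-first patients with MR-HIFU (first-line MR-HIFU
#' effectiveness) and MR-HIFU-first patients with EBRT (first-line EBRT
#' effectiveness, since they are radiation-naive). Strategy B re-irradiates:
#' the no-response probability is the re-irradiation value and the remainder
#' is split between complete and partial in the first-line ratio.
#'
#' @inheritParams initial_response_distribution
#' @param modality the retreatment modality (`"hifu"`, `"mf_ebrt"`, `"sf_ebrt"`).
#' @return Named weights over `complete`, `partial`, `persistent` with an
#'   `onset_fraction` attribute.
#' @export
retreat_response_distribution <- function(strategy, modality, params) {
  strategy <- match.arg(strategy, c("A", "B"))
  if (!modality %in% names(params$treatments)) stop("unknown modality: ", modality)
  t <- params$treatments[[modality]]
  if (strategy == "A" || modality == "hifu") {
    # radiation-naive (or HIFU) retreatment: first-line effectiveness
    w <- c(complete = t$p_complete, partial = t$p_partial, persistent = t$p_none)
  } else {
    pn <- params$p_no_response_retreat
    resp <- t$p_complete + t$p_partial
    split <- if (resp > 0) c(t$p_complete, t$p_partial) / resp else c(0.5, 0.5)
    w <- c(complete = (1 - pn) * split[1], partial = (1 - pn) * split[2],
           persistent = pn)
  }
  attr(w, "onset_fraction") <- entry_onset_fraction(t$onset_days)
  w
}

# per-strategy derived quantities, indexed by first-line modality 1:3
strategy_spec <- function(p, strategy) {
  strategy <- match.arg(strategy, c("A", "B"))
  tr <- p$treatments
  s <- p$strategy
  co <- p$costs
  mf_cost <- s$share_ebrt_outpatient * co$c_mf_ebrt_outpatient +
    (1 - s$share_ebrt_outpatient) * co$c_mf_ebrt_inpatient
  entry_cost <- c(co$c_mri_outpatient + co$c_hifu_inpatient, mf_cost, co$c_sf_ebrt)
  uu <- p$utilities
  entry_du <- c(uu$du_hifu, uu$du_mf_ebrt, uu$du_sf_ebrt)
  prof <- rbind(
    c(tr$hifu$p_complete, tr$hifu$p_partial, tr$hifu$p_none),
    c(tr$mf_ebrt$p_complete, tr$mf_ebrt$p_partial, tr$mf_ebrt$p_none),
    c(tr$sf_ebrt$p_complete, tr$sf_ebrt$p_partial, tr$sf_ebrt$p_none)
  )
  prof <- prof / rowSums(prof)  # printed triplets may be off by rounding
  of <- entry_onset_fraction(c(tr$hifu$onset_days, tr$mf_ebrt$onset_days,
                               tr$sf_ebrt$onset_days))
  pfx_first <- c(tr$hifu$p_fracture_monthly, tr$mf_ebrt$p_fracture_monthly,
                 tr$sf_ebrt$p_fracture_monthly)

  ssf <- s$share_sf_ebrt
  if (strategy == "A") {
    sh <- s$share_hifu_firstline_A
    shares <- c(sh, (1 - sh) * (1 - ssf), (1 - sh) * ssf)
    # retreat of HIFU-first patients: EBRT (MF/SF mix), radiation-naive
    ebrt_prof <- (1 - ssf) * prof[2, ] + ssf * prof[3, ]
    ret_prof <- rbind(ebrt_prof, prof[1, ], prof[1, ])
    ret_cost <- c((1 - ssf) * mf_cost + ssf * co$c_sf_ebrt,
                  co$c_hifu_inpatient, co$c_hifu_inpatient)
    ret_du <- c((1 - ssf) * entry_du[2] + ssf * entry_du[3],
                entry_du[1], entry_du[1])
    ret_of <- c(0, of[1], of[1])
    pfx_ret <- c((1 - ssf) * pfx_first[2] + ssf * pfx_first[3],
                 pfx_first[1], pfx_first[1])
    uptake <- switch(s$retreat_uptake_A,
      by_firstline = c(tr$hifu$p_retreat_monthly, tr$mf_ebrt$p_retreat_monthly,
                       tr$sf_ebrt$p_retreat_monthly),
      strategy_rate = rep(tr$hifu$p_retreat_monthly, 3)
    )
    if (s$retreat_rate_A_override >= 0) uptake <- rep(s$retreat_rate_A_override, 3)
    # eligibility per first-line modality; "by_modality" ties it to the
    # retreatment treatment: MR-HIFU retreat also accepts partial relief,
    # EBRT retreat (re-irradiation-like) only persistent pain
    elig_pain <- switch(s$retreat_eligibility_A,
      persistent_or_partial = list(c(2L, 3L), c(2L, 3L), c(2L, 3L)),
      persistent_only = list(3L, 3L, 3L),
      by_modality = list(3L, c(2L, 3L), c(2L, 3L))
    )
  } else {
    shares <- c(0, 1 - ssf, ssf)
    ret_prof <- rbind(
      c(0, 0, 1),
      unname(retreat_response_distribution("B", "mf_ebrt", p)),
      unname(retreat_response_distribution("B", "sf_ebrt", p))
    )
    ret_cost <- c(0, mf_cost, co$c_sf_ebrt)
    ret_du <- c(0, entry_du[2], entry_du[3])
    ret_of <- c(0, 0, 0)
    pfx_ret <- pfx_first
    uptake <- c(0, tr$mf_ebrt$p_retreat_monthly, tr$sf_ebrt$p_retreat_monthly)
    elig_pain <- if (s$retreat_eligibility_B == "persistent_only")
      list(3L, 3L, 3L) else list(c(2L, 3L), c(2L, 3L), c(2L, 3L))
  }
  list(strategy = strategy, shares = shares, entry_cost = entry_cost,
       entry_du = entry_du, prof = prof, of = of, ret_prof = ret_prof,
       ret_cost = ret_cost, ret_du = ret_du, ret_of = ret_of,
       uptake = uptake, elig_pain = elig_pain,
       pfx_first = pfx_first, pfx_ret = pfx_ret)
}

#' Build the one-cycle transition kernel of the cohort engine
#'
#' Constructs the conditional-on-survival transition matrix over the 36
#' alive states, the per-state accrual reward vectors and the per-state
#' expected one-time event rewards (retreatment costs/disutilities with
#' response-onset corrections, fracture cost/disutility). Mostly useful for
#' inspection and testing; [expected_outcomes()] drives it.
#'
#' @inheritParams initial_response_distribution
#' @return A list with the transition matrix `K`, entry occupancy `w0`,
#'   accrual vectors `r_cost`, `r_util`, `r_pain`, event vectors `e_cost`,
#'   `e_util`, `e_pain`, entry quantities, and the state labels.
#' @export
cohort_kernel <- function(params, strategy) {
  sp <- strategy_spec(params, strategy)
  u <- params$utilities
  gp <- if (params$response_gain_mode == "pooled") u$gain_complete else u$gain_partial
  gain <- c(u$gain_complete, gp, 0)
  r_util <- u$u_base + gain[.PAIN]
  r_cost <- params$costs$c_opioid_monthly * (.PAIN != 1L)
  r_pain <- as.numeric(.PAIN <= 2L)

  p_rel <- params$p_relapse_monthly
  cascade <- params$relapse_structure == "cascade"
  K_rel <- diag(.NS)
  rel_from <- which(.PAIN <= 2L)
  for (s in rel_from) {
    K_rel[s, s] <- 1 - p_rel
    to_pain <- if (cascade) .PAIN[s] + 1L else 3L
    tgt <- .sidx(.FL[s], to_pain, .RT[s], .FX[s])
    K_rel[s, tgt] <- K_rel[s, tgt] + p_rel
  }

  K_ret <- diag(.NS)
  ret_cost_vec <- ret_util1 <- corr_cost <- corr_util <- corr_pain <- numeric(.NS)
  r_u_pain <- params$utilities$u_base + gain
  r_c_pain <- params$costs$c_opioid_monthly * c(0, 1, 1)
  r_p_pain <- c(1, 1, 0)
  elig <- which(.RT == 1L & vapply(seq_len(.NS), function(s)
    .PAIN[s] %in% sp$elig_pain[[.FL[s]]], logical(1)))
  for (s in elig) {
    fl <- .FL[s]
    q <- sp$uptake[fl]
    if (q == 0) next
    K_ret[s, s] <- 1 - q
    for (new in 1:3) {
      tgt <- .sidx(fl, new, 2L, .FX[s])
      K_ret[s, tgt] <- K_ret[s, tgt] + q * sp$ret_prof[fl, new]
    }
    ret_cost_vec[s] <- q * sp$ret_cost[fl]
    ret_util1[s] <- q * sp$ret_du[fl]
    # onset correction: until response onset the cycle is accrued in the
    # pre-retreatment pain state
    blend <- sp$ret_of[fl] - 1
    corr_util[s] <- q * blend * (sum(sp$ret_prof[fl, ] * r_u_pain) - r_u_pain[.PAIN[s]])
    corr_cost[s] <- q * blend * (sum(sp$ret_prof[fl, ] * r_c_pain) - r_c_pain[.PAIN[s]])
    corr_pain[s] <- q * blend * (sum(sp$ret_prof[fl, ] * r_p_pain) - r_p_pain[.PAIN[s]])
  }

  K_fx <- diag(.NS)
  pfx <- ifelse(.RT == 1L, sp$pfx_first[.FL], sp$pfx_ret[.FL])
  fxc <- fxu <- numeric(.NS)
  for (s in which(.FX == 1L)) {
    pf <- pfx[s]
    K_fx[s, s] <- 1 - pf
    K_fx[s, .sidx(.FL[s], .PAIN[s], .RT[s], 2L)] <- pf
    fxc[s] <- pf * params$costs$c_fracture_total
    fxu[s] <- pf * params$utilities$du_fracture
  }

  e_cost <- as.vector(K_rel %*% (ret_cost_vec + corr_cost + K_ret %*% fxc))
  e_util <- as.vector(K_rel %*% (ret_util1 + corr_util + K_ret %*% fxu))
  e_pain <- as.vector(K_rel %*% corr_pain)
  K <- K_rel %*% K_ret %*% K_fx
  leak <- max(abs(rowSums(K) - 1))
  if (leak > 1e-9)
    stop("internal consistency error: probability mass leak ", format(leak))

  w0 <- numeric(.NS)
  for (fl in 1:3)
    for (pain in 1:3)
      w0[.sidx(fl, pain, 1L, 1L)] <- sp$shares[fl] * sp$prof[fl, pain]

  list(K = K, K_fx = K_fx, w0 = w0,
       r_cost = r_cost, r_util = r_util, r_pain = r_pain,
       e_cost = e_cost, e_util = e_util, e_pain = e_pain,
       fxc = fxc, fxu = fxu,
       entry_cost = sum(sp$shares * sp$entry_cost),
       entry_du = sum(sp$shares * sp$entry_du),
       of_state = sp$of[.FL],
       spec = sp,
       state = data.frame(firstline = c("hifu", "mf_ebrt", "sf_ebrt")[.FL],
                          pain = c("complete", "partial", "persistent")[.PAIN],
                          retreat_used = .RT == 2L, fracture = .FX == 2L))
}

#' Advance a cohort occupancy by one cycle
#'
#' Applies the relapse/retreat/fracture kernel to a conditional-on-survival
#' occupancy vector and reports the expected per-cycle accruals (state
#' rewards of the new occupancy plus one-time event rewards of the
#' transition), undiscounted.
#'
#' @param occupancy numeric vector over the 36 alive states (see
#'   [cohort_kernel()]`$state`); total mass may be below 1 if part of the
#'   cohort is dead.
#' @param kernel result of [cohort_kernel()].
#' @return List with the new `occupancy` and expected `cost`, `qaly`,
#'   `pain_months` accrued over the cycle.
#' @export
cycle_update <- function(occupancy, kernel) {
  if (length(occupancy) != .NS) stop("occupancy must have length 36")
  if (any(occupancy < -1e-12)) stop("negative occupancy mass")
  new <- as.vector(occupancy %*% kernel$K)
  if (abs(sum(new) - sum(occupancy)) > 1e-9)
    stop("internal consistency error: probability mass leak in cycle_update")
  list(occupancy = new,
       cost = sum(new * kernel$r_cost) + sum(occupancy * kernel$e_cost),
       qaly = sum(new * kernel$r_util) + sum(occupancy * kernel$e_util),
       pain_months = sum(new * kernel$r_pain) + sum(occupancy * kernel$e_pain))
}

# monthly death probability by cycle index (0-based); years beyond the table
# use the extrapolation value (year-5 by default)
mortality_by_cycle <- function(mort, n_cycles) {
  yr <- pmin((seq_len(n_cycles) - 1L) %/% 12L + 1L, 6L)  # cycles 0..11 -> year 1
  c(mort$monthly_p_by_year, mort$extrapolation_p)[yr]
}

# survival through cycles 0..(n_cycles-1): S[t+1] = P(alive at accrual of cycle t)
survival_curve <- function(mort, n_cycles) {
  cumprod(1 - mortality_by_cycle(mort, n_cycles))
}

#' Expected discounted outcomes of one strategy (cohort engine)
#'
#' Propagates the full joint state distribution month by month and returns
#' exact expected discounted cost (EUR), QALYs and months in complete-or-
#' partial pain response per patient, for the mixed cohort and per cancer
#' type. Serves as the noise-free oracle for the microsimulation and as the
#' inner evaluator for PSA and VOI.
#'
#' @inheritParams initial_response_distribution
#' @return A `bm_arm` object: `mean_cost`, `mean_qaly`, `mean_pain_months`,
#'   `mean_pain_months_undisc`, zero Monte-Carlo SEs, and a `by_cancer`
#'   data frame.
#' @examples
#' expected_outcomes("B", bm_parameters())
#' @export
expected_outcomes <- function(strategy, params) {
  stopifnot_valid(params)
  kern <- cohort_kernel(params, strategy)
  H <- params$horizon_months
  Smat <- vapply(params$mortality, survival_curve, numeric(H), n_cycles = H)
  # truncate once every cancer's survivorship is numerically extinct
  Teff <- min(H, max(which(apply(Smat, 1, max) > 1e-14), 1L) + 1L)
  # a short horizon (the survival-evidence span) leaves survivors by design;
  # only an intended-lifetime horizon with leftover mass is suspicious
  if (H > 120 && Teff >= H && max(Smat[H, ]) > 0.001)
    warning(sprintf("horizon reached with %.2f%% of the cohort still alive",
                    100 * max(Smat[H, ])))

  stream_cost <- stream_util <- stream_pain <- numeric(Teff)
  w0 <- kern$w0
  of <- kern$of_state
  pers <- .sidx(.FL, 3L, .RT, .FX)
  blend <- function(r) of * r + (1 - of) * r[pers]
  stream_cost[1] <- sum(w0 * (blend(kern$r_cost) + kern$fxc))
  stream_util[1] <- sum(w0 * (blend(kern$r_util) + kern$fxu)) + kern$entry_du
  stream_pain[1] <- sum(w0 * blend(kern$r_pain))

  a <- as.vector(w0 %*% kern$K_fx)
  K <- kern$K
  if (Teff > 1) for (t in 2:Teff) {
    anew <- as.vector(a %*% K)
    stream_cost[t] <- sum(anew * kern$r_cost) + sum(a * kern$e_cost)
    stream_util[t] <- sum(anew * kern$r_util) + sum(a * kern$e_util)
    stream_pain[t] <- sum(anew * kern$r_pain) + sum(a * kern$e_pain)
    a <- anew
  }

  disc <- discount_factor(params$discount_annual, 0:(Teff - 1))
  by_cancer <- data.frame(cancer = names(params$mortality),
                          mean_cost = NA_real_, mean_qaly = NA_real_,
                          mean_pain_months = NA_real_,
                          mean_pain_months_undisc = NA_real_)
  for (i in seq_along(params$mortality)) {
    S <- Smat[seq_len(Teff), i]
    by_cancer$mean_cost[i] <- kern$entry_cost + sum(S * disc * stream_cost)
    by_cancer$mean_qaly[i] <- sum(S * disc * stream_util)
    by_cancer$mean_pain_months[i] <- sum(S * disc * stream_pain)
    by_cancer$mean_pain_months_undisc[i] <- sum(S * stream_pain)
  }
  mix <- params$cancer_mix
  out <- list(
    mean_cost = sum(mix * by_cancer$mean_cost),
    mean_qaly = sum(mix * by_cancer$mean_qaly),
    mean_pain_months = sum(mix * by_cancer$mean_pain_months),
    mean_pain_months_undisc = sum(mix * by_cancer$mean_pain_months_undisc),
    se_cost = 0, se_qaly = 0, se_pain = 0,
    n = 1L, engine = "cohort", strategy = strategy, by_cancer = by_cancer
  )
  class(out) <- "bm_arm"
  out
}

#' Run one strategy with either engine
#'
#' @inheritParams initial_response_distribution
#' @param engine `"cohort"` for the deterministic expectation engine,
#'   `"microsim"` for the patient-level simulation.
#' @param n_patients number of simulated patients (microsim only).
#' @param seed master seed (microsim only).
#' @param crn use common random numbers across strategies (microsim only).
#' @return A `bm_arm` object.
#' @export
run_strategy <- function(strategy, params, engine = c("cohort", "microsim"),
                         n_patients = 200000L, seed = 1L, crn = TRUE) {
  engine <- match.arg(engine)
  if (engine == "cohort") expected_outcomes(strategy, params)
  else microsim_arm(strategy, params, n_patients = n_patients, seed = seed, crn = crn)
}

#' @export
print.bm_arm <- function(x, ...) {
  cat(sprintf("Strategy %s (%s engine%s)\n", x$strategy, x$engine,
              if (x$engine == "microsim") sprintf(", n = %d", x$n) else ""))
  cat(sprintf("  mean discounted cost: %10.2f EUR  (SE %.2f)\n", x$mean_cost, x$se_cost))
  cat(sprintf("  mean discounted QALY: %10.4f       (SE %.4f)\n", x$mean_qaly, x$se_qaly))
  cat(sprintf("  pain-response months: %10.3f       (SE %.3f)\n",
              x$mean_pain_months, x$se_pain))
  invisible(x)
}

#' @export
as.data.frame.bm_arm <- function(x, ...) {
  data.frame(strategy = x$strategy, engine = x$engine,
             mean_cost = x$mean_cost, mean_qaly = x$mean_qaly,
             mean_pain_months = x$mean_pain_months,
             se_cost = x$se_cost, se_qaly = x$se_qaly, se_pain = x$se_pain,
             n = x$n)
}
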