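# shared helpers: reduced deterministic configurations for closed-form checks

# set several flat parameters at once
param_flat <- function(p, ...) {
  ov <- list(...)
  for (nm in names(ov)) p <- param_set(p, nm, ov[[nm]])
  p
}

# constant-hazard reduced model: one mortality rate everywhere, optional
# switches for relapse/retreat/fracture, zero discounting by default
reduced_params <- function(p_death = 0.03, p_relapse = 0, retreat = FALSE,
                           fracture = FALSE, discount = 0, horizon = 600L,
                           relapse_structure = "to_persistent") {
  p <- bm_parameters()
  for (cc in names(p$mortality)) {
    p$mortality[[cc]]$monthly_p_by_year <- rep(p_death, 5)
    p$mortality[[cc]]$extrapolation_p <- p_death
  }
  p$p_relapse_monthly <- p_relapse
  p$relapse_structure <- relapse_structure
  if (!retreat)
    for (tr in names(p$treatments)) p$treatments[[tr]]$p_retreat_monthly <- 0
  if (!fracture)
    for (tr in names(p$treatments)) p$treatments[[tr]]$p_fracture_monthly <- 0
  p$discount_annual <- discount
  p$horizon_months <- as.integer(horizon)
  p
}

arm_vec <- function(a) c(cost = a$mean_cost, qaly = a$mean_qaly,
                         pain = a$mean_pain_months)
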