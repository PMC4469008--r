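# Shared fixtures: an order-of-magnitude-plausible parameter set for the
# murine system (r, K, ef, T_death are study values; the rest illustrative)
# and the validated weekly infusion schedule.

base_params <- function(...) {
  defaults <- list(
    r = 0.00106, K = 6.754e15, a_T = 5e-8, supp_floor = 0.69,
    e_supp = 1e4, mu_D = 0.0096, r_a = 0.05, r_e = 0.01, tau = 96,
    theta_D = 2.5e5, theta_a = 2.5e6, mu_Ca = 0.007, mu_Ci = 0.0012,
    p_beta = 5.75e-6, mu_beta = 0.14, ef = 0.5,
    T_death = 1.6e10, T_erad = 1
  )
  mods <- list(...)
  defaults[names(mods)] <- mods
  validate_model_parameters(defaults)
}

inoculum <- function(C_i0 = 1e5) c(6e4, 0, C_i0, 0)

weekly_schedule <- function(n = 3, dose = 1e6, ef = 0.5) {
  dose_schedule(168 * seq_len(n), dose, ef)
}

# minimal trajectory wrapper for metric arithmetic on hand-made series
toy_trajectory <- function(times, T_values, params = base_params()) {
  states <- cbind(T = T_values, C_a = 0, C_i = 0, F_beta = 0)
  dcimmune:::new_trajectory(times, states, rep(0, length(times)),
                            NA_real_, NA_real_, 0L,
                            dt = diff(times)[1], params,
                            dose_schedule())
}
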