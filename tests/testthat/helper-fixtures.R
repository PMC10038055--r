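# shared fixtures: small, fast model/protocol builders used across tests

# noiseless activation-only model (no inactivation, no gating charge)
act_only_model <- function(v05 = 1.48, k = 8.69, vrev = 60.25, ...) {
  args <- utils::modifyList(
    list(n_channels = 5000, gamma_ps = 4, v_rev = vrev, act_v05 = v05,
         act_k = k, p_open_max = 1, tau_act_ms = 2, i_ss = 1,
         q_gating_e0 = 0),
    list(...))
  do.call(channel_model, args)
}

# inactivating model with activation from the WT Ca set
inact_model <- function(v05i = -16, ki = -6.73, iss = 0, tau_i = 500, ...) {
  args <- utils::modifyList(
    list(n_channels = 5000, gamma_ps = 4, v_rev = 60.25, act_v05 = 1.48,
         act_k = 8.69, p_open_max = 1, tau_act_ms = 2, inact_v05 = v05i,
         inact_k = ki, i_ss = iss, tau_inact_ms = tau_i, q_gating_e0 = 0),
    list(...))
  do.call(channel_model, args)
}

# the stochastic NSFA tail fixture: N = 1000, i = -0.5 pA at -49 mV,
# P0 = 0.8, b = 4 pA^2 (model default seed = 1)
nsfa_fixture_model <- function(...) {
  args <- utils::modifyList(
    list(n_channels = 1000, gamma_ps = 0.5 * 1000 / (49 + 60.25),
         v_rev = 60.25, act_v05 = 1.48, act_k = 8.69, p_open_max = 0.8,
         tau_act_ms = 2, i_ss = 1, noise_sd_pa = 2, q_gating_e0 = 0),
    list(...))
  do.call(channel_model, args)
}

# 1-based sample indices of one protocol epoch (test-side reimplementation)
epoch_sample_idx_for_test <- function(p, e) {
  ns <- round(p$epochs$duration_ms * p$sample_rate_khz)
  start <- c(0, cumsum(ns))[e]
  start + seq_len(ns[e])
}

# tiny 2-sweep sweep_set for I/O tests
tiny_sweepset <- function() {
  pr <- voltage_protocol("tiny", -80,
                         data.frame(level_mv = c(-80, NA),
                                    duration_ms = c(0.04, 0.06)),
                         sweep_levels = c(-10, 10), sample_rate_khz = 50)
  sweep_set(time = (0:4) * 0.02,
            sweeps = matrix(c(0.1, -0.2, 0.3, -0.4, 0.5,
                              1, 2, 3, 4, 5), 2, 5, byrow = TRUE),
            protocol = pr, capacitance_pf = 10,
            annotations = list(cell = "c1"))
}
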