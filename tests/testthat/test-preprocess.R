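# passive-only model: linear leak + capacitive transients, no channels,
# no gating charge
passive_model <- function(g_ns, cap_amp = 0, cap_tau = 0.15, ...) {
  args <- utils::modifyList(
    list(n_channels = 1, gamma_ps = 4, v_rev = 60, p_open_max = 0,
         i_ss = 1, q_gating_e0 = 0, leak_conductance_ns = g_ns,
         cap_amp_pa_per_mv = cap_amp, cap_tau_ms = cap_tau),
    list(...))
  do.call(channel_model, args)
}

test_that("P/4 annihilates affine leak + capacitive transients exactly", {
  # property over random passive parameters
  set.seed(404)
  for (rep in 1:5) {
    g <- runif(1, 0.1, 2)
    amp <- runif(1, 0, 5)
    m <- passive_model(g, cap_amp = amp)
    pr <- protocol_iv(v_from = -60, v_to = 40, dv = 25, pulse_ms = 10,
                      sample_rate_khz = 20)
    test <- simulate_sweeps(m, pr, mode = "deterministic")$sweeps
    subs <- simulate_p4_family(m, pr, mode = "deterministic")$sweeps
    corr <- p4_subtract(test, subs)
    expect_lt(max(abs(corr$sweeps)), 1e-10)
    expect_equal(corr$leak_subtracted, "p4")
  }
})

test_that("P/4 with channels recovers the channels-only current", {
  base <- list(n_channels = 2000, gamma_ps = 4, v_rev = 60.25,
               act_v05 = 1.48, act_k = 8.69, p_open_max = 1,
               tau_act_ms = 2, i_ss = 1, q_gating_e0 = 0,
               cap_amp_pa_per_mv = 2)
  with_leak <- do.call(channel_model,
                       utils::modifyList(base,
                                         list(leak_conductance_ns = 0.8)))
  no_leak <- do.call(channel_model,
                     utils::modifyList(base,
                                       list(leak_conductance_ns = 0,
                                            cap_amp_pa_per_mv = 0)))
  pr <- protocol_iv(v_from = -40, v_to = 20, dv = 20, pulse_ms = 20,
                    sample_rate_khz = 20)
  test <- simulate_sweeps(with_leak, pr, mode = "deterministic")$sweeps
  # sub-pulses stay sub-threshold, so the passive template is channel-free
  subs <- simulate_p4_family(with_leak, pr, mode = "deterministic")$sweeps
  corr <- p4_subtract(test, subs)
  ref <- simulate_sweeps(no_leak, pr, mode = "deterministic")$sweeps
  # sub-pulse steps (max -89 + 109/4 = -61.75 mV) open a few channels, so
  # agreement is to a small fraction of the peak, not machine precision
  expect_lt(max(abs(corr$sweeps - ref$sweeps)),
            0.01 * max(abs(ref$sweeps)))
})

test_that("wrongly scaled sub-pulses leave residual leak and a warning", {
  m <- passive_model(1.0)
  pr <- protocol_iv(v_from = -60, v_to = 40, dv = 25, pulse_ms = 10,
                    sample_rate_khz = 20)
  test <- simulate_sweeps(m, pr, mode = "deterministic")$sweeps
  subs <- simulate_p4_family(m, pr, mode = "deterministic")$sweeps
  subs$sweeps <- subs$sweeps * 0.8     # wrong gain
  expect_warning(p4_subtract(test, subs), "residual|scaling")
})

test_that("p4_subtract validates alignment", {
  m <- passive_model(1)
  pr <- protocol_iv(v_from = -60, v_to = 40, dv = 50, pulse_ms = 10,
                    sample_rate_khz = 20)
  test <- simulate_sweeps(m, pr, mode = "deterministic")$sweeps
  subs <- simulate_p4_family(m, pr, mode = "deterministic")$sweeps
  subs$sweeps <- subs$sweeps[-1, , drop = FALSE]
  subs$protocol$sweep_levels <- subs$protocol$sweep_levels[-1]
  expect_error(p4_subtract(test, subs), "alignment")
})

test_that("offline leak fit recovers the true conductance within 1%", {
  m <- channel_model(n_channels = 2000, gamma_ps = 4, v_rev = 60.25,
                     act_v05 = 1.48, act_k = 8.69, p_open_max = 1,
                     tau_act_ms = 2, i_ss = 1, q_gating_e0 = 0,
                     leak_conductance_ns = 0.5)
  sim <- simulate_iv_family(m, v_from = -100, v_to = 30, dv = 10,
                            pulse_ms = 20, sample_rate_khz = 20,
                            mode = "deterministic")
  # fit window well below threshold: Boltzmann-tail channel current at
  # -80 mV and below is < 1% of the leak
  corr <- offline_leak_subtract(sim$sweeps, subthreshold_max_mv = -80)
  expect_lt(abs(attr(corr, "leak_g_ns") / 0.5 - 1), 0.01)
  expect_equal(corr$leak_subtracted, "offline")
  # pure linear leak -> zeros
  ml <- passive_model(0.5)
  siml <- simulate_iv_family(ml, v_from = -80, v_to = 30, dv = 10,
                             pulse_ms = 20, sample_rate_khz = 20,
                             mode = "deterministic")
  corrl <- offline_leak_subtract(siml$sweeps, subthreshold_max_mv = -60)
  expect_lt(max(abs(corrl$sweeps)), 1e-10)
  # too few sub-threshold levels
  expect_error(offline_leak_subtract(sim$sweeps, subthreshold_max_mv = -95),
               ">= 2")
  # activation reaching into the fit window -> warning
  mearly <- channel_model(n_channels = 2000, gamma_ps = 4, v_rev = 60.25,
                          act_v05 = -55, act_k = 8, p_open_max = 1,
                          tau_act_ms = 2, i_ss = 1, q_gating_e0 = 0,
                          leak_conductance_ns = 0.5)
  sime <- simulate_iv_family(mearly, v_from = -80, v_to = 30, dv = 10,
                             pulse_ms = 20, sample_rate_khz = 20,
                             mode = "deterministic")
  expect_warning(offline_leak_subtract(sime$sweeps,
                                       subthreshold_max_mv = -50),
                 "contaminate")
})

test_that("measure_peaks matches the dense gate-ODE solution", {
  m <- inact_model(tau_i = 100)
  sim <- simulate_iv_family(m, v_from = -30, v_to = 20, dv = 10,
                            mode = "deterministic")
  pk <- suppressWarnings(measure_peaks(sim$sweeps))
  # independent dense-grid oracle: |I| = N p(t) h(t) |i(V)| maximized on a
  # 10x finer grid, closed-form gate solutions
  for (r in seq_len(nrow(pk))) {
    v <- pk$step_level[r]
    tt <- seq(0, 50, by = 0.002)
    pinf <- p_inf(m, v); h0 <- h_inf(m, -89); hinf <- h_inf(m, v)
    p0 <- p_inf(m, -89)
    p_t <- pinf + (p0 - pinf) * exp(-tt / 2)
    h_t <- hinf + (h0 - hinf) * exp(-tt / 100)
    i_t <- m$n_channels * p_t * h_t * i_single(m, v)
    expect_equal(pk$peak_pa[r], i_t[which.max(abs(i_t))],
                 tolerance = 1e-3)
    expect_equal(pk$time_to_peak_ms[r], tt[which.max(abs(i_t))],
                 tolerance = 0.05)
  }
})

test_that("measure_peaks handles degenerate sweeps and offsets", {
  m <- act_only_model()
  m$p_open_max <- 0
  sim <- simulate_iv_family(m, v_from = -20, v_to = 30, dv = 10,
                            pulse_ms = 5, mode = "deterministic")
  w <- capture_warnings(pk <- measure_peaks(sim$sweeps))
  expect_true(any(grepl("all-zero", w)))
  expect_true(all(pk$peak_pa == 0))

  # invariance under constant offset after offline leak subtraction
  m2 <- inact_model(leak_conductance_ns = 0.4)
  sim2 <- simulate_iv_family(m2, v_from = -80, v_to = 30, dv = 10,
                             pulse_ms = 20, sample_rate_khz = 20,
                             mode = "deterministic")
  corr <- offline_leak_subtract(sim2$sweeps, subthreshold_max_mv = -60)
  pk1 <- measure_peaks(corr)
  shifted <- corr
  shifted$sweeps <- shifted$sweeps + 3.7
  corr2 <- suppressWarnings(
    offline_leak_subtract(shifted, subthreshold_max_mv = -60))
  pk2 <- measure_peaks(corr2)
  expect_equal(pk1$peak_pa, pk2$peak_pa, tolerance = 1e-8)
})

test_that("r250 definition: steady/peak ratio on a 300-ms pulse", {
  m <- inact_model(v05i = -60, ki = -6, tau_i = 100, tau_act_ms = 0)
  sim <- simulate_iv_family(m, v_from = 40, v_to = 40, dv = 10,
                            pulse_ms = 300, sample_rate_khz = 20,
                            mode = "deterministic")
  pk <- suppressWarnings(
    measure_peaks(sim$sweeps, steady_window_ms = 100))
  seg <- segment(sim$sweeps, 2)[[1]]
  # steady window centered at 250 ms reproduces r250 within the decay slope
  st <- mean(seg$values[(250 - 50) * 20 + (1:(100 * 20))])
  expect_equal(pk$steady_pa / pk$peak_pa,
               r_ratio(seg, at_ms = 250), tolerance = 0.1)
  expect_equal(st / pk$peak_pa, r_ratio(seg, at_ms = 250), tolerance = 0.05)
})

test_that("normalize_density follows the pA/pF convention", {
  expect_equal(normalize_density(259.9, 10), 25.99)
  expect_equal(normalize_density(0, 7), 0)
  expect_error(normalize_density(100, 0), "capacitance")
})

test_that("low-pass smoothing attenuates noise, passes slow waves", {
  m <- nsfa_fixture_model(seed = 2)
  pr <- protocol_nsfa(step_ms = 4, tail_ms = 4)
  sim <- simulate_sweeps(m, pr, mode = "stochastic", n_repeats = 10)
  filt <- lowpass_filter(sim$sweeps, cutoff_khz = 2)
  expect_equal(filt$filter_cutoff_khz, 2)
  # high-frequency power shrinks, slow mean structure survives
  hf <- function(x) mean(diff(x)^2)
  expect_lt(hf(filt$sweeps[1, ]), 0.5 * hf(sim$sweeps$sweeps[1, ]))
  expect_equal(mean(filt$sweeps[1, 250:500]),
               mean(sim$sweeps$sweeps[1, 250:500]), tolerance = 0.05)
})
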