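#' Simulate ensemble currents under a voltage protocol
#'
#' Generates synthetic whole-cell sweeps with fully recorded ground truth.
#' In `stochastic` mode every channel is an independent two-gate Markov
#' chain sampled on the acquisition grid: the activation gate flips
#' C <-> O with rates `alpha(V) = p_inf(V)/tau_act` and
#' `beta(V) = (1 - p_inf(V))/tau_act` (where `p_inf` is already scaled by
#' `p_open_max`), and the inactivation gate analogously from its own
#' Boltzmann with floor `i_ss`.  Per-step transition probabilities use the
#' exact two-state propagator over `dt`
#' (`P(C->O) = p_eq (1 - exp(-(alpha+beta) dt))`, etc.), so the mean of the
#' stochastic mode equals the gate ODE at the sample times for any `dt`;
#' a stability guard still rejects grids coarser than `rate * dt > 0.1`,
#' where the discrete chain badly under-resolves the gating noise
#' spectrum.  The ionic current is
#' `(open count) * i(V) + leak + capacitive transients + gating current +
#' Gaussian noise`.  `deterministic` mode propagates the gate-probability
#' expectations exactly (piecewise closed form) with no noise, so it equals
#' the large-repeat mean of the stochastic mode.
#'
#' Calcium-dependent inactivation, when enabled (`cdi_rate > 0` and
#' `charge_carrier = "Ca"`), multiplies the inactivation rate by
#' `1 + cdi_rate * integral(|I_ionic|) dt` accumulated within each sweep.
#'
#' Sweeps always start from gate equilibrium at the holding potential;
#' identical `(model, protocol, seed)` yield bit-identical output.
#'
#' @param model a [channel_model()].
#' @param protocol a [voltage_protocol()].
#' @param mode "deterministic" (expectation, noiseless) or "stochastic".
#' @param n_repeats stochastic repeats per protocol sweep (rows are grouped
#'   by protocol sweep, repeats consecutive).
#' @param charge_carrier "Ca" or "Ba"; gates CDI and is stamped on the
#'   output metadata.
#' @param conc_mm charge-carrier concentration, mM (metadata).
#' @param capacitance_pf cell capacitance stamped on the output, pF.
#' @param record_states keep per-repeat open-channel-count trajectories in
#'   the truth object (stochastic mode; used by oracle tests).
#' @param seed RNG seed; defaults to `model$seed`.
#' @return list with elements `sweeps` (a [sweep_set()]) and `truth`
#'   (a `simulation_truth`: model snapshot, mode, per-sweep single-channel
#'   currents and expected ON-charge, expected open-probability
#'   trajectories, and optionally the realized open counts).
#' @export
simulate_sweeps <- function(model, protocol,
                            mode = c("deterministic", "stochastic"),
                            n_repeats = 1, charge_carrier = c("Ca", "Ba"),
                            conc_mm = 15, capacitance_pf = 10,
                            record_states = FALSE, seed = model$seed) {
  mode <- match.arg(mode)
  charge_carrier <- match.arg(charge_carrier)
  validate_model(model)
  validate_protocol(protocol)
  m <- model
  p <- protocol
  dt <- 1 / p$sample_rate_khz
  cdi_on <- (charge_carrier == "Ca" && m$cdi_rate > 0)
  check_dt_stability(m, p, dt, mode, cdi_on)

  n_lev <- length(p$sweep_levels)
  n_rep <- if (mode == "stochastic") as.integer(n_repeats) else 1L
  n_samp <- protocol_n_samples(p)
  out <- matrix(0, n_lev * n_rep, n_samp)
  p_open_traj <- matrix(0, n_lev, n_samp)
  open_counts <- if (record_states && mode == "stochastic")
    vector("list", n_lev) else NULL

  if (mode == "stochastic") {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    })
  }

  for (k in seq_len(n_lev)) {
    v <- voltage_trace(p, k)
    passive <- passive_currents(m, p, k)
    if (mode == "deterministic") {
      g <- det_gate_traj(m, p, k, cdi_on)
      out[k, ] <- m$n_channels * g$p * g$h * i_single(m, v) + passive
      p_open_traj[k, ] <- g$p * g$h
    } else {
      st <- stoch_open_counts(m, p, k, n_rep, cdi_on)
      rows <- (k - 1L) * n_rep + seq_len(n_rep)
      ionic <- st$open * matrix(i_single(m, v), n_rep, n_samp, byrow = TRUE)
      noise <- if (m$noise_sd_pa > 0)
        matrix(stats::rnorm(n_rep * n_samp, 0, m$noise_sd_pa),
               n_rep, n_samp) else 0
      out[rows, ] <- ionic + matrix(passive, n_rep, n_samp, byrow = TRUE) +
        noise
      p_open_traj[k, ] <- colMeans(st$open) / m$n_channels
      if (!is.null(open_counts)) open_counts[[k]] <- st$open
    }
  }

  proto_out <- p
  proto_out$sweep_levels <- rep(p$sweep_levels, each = n_rep)
  attrs <- attributes(p)
  for (a in setdiff(names(attrs), c("names", "class")))
    attr(proto_out, a) <- attrs[[a]]
  time <- (seq_len(n_samp) - 1L) * dt
  sweeps <- sweep_set(
    time = time, sweeps = out, protocol = proto_out,
    capacitance_pf = capacitance_pf,
    charge_carrier = list(ion = charge_carrier, conc_mm = conc_mm),
    annotations = list(simulated = "true", mode = mode,
                       seed = as.character(seed)))
  truth <- structure(
    list(model = m, mode = mode, charge_carrier = charge_carrier,
         seed = seed, n_repeats = n_rep, sweep_levels = p$sweep_levels,
         i_test = i_single(m, p$sweep_levels),
         expected_q_on = q_gating_inf(m, p$sweep_levels) -
           q_gating_inf(m, p$holding_mv),
         p_open_traj = p_open_traj, open_counts = open_counts),
    class = "simulation_truth")
  list(sweeps = sweeps, truth = truth)
}

check_dt_stability <- function(m, p, dt, mode, cdi_on) {
  if (mode == "deterministic" && !cdi_on) return(invisible(TRUE))
  lev <- unique(c(p$holding_mv, p$epochs$level_mv, p$sweep_levels))
  lev <- lev[!is.na(lev)]
  taus <- vapply(lev, function(v) tau_act_at(m, v), 0)
  taus <- taus[taus > 0]
  max_rate <- max(c(if (length(taus)) 1 / taus, 1 / m$tau_inact_ms))
  if (max_rate * dt > 0.1)
    stop(sprintf(paste0("sampling too coarse for stable gating transitions ",
                        "(rate*dt = %.3g > 0.1); increase sample_rate_khz"),
                 max_rate * dt))
  invisible(TRUE)
}

## leak + capacitive transients + gating current (all deterministic)
passive_currents <- function(m, p, sweep) {
  v <- voltage_trace(p, sweep)
  dt <- 1 / p$sample_rate_khz
  cur <- m$leak_conductance_ns * v
  ns <- epoch_samples(p)
  starts <- epoch_starts(p)
  q0 <- q_gating_inf(m, p$holding_mv)
  v_prev <- p$holding_mv
  for (e in seq_len(nrow(p$epochs))) {
    idx <- starts[e] + seq_len(ns[e])
    t_rel <- (seq_len(ns[e]) - 1L) * dt
    v_e <- v[idx[1]]
    dv <- v_e - v_prev
    if (m$cap_amp_pa_per_mv != 0 && dv != 0)
      cur[idx] <- cur[idx] +
        m$cap_amp_pa_per_mv * dv * exp(-t_rel / m$cap_tau_ms)
    q_inf <- q_gating_inf(m, v_e)
    if (m$q_gating_e0 != 0)
      cur[idx] <- cur[idx] +
        (q_inf - q0) / m$tau_gating_ms * exp(-t_rel / m$tau_gating_ms)
    q0 <- q_inf + (q0 - q_inf) * exp(-ns[e] * dt / m$tau_gating_ms)
    v_prev <- v_e
  }
  cur
}

## expectation trajectories of the two gates; closed form per epoch unless
## CDI couples the inactivation rate to the running current integral
det_gate_traj <- function(m, p, sweep, cdi_on) {
  v <- voltage_trace(p, sweep)
  dt <- 1 / p$sample_rate_khz
  ns <- epoch_samples(p)
  starts <- epoch_starts(p)
  n <- sum(ns)
  pg <- numeric(n)
  hg <- numeric(n)
  p_cur <- p_inf(m, p$holding_mv)
  h_cur <- h_inf(m, p$holding_mv)
  no_inact <- (m$i_ss >= 1)
  cdi_int <- 0
  for (e in seq_len(nrow(p$epochs))) {
    idx <- starts[e] + seq_len(ns[e])
    v_e <- v[idx[1]]
    pinf <- p_inf(m, v_e)
    hinf <- h_inf(m, v_e)
    ta <- tau_act_at(m, v_e)
    t_rel <- (seq_len(ns[e]) - 1L) * dt
    pg[idx] <- if (ta > 0) pinf + (p_cur - pinf) * exp(-t_rel / ta) else pinf
    p_cur <- pg[idx[length(idx)]]
    if (no_inact) {
      hg[idx] <- 1
      h_cur <- 1
    } else if (!cdi_on) {
      hg[idx] <- hinf + (h_cur - hinf) * exp(-t_rel / m$tau_inact_ms)
      h_cur <- hg[idx[length(idx)]]
    } else {
      ## per-sample exponential update with CDI-scaled inactivation rate
      a_h <- hinf / m$tau_inact_ms
      b_h <- (1 - hinf) / m$tau_inact_ms
      i_v <- i_single(m, v_e)
      for (s in seq_along(idx)) {
        hg[idx[s]] <- h_cur
        f <- 1 + m$cdi_rate * cdi_int
        rt <- a_h + b_h * f
        h_eq <- a_h / rt
        h_cur <- h_eq + (h_cur - h_eq) * exp(-rt * dt)
        cdi_int <- cdi_int +
          abs(m$n_channels * pg[idx[s]] * hg[idx[s]] * i_v) * dt
      }
    }
  }
  list(p = pg, h = hg)
}

## binomial state-count simulation, vectorized across repeats
stoch_open_counts <- function(m, p, sweep, n_rep, cdi_on) {
  v <- voltage_trace(p, sweep)
  dt <- 1 / p$sample_rate_khz
  ns <- epoch_samples(p)
  starts <- epoch_starts(p)
  n_samp <- sum(ns)
  N <- m$n_channels
  no_inact <- (m$i_ss >= 1)

  p0 <- p_inf(m, p$holding_mv)
  h0 <- if (no_inact) 1 else h_inf(m, p$holding_mv)
  nA <- if (no_inact) rep(N, n_rep) else stats::rbinom(n_rep, N, h0)
  nOA <- stats::rbinom(n_rep, nA, p0)
  nOI <- stats::rbinom(n_rep, N - nA, p0)
  nCA <- nA - nOA
  nCI <- N - nA - nOI

  open <- matrix(0L, n_rep, n_samp)
  cdi_int <- numeric(n_rep)

  for (e in seq_len(nrow(p$epochs))) {
    idx <- starts[e] + seq_len(ns[e])
    v_e <- v[idx[1]]
    pinf <- p_inf(m, v_e)
    hinf <- if (no_inact) 1 else h_inf(m, v_e)
    ta <- tau_act_at(m, v_e)
    inst_act <- (ta <= 0)
    if (!inst_act) {
      ## exact two-state propagator over dt (stochastic mean == gate ODE)
      ea <- exp(-dt / ta)
      qa_on <- pinf * (1 - ea)                   # C -> O
      qa_off <- (1 - pinf) * (1 - ea)            # O -> C
    }
    a_h <- hinf / m$tau_inact_ms
    b_h <- (1 - hinf) / m$tau_inact_ms
    eh <- exp(-dt / m$tau_inact_ms)
    qh_on <- hinf * (1 - eh)                     # I -> A (recovery)
    i_v <- i_single(m, v_e)

    for (s in idx) {
      open[, s] <- nOA
      if (cdi_on) cdi_int <- cdi_int + abs(nOA * i_v) * dt
      ## activation-gate flips
      if (inst_act) {
        nOA2 <- stats::rbinom(n_rep, nCA + nOA, pinf)
        nCA2 <- nCA + nOA - nOA2
        nOI2 <- stats::rbinom(n_rep, nCI + nOI, pinf)
        nCI2 <- nCI + nOI - nOI2
      } else {
        up_a <- stats::rbinom(n_rep, nCA, qa_on)
        dn_a <- stats::rbinom(n_rep, nOA, qa_off)
        up_i <- stats::rbinom(n_rep, nCI, qa_on)
        dn_i <- stats::rbinom(n_rep, nOI, qa_off)
        nCA2 <- nCA - up_a + dn_a
        nOA2 <- nOA + up_a - dn_a
        nCI2 <- nCI - up_i + dn_i
        nOI2 <- nOI + up_i - dn_i
      }
      ## inactivation-gate flips (independent of the activation flip)
      if (!no_inact) {
        if (cdi_on) {
          f <- 1 + m$cdi_rate * cdi_int
          rt <- a_h + b_h * f
          decay <- 1 - exp(-rt * dt)
          qh_off <- (b_h * f / rt) * decay
          qh_on <- (a_h / rt) * decay
        } else qh_off <- (1 - hinf) * (1 - eh)
        ina_c <- stats::rbinom(n_rep, nCA2, qh_off)
        ina_o <- stats::rbinom(n_rep, nOA2, qh_off)
        rec_c <- stats::rbinom(n_rep, nCI2, qh_on)
        rec_o <- stats::rbinom(n_rep, nOI2, qh_on)
        nCA <- nCA2 - ina_c + rec_c
        nOA <- nOA2 - ina_o + rec_o
        nCI <- nCI2 + ina_c - rec_c
        nOI <- nOI2 + ina_o - rec_o
      } else {
        nCA <- nCA2; nOA <- nOA2; nCI <- nCI2; nOI <- nOI2
      }
    }
  }
  list(open = open)
}

#' Simulate an I-V step family
#'
#' One sweep per test potential on a regular grid, square pulse from
#' holding (-89 mV by default).  A 300-ms pulse with `dv = 10` gives the
#' r250 family.
#'
#' @inheritParams simulate_sweeps
#' @param v_from,v_to,dv test-potential grid, mV.
#' @param pulse_ms pulse duration, ms.
#' @param holding_mv holding potential, mV.
#' @param sample_rate_khz sampling rate, kHz.
#' @param ... passed to [simulate_sweeps()].
#' @return as [simulate_sweeps()].
#' @export
simulate_iv_family <- function(model, v_from = -80, v_to = 70, dv = 5,
                               pulse_ms = 50,
                               mode = c("deterministic", "stochastic"),
                               holding_mv = -89, sample_rate_khz = 50, ...) {
  if (dv <= 0) stop("dv must be > 0")
  if (v_to < v_from) stop("v_to must be >= v_from")
  proto <- protocol_iv(v_from, v_to, dv, pulse_ms, holding_mv,
                       sample_rate_khz)
  simulate_sweeps(model, proto, mode = match.arg(mode), ...)
}

#' Simulate a steady-state inactivation family
#'
#' Each sweep carries a reference 50-ms test pulse, a long conditioning
#' epoch at the sweep's conditioning potential, and a second test pulse;
#' channel availability is the post/pre test-pulse peak ratio.
#'
#' @inheritParams simulate_sweeps
#' @param cond_levels conditioning potentials, mV.
#' @param cond_ms conditioning duration, ms (5 s default).
#' @param test_level test-pulse potential; defaults to the model's voltage
#'   of maximal inward current (rounded to 1 mV).
#' @param test_ms test-pulse duration, ms.
#' @param holding_mv,sample_rate_khz protocol framing.
#' @param ... passed to [simulate_sweeps()].
#' @export
simulate_ssi_family <- function(model, cond_levels = seq(-89, 31, by = 10),
                                cond_ms = 5000, test_level = NULL,
                                test_ms = 50,
                                mode = c("deterministic", "stochastic"),
                                holding_mv = -89, sample_rate_khz = 20, ...) {
  if (is.null(test_level)) test_level <- round(v_max_model(model))
  proto <- protocol_ssi(cond_levels, cond_ms, test_level, test_ms,
                        holding_mv, sample_rate_khz)
  simulate_sweeps(model, proto, mode = match.arg(mode), ...)
}

#' Voltage of maximal inward current of a model (continuous)
#'
#' Maximizes `|i(V) * p_inf(V)|` between -70 mV and the reversal potential.
#'
#' @param m a `channel_model`.
#' @export
v_max_model <- function(m) {
  stats::optimize(function(v) abs(i_single(m, v)) * p_inf(m, v),
                  c(-70, m$v_rev - 0.5), maximum = TRUE)$maximum
}

#' Simulate the P/4 leak sub-pulse family for a protocol
#'
#' Four identical sub-sweeps per test sweep, stepped from holding with all
#' voltage excursions scaled to one quarter, in the same polarity as the
#' test step.  Rows are grouped: sub-sweeps `4(k-1)+1 .. 4k` belong to test
#' sweep `k`.
#'
#' @inheritParams simulate_sweeps
#' @param n_sub number of sub-pulses (4 for P/4).
#' @param ... passed to [simulate_sweeps()].
#' @export
simulate_p4_family <- function(model, protocol,
                               mode = c("deterministic", "stochastic"),
                               n_sub = 4, ...) {
  validate_protocol(protocol)
  p <- protocol
  scale_lev <- function(lv) p$holding_mv + (lv - p$holding_mv) / n_sub
  sub_epochs <- p$epochs
  sub_epochs$level_mv <- ifelse(is.na(p$epochs$level_mv), NA_real_,
                                scale_lev(p$epochs$level_mv))
  sub_proto <- voltage_protocol(
    name = paste0(p$name, "_p4sub"),
    holding_mv = p$holding_mv,
    epochs = sub_epochs,
    sweep_levels = rep(scale_lev(p$sweep_levels), each = n_sub),
    sample_rate_khz = p$sample_rate_khz)
  simulate_sweeps(model, sub_proto, mode = match.arg(mode), ...)
}
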