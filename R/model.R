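## elementary charge expressed in pA*ms (= fC): 1.602e-19 C = 1.602e-4 fC
E0_PA_MS <- 1.602e-4

#' Ground-truth channel-ensemble model
#'
#' Generative parameters for an ensemble of `n_channels` identical,
#' independent two-gate channels.  The activation gate has a Boltzmann
#' steady state `p_inf(V) = p_open_max / (1 + exp((act_v05 - V)/act_k))`
#' and mono-exponential kinetics with time constant `tau_act_ms` (constant
#' or a function of voltage; 0 means instantaneous equilibration).  The
#' inactivation gate relaxes toward
#' `h_inf(V) = i_ss + (1 - i_ss)/(1 + exp((V - inact_v05)/|inact_k|))`
#' with `tau_inact_ms`; `i_ss` is the non-inactivating fraction and setting
#' `i_ss = 1` disables inactivation entirely.  `inact_k` is stored with the
#' negative sign convention used when reporting inactivation slope factors.
#'
#' Conduction is ohmic: the single-channel current is
#' `i(V) = gamma_ps * (V - v_rev) / 1000` pA, zero at the reversal
#' potential.  Gating-charge displacement is modeled as a charge pool
#' `Q(V)` relaxing with `tau_gating_ms` toward
#' `N * q_gating_e0 * e0 * Boltzmann(gating_v05, gating_k)`; the gating
#' current is `dQ/dt`.  Linear leak (`leak_conductance_ns * V`),
#' capacitive edge transients (`cap_amp_pa_per_mv * dV * exp(-t/cap_tau_ms)`)
#' and white Gaussian background noise of standard deviation `noise_sd_pa`
#' (variance `b = noise_sd_pa^2`) complete the measurement model.
#'
#' Calcium-dependent inactivation (CDI) is a rate multiplier
#' `1 + cdi_rate * integral(|I_ionic|) dt` on the inactivation rate,
#' applied only when the simulated charge carrier is Ca; `cdi_rate = 0`
#' disables it.
#'
#' @param n_channels number of channels N (integer >= 1).
#' @param gamma_ps single-channel chord conductance, pS.
#' @param v_rev reversal potential, mV.
#' @param act_v05,act_k activation Boltzmann midpoint and slope, mV (k > 0).
#' @param p_open_max maximal open probability in (0, 1].
#' @param tau_act_ms activation time constant, ms; a constant, 0
#'   (instantaneous), or `function(V)`.
#' @param inact_v05,inact_k inactivation Boltzmann midpoint and slope, mV
#'   (`inact_k < 0` by reporting convention; its magnitude is used).
#' @param i_ss non-inactivating fraction in [0, 1] (1 = no inactivation).
#' @param tau_inact_ms inactivation time constant, ms.
#' @param cdi_rate CDI rate multiplier per unit of integrated |I| (1/(pA*ms)).
#' @param q_gating_e0 gating charge per channel, elementary charges.
#' @param gating_v05,gating_k charge-voltage Boltzmann parameters, mV.
#' @param tau_gating_ms gating-charge relaxation time constant, ms.
#' @param leak_conductance_ns linear leak conductance, nS.
#' @param noise_sd_pa Gaussian background noise SD, pA.
#' @param cap_amp_pa_per_mv,cap_tau_ms capacitive transient amplitude per mV
#'   of step and its decay constant.
#' @param seed default RNG seed for stochastic simulations.
#' @return An object of class `channel_model`.
#' @export
channel_model <- function(n_channels = 1000, gamma_ps = 4.6,
                          v_rev = 60.25, act_v05 = 1.48, act_k = 8.69,
                          p_open_max = 0.8, tau_act_ms = 2,
                          inact_v05 = -16, inact_k = -6.73, i_ss = 0,
                          tau_inact_ms = 500, cdi_rate = 0,
                          q_gating_e0 = 12, gating_v05 = -20, gating_k = 15,
                          tau_gating_ms = 0.3, leak_conductance_ns = 0,
                          noise_sd_pa = 0, cap_amp_pa_per_mv = 0,
                          cap_tau_ms = 0.1, seed = 1L) {
  m <- structure(
    list(n_channels = as.integer(n_channels), gamma_ps = gamma_ps,
         v_rev = v_rev, act_v05 = act_v05, act_k = act_k,
         p_open_max = p_open_max, tau_act_ms = tau_act_ms,
         inact_v05 = inact_v05, inact_k = inact_k, i_ss = i_ss,
         tau_inact_ms = tau_inact_ms, cdi_rate = cdi_rate,
         q_gating_e0 = q_gating_e0, gating_v05 = gating_v05,
         gating_k = gating_k, tau_gating_ms = tau_gating_ms,
         leak_conductance_ns = leak_conductance_ns,
         noise_sd_pa = noise_sd_pa, cap_amp_pa_per_mv = cap_amp_pa_per_mv,
         cap_tau_ms = cap_tau_ms, seed = as.integer(seed)),
    class = "channel_model")
  validate_model(m)
  m
}

validate_model <- function(m) {
  if (!inherits(m, "channel_model")) stop("not a channel_model")
  if (m$n_channels < 1) stop("n_channels must be >= 1")
  if (m$p_open_max <= 0 && m$p_open_max != 0)
    stop("p_open_max must be in [0, 1]")
  if (m$p_open_max > 1 || m$p_open_max < 0) stop("p_open_max must be in [0, 1]")
  if (m$act_k <= 0) stop("act_k must be > 0")
  if (m$i_ss < 0 || m$i_ss > 1) stop("i_ss must be in [0, 1]")
  if (!is.function(m$tau_act_ms) && m$tau_act_ms < 0)
    stop("tau_act_ms must be >= 0")
  if (m$tau_inact_ms <= 0) stop("tau_inact_ms must be > 0")
  if (m$tau_gating_ms <= 0) stop("tau_gating_ms must be > 0")
  if (m$noise_sd_pa < 0) stop("noise_sd_pa must be >= 0")
  invisible(TRUE)
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf("<channel_model> N=%d, gamma=%g pS, Vrev=%g mV\n",
              x$n_channels, x$gamma_ps, x$v_rev))
  cat(sprintf("  act: V05=%g, k=%g, Pomax=%g | inact: V05=%g, k=%g, Iss=%g\n",
              x$act_v05, x$act_k, x$p_open_max, x$inact_v05, x$inact_k,
              x$i_ss))
  invisible(x)
}

#' Model steady states and single-channel current
#'
#' `p_inf` is the steady-state open probability of the activation gate
#' (scaled by `p_open_max`), `h_inf` the steady-state availability of the
#' inactivation gate, and `i_single` the ohmic single-channel current in pA.
#'
#' @param m a `channel_model`.
#' @param v voltage(s), mV.
#' @export
p_inf <- function(m, v) m$p_open_max * stats::plogis((v - m$act_v05) / m$act_k)

#' @rdname p_inf
#' @export
h_inf <- function(m, v)
  m$i_ss + (1 - m$i_ss) * stats::plogis(-(v - m$inact_v05) / abs(m$inact_k))

#' @rdname p_inf
#' @export
i_single <- function(m, v) m$gamma_ps * (v - m$v_rev) / 1000

tau_act_at <- function(m, v) {
  if (is.function(m$tau_act_ms)) m$tau_act_ms(v) else m$tau_act_ms
}

## equilibrium gating charge per cell at voltage v, in pA*ms
q_gating_inf <- function(m, v) {
  m$n_channels * m$q_gating_e0 * E0_PA_MS *
    stats::plogis((v - m$gating_v05) / m$gating_k)
}

#' Preset models
#'
#' `model_wt_ca()` / `model_wt_ba()` are L-type (Cav1.4-like) wild-type
#' parameter sets for 15 mM Ca or Ba charge carrier in HEK-293 cells:
#' activation and inactivation Boltzmanns from whole-cell population means,
#' slow voltage-dependent inactivation, and a high open probability under
#' channel-agonist (BayK8644) conditions.  `apply_bayk()` coarsely models
#' the agonist itself: it raises `p_open_max` and slows gate kinetics by
#' `deact_factor` (longer openings / slower deactivation); no explicit
#' ligand scheme is used.
#'
#' @param ... overrides passed on to [channel_model()].
#' @export
model_wt_ca <- function(...) {
  args <- list(n_channels = 1000, gamma_ps = 4.6, v_rev = 60.25,
               act_v05 = 1.48, act_k = 8.69, p_open_max = 0.8,
               tau_act_ms = 2, inact_v05 = -16, inact_k = -6.73,
               i_ss = 0, tau_inact_ms = 500)
  do.call(channel_model, utils::modifyList(args, list(...)))
}

#' @rdname model_wt_ca
#' @export
model_wt_ba <- function(...) {
  args <- list(n_channels = 1000, gamma_ps = 4.6, v_rev = 43.25,
               act_v05 = -9.67, act_k = 7.74, p_open_max = 0.8,
               tau_act_ms = 2, inact_v05 = -16, inact_k = -6.73,
               i_ss = 0, tau_inact_ms = 500, cdi_rate = 0)
  do.call(channel_model, utils::modifyList(args, list(...)))
}

#' @rdname model_wt_ca
#' @param m a `channel_model`.
#' @param p_open_max agonist-bound maximal open probability.
#' @param deact_factor multiplicative slowing of the activation-gate time
#'   constant (affects deactivation of the tail as well).
#' @export
apply_bayk <- function(m, p_open_max = 0.8, deact_factor = 2) {
  validate_model(m)
  m$p_open_max <- p_open_max
  base_tau <- m$tau_act_ms
  m$tau_act_ms <- if (is.function(base_tau)) {
    function(v) deact_factor * base_tau(v)
  } else deact_factor * base_tau
  m
}
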