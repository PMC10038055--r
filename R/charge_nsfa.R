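#' ON-gating-charge integration
#'
#' Integrates the current over the first `window_ms` (2 ms by default) of a
#' test pulse delivered at the reversal potential, where no net ionic
#' current flows and the integral isolates the gating-charge displacement.
#' Trapezoidal rule; units pA*ms (1 pA*ms = 1 fC).  The per-capacitance
#' density `q_on / C_m` is reported alongside (pA*ms/pF).
#'
#' @param seg a `sweep_segment` starting at the test-pulse onset.
#' @param window_ms integration window from onset, ms.
#' @param capacitance_pf cell capacitance for the density, pF.
#' @return object of class `gating_charge`: `q_on_pa_ms`, `q_on_density`,
#'   `v_used`, `window_ms`.
#' @export
q_on <- function(seg, window_ms = 2, capacitance_pf = NA_real_) {
  stopifnot(inherits(seg, "sweep_segment"))
  rate <- seg$sample_rate_khz
  n_need <- round(window_ms * rate) + 1L
  if (n_need > length(seg$values))
    stop("integration window exceeds the epoch")
  y <- seg$values[seq_len(n_need)]
  dt <- 1 / rate
  q <- sum((y[-1] + y[-length(y)]) / 2) * dt
  structure(list(q_on_pa_ms = q,
                 q_on_density = if (is.finite(capacitance_pf))
                   normalize_density(q, capacitance_pf) else NA_real_,
                 v_used = seg$step_level,
                 window_ms = c(0, window_ms)),
            class = "gating_charge")
}

#' ON-gating charge from a sweep family
#'
#' Selects the sweep whose step level is closest to the (fitted) reversal
#' potential, warning when the mismatch exceeds `tol_mv`, and integrates
#' its first `window_ms`.
#'
#' @param s a `sweep_set`.
#' @param v_rev target reversal potential, mV.
#' @param epoch_index test-pulse epoch (default: first per-sweep epoch).
#' @param window_ms integration window, ms.
#' @param tol_mv warning tolerance on `|step level - v_rev|`.
#' @return a `gating_charge` (see [q_on()]).
#' @export
q_on_at_rev <- function(s, v_rev, epoch_index = NULL, window_ms = 2,
                        tol_mv = 2) {
  validate_sweepset(s)
  if (is.null(epoch_index))
    epoch_index <- which(is.na(s$protocol$epochs$level_mv))[1]
  lev <- s$protocol$sweep_levels
  k <- which.min(abs(lev - v_rev))
  if (abs(lev[k] - v_rev) > tol_mv)
    warning(sprintf("nearest sweep level %g mV is %.2f mV from V_rev",
                    lev[k], abs(lev[k] - v_rev)))
  q_on(segment(s, epoch_index)[[k]], window_ms = window_ms,
       capacitance_pf = s$capacitance_pf)
}

#' Charge-current coupling slope
#'
#' Ordinary least squares of maximal current (density) on ON-gating charge
#' (density) across cells; the slope measures the efficiency of coupling
#' between voltage-sensor charge movement and pore opening.  A
#' zero-intercept variant is reported alongside.
#'
#' @param cells data.frame with `q_on_density` and `i_max_density`
#'   (>= 3 cells).
#' @return list with `slope`, `se`, `intercept`, `slope_zero_intercept`,
#'   `se_zero_intercept`, `n`.
#' @export
q_imax_slope <- function(cells) {
  stopifnot(is.data.frame(cells),
            all(c("q_on_density", "i_max_density") %in% names(cells)))
  if (nrow(cells) < 3) stop("need >= 3 cells")
  if (diff(range(cells$q_on_density)) == 0)
    stop("degenerate: all Q_ON values are equal")
  f <- stats::lm(i_max_density ~ q_on_density, data = cells)
  f0 <- stats::lm(i_max_density ~ q_on_density + 0, data = cells)
  s <- summary(f)$coefficients
  s0 <- summary(f0)$coefficients
  list(slope = s["q_on_density", "Estimate"],
       se = s["q_on_density", "Std. Error"],
       intercept = s["(Intercept)", "Estimate"],
       slope_zero_intercept = s0["q_on_density", "Estimate"],
       se_zero_intercept = s0["q_on_density", "Std. Error"],
       n = nrow(cells))
}

#' Non-stationary fluctuation analysis of tail currents
#'
#' Estimates the single-channel current `i`, channel number `N`, open
#' probability `P0` and background variance `b` from the across-sweep
#' fluctuations of repeated tail currents.  At each sample of the tail the
#' ensemble mean `I(t)` and unbiased variance `sigma^2(t)` are computed;
#' within the analysis window (from just after the peak of the mean tail
#' down to where `|I|` has decayed to `end_frac` of the tail peak) the
#' variance-mean pairs are pooled into equal-count bins and fitted by least
#' squares to the binomial parabola
#' `sigma^2 = i I - I^2 / N + b`.
#' The fit is linear in `(I, I^2)`.  `P0 = I_peak / (i N)`, and the channel
#' surface density uses the 1 uF/cm^2 membrane convention (1 pF = 100 um^2).
#'
#' Signs: inward tails give negative `I` and negative fitted `i`;
#' `i_magnitude` is reported for convenience.
#'
#' @param tails a `sweep_set` of repeated identical tail sweeps (>= 50;
#'   250-500 is the recommended range, warned otherwise).
#' @param epoch_index tail epoch; defaults to the protocol's `tail_epoch`
#'   attribute.
#' @param start_offset_ms analysis start offset after the mean-tail peak,
#'   ms.
#' @param end_frac analysis end when `|I|` decays to this fraction of the
#'   tail peak.
#' @param n_bins equal-count bins for the parabola fit (no binning when the
#'   window holds fewer than `2 * n_bins` samples).
#' @param var_estimator "across" for the plain unbiased across-sweep
#'   variance, "successive" for the pairwise successive-difference
#'   estimator (robust to slow rundown).
#' @param weighting "none" (default; reproducible plain least squares) or
#'   "variance" for iteratively reweighted least squares with weights
#'   `1/sigma_fit^4`, the theoretical sampling variance of a sample
#'   variance.
#' @param min_sweeps hard floor on the sweep count.
#' @return object of class `nsfa_fit`: `i`, `i_magnitude`, `n_channels`,
#'   `b`, `p_open`, `channel_density_um2`, `mean_curve` (data.frame
#'   `t_ms`, `i_mean`, `variance`, `in_window`), `binned` (data.frame),
#'   `n_sweeps_used`, diagnostics.
#' @export
nsfa <- function(tails, epoch_index = NULL, start_offset_ms = 0.1,
                 end_frac = 0.05, n_bins = 50,
                 var_estimator = c("across", "successive"),
                 weighting = c("none", "variance"),
                 min_sweeps = 50) {
  validate_sweepset(tails)
  var_estimator <- match.arg(var_estimator)
  weighting <- match.arg(weighting)
  n_sw <- nrow(tails$sweeps)
  if (n_sw < min_sweeps)
    stop("NSFA needs at least ", min_sweeps, " sweeps; got ", n_sw)
  if (n_sw < 250 || n_sw > 500)
    warning("sweep count ", n_sw, " outside the recommended 250-500 range")
  if (is.null(epoch_index)) epoch_index <- attr(tails$protocol, "tail_epoch")
  if (is.null(epoch_index)) stop("no tail epoch; give epoch_index")
  idx <- epoch_sample_idx(tails$protocol, epoch_index)
  rate <- tails$protocol$sample_rate_khz
  m <- tails$sweeps[, idx, drop = FALSE]
  mu <- colMeans(m)
  v <- if (var_estimator == "across") {
    apply(m, 2, stats::var)
  } else {
    d <- diff(m) / sqrt(2)                     # successive sweep differences
    colSums(d^2) / (n_sw - 1)
  }
  ip <- which.max(abs(mu))
  i_peak <- mu[ip]
  start <- ip + max(1L, round(start_offset_ms * rate))
  if (start >= length(mu)) stop("analysis window empty: tail too short")
  below <- which(abs(mu) < end_frac * abs(i_peak))
  below <- below[below > start]
  end <- if (length(below)) below[1] - 1L else length(mu)
  win <- start:end
  if (length(win) < 8) stop("analysis window too short for the parabola fit")
  if (max(v[win]) < 1e-12)
    stop("variance is zero across the analysis window; NSFA requires ",
         "stochastic sweeps")

  core <- nsfa_parabola(mu[win], v[win], n_bins = n_bins,
                        weighting = weighting)
  i_hat <- core$i
  n_hat <- core$n_channels
  b_hat <- core$b
  Ib <- core$binned$i_mean
  Sb <- core$binned$variance
  p0 <- i_peak / (i_hat * n_hat)
  dens <- if (is.finite(tails$capacitance_pf))
    n_hat / (tails$capacitance_pf * 100) else NA_real_

  structure(
    list(i = i_hat, i_magnitude = abs(i_hat), n_channels = n_hat,
         b = b_hat, p_open = p0, channel_density_um2 = dens,
         i_tail_peak = i_peak,
         mean_curve = data.frame(t_ms = (idx[seq_along(mu)] - idx[1]) / rate,
                                 i_mean = mu, variance = v,
                                 in_window = seq_along(mu) %in% win),
         binned = data.frame(i_mean = as.numeric(Ib),
                             variance = as.numeric(Sb)),
         n_sweeps_used = n_sw, var_estimator = var_estimator,
         weighting = weighting,
         start_offset_ms = start_offset_ms, end_frac = end_frac,
         ssr = core$ssr),
    class = "nsfa_fit")
}

#' Core variance-mean parabola fit
#'
#' Fits `sigma^2 = i I - I^2/N + b` (linear in `I` and `I^2`) to a
#' variance-mean curve.  Used internally by [nsfa()]; exposed so that
#' analytic expectation curves can be fitted directly.
#'
#' @param i_mean mean-current values, pA.
#' @param variance across-sweep variances, pA^2.
#' @param n_bins equal-count bins (0 or fewer points than `2 * n_bins`
#'   disables binning).
#' @param weighting see [nsfa()].
#' @return object of class `nsfa_fit` with `i`, `i_magnitude`,
#'   `n_channels`, `b`, `binned`, `ssr` (tail-dependent fields are `NA`).
#' @export
nsfa_parabola <- function(i_mean, variance, n_bins = 0,
                          weighting = c("none", "variance")) {
  weighting <- match.arg(weighting)
  stopifnot(length(i_mean) == length(variance))
  I <- i_mean
  S <- variance
  if (n_bins > 0 && length(I) >= 2 * n_bins) {
    ord <- order(I)
    grp <- cut(seq_along(ord), breaks = n_bins, labels = FALSE)
    Ib <- as.numeric(tapply(I[ord], grp, mean))
    Sb <- as.numeric(tapply(S[ord], grp, mean))
  } else {
    Ib <- I; Sb <- S
  }
  dat <- data.frame(Ib = Ib, Sb = Sb, I2 = Ib^2)
  fit <- stats::lm(Sb ~ Ib + I2, data = dat)
  if (weighting == "variance") {
    for (it in 1:3) {
      w <- 1 / pmax(abs(stats::fitted(fit)), 1e-9)^2
      fit <- stats::lm(Sb ~ Ib + I2, data = dat, weights = w)
    }
  }
  cf <- stats::coef(fit)
  if (!is.finite(cf["I2"]) || cf["I2"] >= 0)
    stop("variance not saturating (parabola opens upward); cannot ",
         "estimate channel number")
  structure(
    list(i = unname(cf["Ib"]), i_magnitude = abs(unname(cf["Ib"])),
         n_channels = -1 / unname(cf["I2"]),
         b = unname(cf["(Intercept)"]),
         p_open = NA_real_, channel_density_um2 = NA_real_,
         i_tail_peak = NA_real_,
         binned = data.frame(i_mean = Ib, variance = Sb),
         n_sweeps_used = NA_integer_, var_estimator = "analytic",
         weighting = weighting, ssr = sum(stats::residuals(fit)^2)),
    class = "nsfa_fit")
}

#' @export
print.nsfa_fit <- function(x, ...) {
  cat(sprintf("<nsfa_fit> i = %.3g pA, N = %.4g, P0 = %.3g, b = %.3g pA^2\n",
              x$i, x$n_channels, x$p_open, x$b))
  cat(sprintf("  density = %.3g channels/um^2 (%d sweeps, %s variance)\n",
              x$channel_density_um2, x$n_sweeps_used, x$var_estimator))
  invisible(x)
}

#' Consistency check on the fitted variance-mean parabola
#'
#' The derivative of the parabola, `d sigma^2 / d I = i - 2 I / N`, equals
#' the single-channel current at `I -> 0` and crosses zero at `I = i N / 2`
#' (the variance maximum).  The finite-difference derivative of the binned
#' data is compared against this line; discrepancies beyond
#' `tol_frac * |i|` (median absolute) flag heteroscedastic or non-binomial
#' noise.
#'
#' @param fit an `nsfa_fit`.
#' @param tol_frac tolerance on the median absolute derivative discrepancy,
#'   as a fraction of `|i|`.
#' @return list with `i_at_zero`, `root_I` (= iN/2), `fd_discrepancy`
#'   (median absolute), `flagged`, and the per-interval table.
#' @export
nsfa_derivative_check <- function(fit, tol_frac = 0.25) {
  stopifnot(inherits(fit, "nsfa_fit"))
  b <- fit$binned[order(fit$binned$i_mean), ]
  dI <- diff(b$i_mean)
  keep <- abs(dI) > 1e-12
  fd <- diff(b$variance)[keep] / dI[keep]
  Imid <- ((b$i_mean[-1] + b$i_mean[-nrow(b)]) / 2)[keep]
  pred <- fit$i - 2 * Imid / fit$n_channels
  disc <- stats::median(abs(fd - pred))
  list(i_at_zero = fit$i,
       root_I = fit$i * fit$n_channels / 2,
       fd_discrepancy = disc,
       flagged = disc > tol_frac * abs(fit$i),
       table = data.frame(i_mid = Imid, fd_deriv = fd, model_deriv = pred))
}
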