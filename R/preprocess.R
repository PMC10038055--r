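#' P/4 leak subtraction
#'
#' Classical P/4 correction: four sub-sweeps with quarter-amplitude voltage
#' excursions are baseline-corrected on the pre-step holding epoch, summed,
#' and subtracted from the baseline-corrected test sweep.  Any current
#' component affine in voltage (ohmic leak and capacitive transients, whose
#' amplitudes scale linearly with the step) is annihilated exactly.
#'
#' @param test a `sweep_set` of test sweeps.
#' @param subpulses a `sweep_set` holding `n_sub` sub-sweeps per test sweep
#'   (grouped consecutively), same sample count and rate; see
#'   [simulate_p4_family()].
#' @param n_sub sub-sweeps per test sweep (4 for P/4).
#' @param baseline_epoch epoch used for baseline estimation (default 1,
#'   the pre-step holding epoch).
#' @return a `sweep_set` with `leak_subtracted = "p4"`.
#' @export
p4_subtract <- function(test, subpulses, n_sub = 4, baseline_epoch = 1L) {
  validate_sweepset(test)
  validate_sweepset(subpulses)
  if (ncol(subpulses$sweeps) != ncol(test$sweeps))
    stop("alignment error: sub-pulse sample count differs from test sweeps")
  if (nrow(subpulses$sweeps) != n_sub * nrow(test$sweeps))
    stop("alignment error: expected ", n_sub, " sub-sweeps per test sweep (",
         n_sub * nrow(test$sweeps), "), got ", nrow(subpulses$sweeps))
  if (abs(subpulses$protocol$sample_rate_khz -
          test$protocol$sample_rate_khz) > 1e-9)
    stop("alignment error: sample rates differ")

  bidx <- epoch_sample_idx(test$protocol, baseline_epoch)
  out <- test$sweeps
  for (k in seq_len(nrow(test$sweeps))) {
    rows <- (k - 1L) * n_sub + seq_len(n_sub)
    subs <- subpulses$sweeps[rows, , drop = FALSE]
    subs <- subs - rowMeans(subs[, bidx, drop = FALSE])
    templ <- colSums(subs)
    out[k, ] <- test$sweeps[k, ] - mean(test$sweeps[k, bidx]) - templ
  }
  warn_residual_leak(out, test$protocol)
  res <- test
  res$sweeps <- out
  res$leak_subtracted <- "p4"
  res
}

epoch_sample_idx <- function(p, e) {
  if (e < 1 || e > nrow(p$epochs)) stop("epoch index out of range: ", e)
  epoch_starts(p)[e] + seq_len(epoch_samples(p)[e])
}

## heuristic residual-leak screen: if the late-step steady current is an
## almost perfect linear function of the step amplitude across sweeps, the
## remaining current is ohmic (sub-pulse scaling was probably wrong)
warn_residual_leak <- function(sweeps, p) {
  step_epoch <- which(is.na(p$epochs$level_mv))[1]
  if (is.na(step_epoch) || nrow(sweeps) < 4) return(invisible(NULL))
  idx <- epoch_sample_idx(p, step_epoch)
  late <- idx[idx > idx[1] + 0.8 * length(idx)]
  r <- rowMeans(sweeps[, late, drop = FALSE])
  dv <- p$sweep_levels - p$holding_mv
  if (length(unique(dv)) < 3 || max(abs(r)) < 1e-9) return(invisible(NULL))
  fit <- stats::lm.fit(cbind(1, dv), r)
  ssr <- sum(fit$residuals^2)
  sst <- sum((r - mean(r))^2)
  if (sst > 0 && (1 - ssr / sst) > 0.999 && abs(fit$coefficients[2]) > 1e-6)
    warning(sprintf(paste0("residual ohmic leak after subtraction ",
                           "(~%.3g nS); check sub-pulse scaling"),
                    fit$coefficients[2]))
  invisible(NULL)
}

#' Offline linear leak subtraction
#'
#' Fits `I_leak = g*V + c` by least squares to the mean currents of
#' holding and sub-threshold step segments (where the channels are closed)
#' and subtracts `g*V(t) + c` sample-wise using the protocol's command
#' voltage.
#'
#' @param s a `sweep_set`.
#' @param subthreshold_max_mv steps at or below this potential are treated
#'   as channel-free and used for the fit (at least 2 required).
#' @param step_epoch epoch index of the test step (default: first
#'   per-sweep-level epoch).
#' @return a `sweep_set` with `leak_subtracted = "offline"`; fitted `g`
#'   (nS) and `c` (pA) are stored in `annotations$leak_fit`.
#' @export
offline_leak_subtract <- function(s, subthreshold_max_mv = -60,
                                  step_epoch = NULL) {
  validate_sweepset(s)
  p <- s$protocol
  if (is.null(step_epoch)) step_epoch <- which(is.na(p$epochs$level_mv))[1]
  if (is.na(step_epoch)) stop("no per-sweep step epoch in protocol")
  sub <- which(p$sweep_levels <= subthreshold_max_mv)
  if (length(sub) < 2)
    stop("need >= 2 sub-threshold levels at or below ", subthreshold_max_mv,
         " mV for the leak fit")
  idx <- epoch_sample_idx(p, step_epoch)
  late <- idx[idx > idx[1] + 0.5 * length(idx)]
  hidx <- epoch_sample_idx(p, 1L)
  vs <- c(p$sweep_levels[sub], rep(p$holding_mv, length(sub)))
  is <- c(rowMeans(s$sweeps[sub, late, drop = FALSE]),
          rowMeans(s$sweeps[sub, hidx, drop = FALSE]))
  fit <- stats::lm.fit(cbind(1, vs), is)
  cc <- fit$coefficients[1]
  g <- fit$coefficients[2]
  if (max(abs(fit$residuals)) > 0.05 * max(diff(range(is)), 1e-12))
    warning("leak fit residuals are large; activation may contaminate the ",
            "sub-threshold window")
  out <- s$sweeps
  for (k in seq_len(nrow(out)))
    out[k, ] <- out[k, ] - (g * voltage_trace(p, k) + cc)
  res <- s
  res$sweeps <- out
  res$leak_subtracted <- "offline"
  res$annotations$leak_fit <- sprintf("g_ns=%.8e;c_pa=%.8e", g, cc)
  attr(res, "leak_g_ns") <- unname(g)
  attr(res, "leak_c_pa") <- unname(cc)
  res
}

#' Zero-phase low-pass smoothing
#'
#' Gaussian FIR smoothing with the kernel width chosen so the -3 dB point
#' sits at `cutoff_khz`; symmetric (zero-phase, no ringing), a practical
#' stand-in for the Bessel response of acquisition hardware.  Edges use
#' reflection padding.
#'
#' @param s a `sweep_set`.
#' @param cutoff_khz -3 dB cutoff in kHz (presets: 2 or 10).
#' @return a filtered `sweep_set` with `filter_cutoff_khz` set.
#' @export
lowpass_filter <- function(s, cutoff_khz = 2) {
  validate_sweepset(s)
  if (cutoff_khz <= 0) stop("cutoff_khz must be > 0")
  rate <- s$protocol$sample_rate_khz
  sigma_ms <- sqrt(log(2)) / (2 * pi * cutoff_khz)
  sigma_samp <- sigma_ms * rate
  half <- max(1L, ceiling(4 * sigma_samp))
  x <- (-half):half
  kern <- exp(-x^2 / (2 * sigma_samp^2))
  kern <- kern / sum(kern)
  n <- ncol(s$sweeps)
  pad <- function(v) c(rev(v[seq_len(half) + 1L]), v,
                       rev(v[n - seq_len(half)]))
  out <- t(apply(s$sweeps, 1, function(v)
    stats::filter(pad(v), kern, sides = 2)[half + seq_len(n)]))
  res <- s
  res$sweeps <- out
  res$filter_cutoff_khz <- cutoff_khz
  res
}

#' Peak and steady-state current of each sweep
#'
#' The peak is the extremum of largest absolute amplitude within the epoch
#' (signed; inward peaks are negative, sweeps beyond the reversal potential
#' yield positive peaks), searched after a blanking window that skips the
#' capacitive spike at step onset.  `steady` is the mean over the terminal
#' `steady_window_ms` of the epoch.
#'
#' @param s a `sweep_set` (leak-subtracted input recommended; a warning is
#'   issued otherwise).
#' @param epoch_index epoch to analyze (default: first per-sweep epoch).
#' @param steady_window_ms terminal averaging window, ms.
#' @param blank_ms onset blanking, ms (default 0.2).
#' @return data.frame with `sweep_index`, `step_level`, `peak_pa`,
#'   `time_to_peak_ms` (from epoch onset), `steady_pa`.
#' @export
measure_peaks <- function(s, epoch_index = NULL, steady_window_ms = 5,
                          blank_ms = 0.2) {
  validate_sweepset(s)
  p <- s$protocol
  if (is.null(epoch_index)) epoch_index <- which(is.na(p$epochs$level_mv))[1]
  if (is.na(epoch_index)) stop("no per-sweep step epoch; give epoch_index")
  if (s$leak_subtracted == "none")
    warning("input is not leak-subtracted; peaks include leak current")
  segs <- segment(s, epoch_index)
  rate <- p$sample_rate_khz
  res <- lapply(segs, function(sg) {
    v <- sg$values
    if (length(v) == 0) stop("empty epoch")
    skip <- min(length(v) - 1L, ms_to_sample(blank_ms, rate))
    vv <- v[(skip + 1L):length(v)]
    if (all(vv == 0)) {
      warning("all-zero sweep ", sg$sweep_index, "; peak undefined")
      ip <- 1L
    } else ip <- which.max(abs(vv))
    nw <- max(1L, round(steady_window_ms * rate))
    data.frame(sweep_index = sg$sweep_index,
               step_level = sg$step_level,
               peak_pa = vv[ip],
               time_to_peak_ms = (skip + ip - 1L) / rate,
               steady_pa = mean(v[(length(v) - nw + 1L):length(v)]))
  })
  do.call(rbind, res)
}

#' Current-density normalization
#'
#' @param value_pa current in pA.
#' @param capacitance_pf cell capacitance in pF (> 0).
#' @return current density in pA/pF.
#' @export
normalize_density <- function(value_pa, capacitance_pf) {
  if (!is.finite(capacitance_pf) || capacitance_pf <= 0)
    stop("capacitance must be > 0 for density normalization")
  value_pa / capacitance_pf
}
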