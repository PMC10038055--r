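#' Availability from a steady-state inactivation family
#'
#' For each sweep of a [simulate_ssi_family()]-shaped recording, channel
#' availability is the ratio of the post-conditioning test-pulse peak to
#' the pre-conditioning reference peak of the same sweep (which cancels
#' slow rundown).
#'
#' @param s a `sweep_set` whose protocol carries `pre_test_epoch` /
#'   `post_test_epoch` attributes (as built by [protocol_ssi()]).
#' @param blank_ms onset blanking for the peak search, ms.
#' @return data.frame with `v_cond` and `availability`.
#' @export
ssi_availability <- function(s, blank_ms = 0.2) {
  validate_sweepset(s)
  pre_e <- attr(s$protocol, "pre_test_epoch")
  post_e <- attr(s$protocol, "post_test_epoch")
  if (is.null(pre_e) || is.null(post_e))
    stop("protocol lacks pre/post test-pulse epochs (not an SSI family?)")
  pre <- measure_peaks(s, pre_e, blank_ms = blank_ms)
  post <- measure_peaks(s, post_e, blank_ms = blank_ms)
  data.frame(v_cond = s$protocol$sweep_levels,
             availability = post$peak_pa / pre$peak_pa)
}

#' Fit the steady-state inactivation Boltzmann
#'
#' Least-squares fit of
#' `I = I_ss + (1 - I_ss) / (1 + exp((V - V_0.5,inact)/k))`
#' to availability-versus-conditioning-voltage data, where `I_ss` is the
#' non-inactivating fraction.  The slope factor is fitted as a positive
#' magnitude (the curve falls with depolarization) and reported as
#' `k_inact = -|k|`, the negative sign convention used for inactivation
#' slopes.
#'
#' @param points data.frame with `v_cond` (mV) and `availability` in
#'   `[-0.05, 1.1]`; at least 5 conditioning levels.
#' @return object of class `ssi_fit` with `v05_inact`, `k_inact` (< 0),
#'   `i_ss`, `residuals`, `ssr`, `converged`, `points`.
#' @export
fit_ssi <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("v_cond", "availability") %in% names(points)))
  pts <- points[order(points$v_cond), ]
  if (nrow(pts) < 5) stop("need >= 5 conditioning levels")
  a <- pts$availability
  if (any(a < -0.05 | a > 1.1))
    stop("availability outside [-0.05, 1.1]: check sign/normalization")
  if (diff(range(a)) < 0.05)
    stop("no inactivation detected: availability is constant")

  iss0 <- max(min(a), 0)
  mid <- (1 + iss0) / 2
  j <- which(a <= mid)[1]
  v05_0 <- if (is.na(j) || j == 1) mean(range(pts$v_cond)) else
    pts$v_cond[j - 1] + (a[j - 1] - mid) * (pts$v_cond[j] - pts$v_cond[j - 1]) /
      (a[j - 1] - a[j])
  fit <- stats::nls(
    availability ~ iss + (1 - iss) / (1 + exp((v_cond - v05) / kmag)),
    data = pts,
    start = list(iss = min(max(iss0, 1e-3), 0.9), v05 = v05_0, kmag = 6),
    algorithm = "port",
    lower = c(iss = 0, v05 = -150, kmag = 0.5),
    upper = c(iss = 1, v05 = 100, kmag = 60),
    control = stats::nls.control(maxiter = 500, tol = 1e-12,
                                 minFactor = 1e-12))
  cf <- stats::coef(fit)
  structure(
    list(v05_inact = unname(cf["v05"]), k_inact = -unname(cf["kmag"]),
         i_ss = unname(cf["iss"]),
         residuals = unname(stats::residuals(fit)),
         ssr = sum(stats::residuals(fit)^2),
         converged = fit$convInfo$isConv, points = pts,
         predict = function(v) cf["iss"] + (1 - cf["iss"]) /
           (1 + exp((v - cf["v05"]) / cf["kmag"]))),
    class = "ssi_fit")
}

#' @export
print.ssi_fit <- function(x, ...) {
  cat(sprintf("<ssi_fit> V0.5,inact = %.4g mV, k_inact = %.4g mV, Iss = %.4g\n",
              x$v05_inact, x$k_inact, x$i_ss))
  invisible(x)
}

#' Residual-current ratios (r250 and friends)
#'
#' `r_ratio` is the current remaining a fixed time after step onset,
#' normalized to the peak of the step: `I(at_ms)/I_peak` with the sample
#' nearest `at_ms` (ties toward earlier).  `at_ms = 250` on a 300-ms pulse
#' gives the classical r250 inactivation metric; `residual_after` is the
#' same quantity for long pulses (default 5 s).  The ratio is invariant to
#' uniform gain and is flagged `NA` when the peak is below `noise_floor_pa`.
#'
#' @param seg a `sweep_segment` covering the pulse.
#' @param at_ms evaluation time from step onset, ms.
#' @param blank_ms onset blanking for the peak search, ms.
#' @param noise_floor_pa undefined-ratio guard on `|peak|`.
#' @return unitless ratio (NA with a warning when undefined).
#' @export
r_ratio <- function(seg, at_ms = 250, blank_ms = 0.2, noise_floor_pa = 0) {
  stopifnot(inherits(seg, "sweep_segment"))
  rate <- seg$sample_rate_khz
  n <- length(seg$values)
  if (at_ms > n / rate) stop("segment shorter than at_ms")
  skip <- min(n - 1L, ms_to_sample(blank_ms, rate))
  vv <- seg$values[(skip + 1L):n]
  pk <- vv[which.max(abs(vv))]
  if (abs(pk) <= noise_floor_pa || pk == 0) {
    warning("peak below noise floor; residual ratio undefined")
    return(NA_real_)
  }
  idx <- min(n, ms_to_sample(at_ms, rate) + 1L)
  seg$values[idx] / pk
}

#' @rdname r_ratio
#' @param t_ms evaluation time for the long-pulse residual, ms.
#' @export
residual_after <- function(seg, t_ms = 5000, blank_ms = 0.2,
                           noise_floor_pa = 0) {
  r_ratio(seg, at_ms = t_ms, blank_ms = blank_ms,
          noise_floor_pa = noise_floor_pa)
}

#' Calcium-dependent inactivation index
#'
#' Quantifies CDI as the difference in r250 between matched Ba and Ca
#' recordings of the same construct: `r250(Ba) - r250(Ca)` at each matched
#' step level.  A positive index means faster inactivation with Ca, i.e.
#' CDI is present; identical inputs give exactly zero.
#'
#' @param ca_metrics,ba_metrics data.frames with `step_level` and `r250`.
#' @return data.frame with `step_level` and `cdi_index`.
#' @export
cdi_index <- function(ca_metrics, ba_metrics) {
  stopifnot(is.data.frame(ca_metrics), is.data.frame(ba_metrics),
            all(c("step_level", "r250") %in% names(ca_metrics)),
            all(c("step_level", "r250") %in% names(ba_metrics)))
  ca <- ca_metrics[order(ca_metrics$step_level), ]
  ba <- ba_metrics[order(ba_metrics$step_level), ]
  if (nrow(ca) != nrow(ba) ||
      any(abs(ca$step_level - ba$step_level) > 1e-9))
    stop("step levels of Ca and Ba metrics do not match")
  data.frame(step_level = ca$step_level,
             cdi_index = ba$r250 - ca$r250)
}

#' r250 table for a step family
#'
#' Convenience wrapper: computes `r250` for every sweep of a 300-ms step
#' family.
#'
#' @param s a `sweep_set`.
#' @param epoch_index pulse epoch (default: first per-sweep epoch).
#' @param at_ms evaluation time, ms.
#' @param ... passed to [r_ratio()].
#' @return data.frame with `step_level` and `r250`.
#' @export
r250_table <- function(s, epoch_index = NULL, at_ms = 250, ...) {
  validate_sweepset(s)
  if (is.null(epoch_index))
    epoch_index <- which(is.na(s$protocol$epochs$level_mv))[1]
  segs <- segment(s, epoch_index)
  data.frame(
    step_level = vapply(segs, function(x) x$step_level, 0),
    r250 = vapply(segs, function(x) r_ratio(x, at_ms = at_ms, ...), 0))
}
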