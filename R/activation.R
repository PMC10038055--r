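#' Fit the current-voltage relationship
#'
#' Nonlinear least squares of the standard linear-driving-force Boltzmann
#' I-V curve
#' `I = G_max (V - V_rev) / (1 + exp((V_0.5 - V)/k))`,
#' where `I` is the peak current (pA, or pA/pF for densities), `G_max` the
#' maximum slope conductance (nS, or nS/pF), `V_rev` the extrapolated
#' reversal potential, `V_0.5` the half-maximal activation voltage and `k`
#' the slope factor.
#'
#' Initialization is deterministic: `V_rev` from the highest-voltage sign
#' change (linear interpolation), `V_0.5` from the half-amplitude crossing
#' of the hyperpolarized flank, `k = 8`, `G_max` from the I-V slope above
#' the peak; five jittered restarts (fixed internal seed) are run and the
#' lowest SSR wins.
#'
#' Derived quantities: `v_max` is the measured grid level of largest
#' absolute current (ties resolved toward the more hyperpolarized level),
#' `v_max_continuous` the argmax of the fitted curve, and `act_thresh` the
#' voltage on the hyperpolarized flank where the fitted curve reaches 5% of
#' its continuous peak amplitude, found by bisection to 0.001 mV.
#'
#' @param points data.frame with columns `v` (mV) and `i` (peak current,
#'   pA or pA/pF); at least 6 distinct voltages spanning both sides of the
#'   current peak.
#' @param thresh_frac threshold fraction for `act_thresh` (default 0.05).
#' @return An object of class `iv_fit` with fields `g_max`, `v05_act`,
#'   `k_act`, `v_rev`, `v_max`, `v_max_continuous`, `act_thresh`, `cd_max`,
#'   `residuals`, `ssr`, `iterations`, `converged`, `points`.
#' @export
fit_iv <- function(points, thresh_frac = 0.05) {
  stopifnot(is.data.frame(points), all(c("v", "i") %in% names(points)))
  pts <- points[order(points$v), c("v", "i")]
  if (length(unique(pts$v)) < 6)
    stop("need >= 6 distinct voltages for the I-V fit")
  if (all(pts$i == 0)) stop("all currents are zero: no peak to fit")
  imax_idx <- which.max(abs(pts$i))
  if (imax_idx == 1L || imax_idx == nrow(pts))
    stop("no interior current peak (monotone I-V data); cannot fit")

  iv_f <- function(v, g, v05, k, vr) g * (v - vr) / (1 + exp((v05 - v) / k))
  start <- iv_start_values(pts, imax_idx)
  starts <- iv_jittered_starts(start)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::nls(i ~ g * (v - vr) / (1 + exp((v05 - v) / k)),
                 data = pts, start = st, algorithm = "port",
                 lower = c(g = -Inf, v05 = -200, k = 1e-3, vr = -200),
                 upper = c(g = Inf, v05 = 200, k = 100, vr = 300),
                 control = stats::nls.control(maxiter = 500, tol = 1e-12,
                                              minFactor = 1e-12,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(stats::residuals(fit)^2)
    if (is.null(best) || ssr < best$ssr)
      best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best))
    stop("I-V fit did not converge from any start; data may not follow a ",
         "Boltzmann-shaped I-V")
  cf <- stats::coef(best$fit)
  g <- unname(cf["g"]); v05 <- unname(cf["v05"])
  k <- unname(cf["k"]); vr <- unname(cf["vr"])

  vmax_grid <- pts$v[which.max(abs(pts$i))]
  opt <- stats::optimize(function(v) abs(iv_f(v, g, v05, k, vr)),
                         range(pts$v), maximum = TRUE, tol = 1e-6)
  vmax_cont <- opt$maximum
  peak_amp <- opt$objective
  thr <- act_threshold_bisect(function(v) abs(iv_f(v, g, v05, k, vr)),
                              vmax_cont, thresh_frac * peak_amp,
                              lo = min(pts$v) - 60)
  structure(
    list(g_max = g, v05_act = v05, k_act = k, v_rev = vr,
         v_max = vmax_grid, v_max_continuous = vmax_cont,
         act_thresh = thr, cd_max = max(abs(pts$i)),
         residuals = unname(stats::residuals(best$fit)), ssr = best$ssr,
         iterations = best$fit$convInfo$finIter,
         converged = best$fit$convInfo$isConv,
         points = pts,
         predict = function(v) iv_f(v, g, v05, k, vr)),
    class = "iv_fit")
}

iv_start_values <- function(pts, imax_idx) {
  v <- pts$v; i <- pts$i
  ## reversal: highest-voltage sign change, linearly interpolated
  vr <- max(v) + 10
  for (j in rev(seq_len(length(v) - 1))) {
    if (i[j] != 0 && i[j + 1] != 0 && sign(i[j]) != sign(i[j + 1])) {
      vr <- v[j] - i[j] * (v[j + 1] - v[j]) / (i[j + 1] - i[j])
      break
    }
  }
  ## half-maximal |I| crossing on the hyperpolarized flank
  half <- abs(i[imax_idx]) / 2
  v05 <- v[imax_idx] - 10
  for (j in seq_len(imax_idx - 1)) {
    if (abs(i[j]) <= half && abs(i[j + 1]) > half) {
      v05 <- v[j] + (half - abs(i[j])) * (v[j + 1] - v[j]) /
        (abs(i[j + 1]) - abs(i[j]))
      break
    }
  }
  above <- pts[pts$v >= pts$v[imax_idx], ]
  g <- if (nrow(above) >= 2)
    unname(stats::coef(stats::lm(i ~ v, above))[2]) else
      abs(i[imax_idx]) / max(abs(v[imax_idx] - vr), 1)
  list(g = g, v05 = v05, k = 8, vr = vr)
}

iv_jittered_starts <- function(start) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(177013L)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  starts <- list(start)
  for (r in seq_len(4)) {
    st <- start
    st$g <- st$g * stats::runif(1, 0.7, 1.4)
    st$v05 <- st$v05 + stats::runif(1, -5, 5)
    st$k <- st$k * stats::runif(1, 0.6, 1.6)
    st$vr <- st$vr + stats::runif(1, -4, 4)
    starts[[r + 1]] <- st
  }
  starts
}

## bisection for |I_fit(V)| = target on the hyperpolarized flank
act_threshold_bisect <- function(absf, vmax_cont, target, lo, tol = 1e-3) {
  hi <- vmax_cont
  while (absf(lo) > target && lo > -300) lo <- lo - 20
  if (absf(lo) > target) stop("activation threshold bracket not found")
  while (hi - lo > tol) {
    mid <- (hi + lo) / 2
    if (absf(mid) < target) lo <- mid else hi <- mid
  }
  (hi + lo) / 2
}

#' @export
print.iv_fit <- function(x, ...) {
  cat("<iv_fit>\n")
  cat(sprintf("  G_max = %.4g, V0.5,act = %.4g mV, k = %.4g mV, Vrev = %.4g mV\n",
              x$g_max, x$v05_act, x$k_act, x$v_rev))
  cat(sprintf("  Vmax = %g mV (cont. %.2f), act thresh = %.2f mV, SSR = %.3g\n",
              x$v_max, x$v_max_continuous, x$act_thresh, x$ssr))
  invisible(x)
}

#' Conductance-voltage (activation) curve
#'
#' Chord conductance at each voltage step, `G(V) = I * 1000 / (V - V_rev)`
#' (pA/mV -> pS; positive for a conducting channel), normalized to its
#' maximum.  Points at the reversal potential are excluded with a warning.
#'
#' @param fit an `iv_fit` (supplies `V_rev`).
#' @param points data.frame with `v`, `i`; defaults to the fitted points.
#' @param tol_mv exclusion tolerance around `V_rev`.
#' @return data.frame with `v`, `g_ps`, `g_norm`.
#' @export
gv_curve <- function(fit, points = fit$points, tol_mv = 1e-6) {
  stopifnot(inherits(fit, "iv_fit"))
  keep <- abs(points$v - fit$v_rev) > tol_mv
  if (any(!keep))
    warning(sum(!keep), " point(s) at the reversal potential excluded")
  pts <- points[keep, ]
  g <- pts$i * 1000 / (pts$v - fit$v_rev)
  data.frame(v = pts$v, g_ps = g, g_norm = g / max(g))
}

#' Activation kinetics of one sweep
#'
#' Fits the rising phase (onset blanking to the current peak) with a
#' mono-exponential `I(t) = A (1 - exp(-t/tau)) + C`; a bi-exponential
#' alternative is fitted as well and selected only when favored by the
#' corrected Akaike criterion (delta AICc > 2), mirroring the practice of
#' reporting mono-exponential time constants and flagging traces where the
#' bi-exponential wins.
#'
#' @param seg a `sweep_segment` covering the depolarizing step.
#' @param blank_ms onset blanking, ms.
#' @return list with `step_level`, `tau_ms`, `time_to_peak_ms`, `model`
#'   ("mono" or "bi"), `tau2_ms` (bi only), `delta_aicc`, `ssr`.
#' @export
fit_activation_kinetics <- function(seg, blank_ms = 0.2) {
  stopifnot(inherits(seg, "sweep_segment"))
  v <- seg$values
  if (diff(range(v)) == 0) stop("flat trace: no rising phase to fit")
  rate <- seg$sample_rate_khz
  skip <- ms_to_sample(blank_ms, rate)
  if (skip >= length(v) - 4) stop("blanking window leaves no data")
  vv <- v[(skip + 1L):length(v)]
  ip <- which.max(abs(vv))
  if (ip < 5) stop("current peak falls within the blanking window")
  y <- vv[seq_len(ip)]
  t <- (seq_len(ip) - 1L) / rate
  dat <- data.frame(t = t, y = y)

  amp <- y[ip] - y[1]
  i63 <- which(abs(y - y[1]) >= 0.632 * abs(amp))[1]
  tau0 <- max(t[i63], 1.5 / rate)
  mono <- tryCatch(
    stats::nls(y ~ A * (1 - exp(-t / tau)) + C, data = dat,
               start = list(A = amp, tau = tau0, C = y[1]),
               algorithm = "port", lower = c(A = -Inf, tau = 1e-4, C = -Inf),
               control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                            warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(mono)) stop("mono-exponential fit failed on the rising phase")
  ssr_m <- sum(stats::residuals(mono)^2)
  cf_m <- stats::coef(mono)

  ## candidate model probe; convergence failures here just mean "no better
  ## than mono", so its warnings are silenced
  bi <- tryCatch(suppressWarnings(
    stats::nls(y ~ A1 * (1 - exp(-t / tau1)) + A2 * (1 - exp(-t / tau2)) + C,
               data = dat,
               start = list(A1 = amp / 2, tau1 = cf_m[["tau"]] / 4,
                            A2 = amp / 2, tau2 = cf_m[["tau"]] * 4,
                            C = y[1]),
               algorithm = "port",
               lower = c(A1 = -Inf, tau1 = 1e-4, A2 = -Inf, tau2 = 1e-4,
                         C = -Inf),
               control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                            warnOnly = TRUE))),
    error = function(e) NULL)

  n <- length(y)
  aicc <- function(ssr, k) {
    if (ssr < n * 1e-24) return(-Inf)            # numerically perfect fit
    n * log(ssr / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
  }
  a_m <- aicc(ssr_m, 4)
  d_aicc <- NA_real_
  use_bi <- FALSE
  tau2 <- NA_real_
  if (!is.null(bi)) {
    ssr_b <- sum(stats::residuals(bi)^2)
    a_b <- aicc(ssr_b, 6)
    d_aicc <- a_m - a_b            # +Inf when only the bi fit is perfect
    use_bi <- !is.nan(d_aicc) && d_aicc > 2
    if (use_bi) {
      taus <- sort(c(stats::coef(bi)[["tau1"]], stats::coef(bi)[["tau2"]]))
      tau2 <- taus[2]
    }
  }
  list(step_level = seg$step_level,
       tau_ms = if (use_bi) sort(c(stats::coef(bi)[["tau1"]],
                                   stats::coef(bi)[["tau2"]]))[1]
                else unname(cf_m[["tau"]]),
       time_to_peak_ms = (skip + ip - 1L) / rate,
       model = if (use_bi) "bi" else "mono",
       tau2_ms = tau2, delta_aicc = d_aicc,
       ssr = if (use_bi) sum(stats::residuals(bi)^2) else ssr_m)
}
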