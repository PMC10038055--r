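gating_only_model <- function(...) {
  args <- utils::modifyList(
    list(n_channels = 3000, gamma_ps = 4, v_rev = 60.25, p_open_max = 0,
         i_ss = 1, q_gating_e0 = 12, gating_v05 = -20, gating_k = 15,
         tau_gating_ms = 0.3),
    list(...))
  do.call(channel_model, args)
}

test_that("q_on matches the analytic exponential integral", {
  m <- gating_only_model()
  sim <- simulate_iv_family(m, v_from = 60, v_to = 60, dv = 5,
                            mode = "deterministic")
  seg <- segment(sim$sweeps, 2)[[1]]
  res <- q_on(seg, window_ms = 2, capacitance_pf = 10)
  # expected charge: Q_inf(60) - Q_inf(-89), 2-ms window captures
  # 1 - exp(-2/0.3) = 99.87% of the relaxation
  expQ <- sim$truth$expected_q_on
  expect_lt(abs(res$q_on_pa_ms / expQ - 1), 0.01)
  expect_equal(res$q_on_density, res$q_on_pa_ms / 10)
  expect_equal(res$v_used, 60)

  # gating-free, ionic-free trace integrates to zero
  m0 <- gating_only_model(q_gating_e0 = 0)
  sim0 <- simulate_iv_family(m0, v_from = 60, v_to = 60, dv = 5,
                             mode = "deterministic")
  expect_equal(q_on(segment(sim0$sweeps, 2)[[1]], 2)$q_on_pa_ms, 0)

  # doubling the sample rate changes the integral by < 0.5%
  sim2 <- simulate_iv_family(m, v_from = 60, v_to = 60, dv = 5,
                             sample_rate_khz = 100, mode = "deterministic")
  q2 <- q_on(segment(sim2$sweeps, 2)[[1]], 2)$q_on_pa_ms
  expect_lt(abs(q2 / res$q_on_pa_ms - 1), 0.005)

  expect_error(q_on(seg, window_ms = 100), "window")
})

test_that("q_on is additive over disjoint sub-windows", {
  m <- gating_only_model()
  sim <- simulate_iv_family(m, v_from = 60, v_to = 60, dv = 5,
                            mode = "deterministic")
  seg <- segment(sim$sweeps, 2)[[1]]
  q_full <- q_on(seg, window_ms = 2)$q_on_pa_ms
  q_a <- q_on(seg, window_ms = 1)$q_on_pa_ms
  seg_b <- seg
  seg_b$values <- seg$values[-(1:50)]          # drop the first 1 ms
  q_b <- q_on(seg_b, window_ms = 1)$q_on_pa_ms
  expect_equal(q_a + q_b, q_full, tolerance = 1e-9)
})

test_that("q_on_at_rev selects the sweep nearest the reversal potential", {
  m <- gating_only_model()
  sim <- simulate_iv_family(m, v_from = -80, v_to = 70, dv = 5,
                            mode = "deterministic")
  res <- q_on_at_rev(sim$sweeps, v_rev = 60.25)
  expect_equal(res$v_used, 60)
  expect_warning(q_on_at_rev(sim$sweeps, v_rev = 67.5), "V_rev")
})

test_that("q_imax_slope fits the coupling line", {
  d <- data.frame(q_on_density = c(1, 2, 3, 4),
                  i_max_density = 46 * c(1, 2, 3, 4))
  f <- suppressWarnings(q_imax_slope(d))   # lm warns on a perfect fit
  expect_equal(f$slope, 46, tolerance = 1e-10)
  expect_equal(f$se, 0, tolerance = 1e-8)
  expect_equal(f$slope_zero_intercept, 46, tolerance = 1e-10)
  expect_error(q_imax_slope(d[1, , drop = FALSE]), ">= 3")
  expect_error(q_imax_slope(data.frame(q_on_density = c(1, 1, 1),
                                       i_max_density = 1:3)), "degenerate")

  # synthetic cohort with configured coupling ratio and scatter
  set.seed(7)
  q <- runif(20, 0.5, 5)
  d2 <- data.frame(q_on_density = q,
                   i_max_density = 30 * q + rnorm(20, 0, 2))
  f2 <- q_imax_slope(d2)
  expect_lt(abs(f2$slope - 30), 3 * f2$se)
})

test_that("NSFA on the analytic expectation fixture is exact", {
  # sigma^2 = i I - I^2/N is the exact binomial identity; build the
  # variance-mean curve directly from it and check the fit is exact
  N <- 1000; i <- -0.5; b <- 0
  p <- seq(0.79, 0.01, length.out = 200)
  I <- N * p * i
  S <- N * p * (1 - p) * i^2 + b
  fit <- nsfa_parabola(I, S)
  expect_equal(fit$i, i, tolerance = 1e-3)
  expect_equal(fit$n_channels, N, tolerance = 1e-3)
  expect_equal(fit$b, 0, tolerance = 1e-9)
})

test_that("NSFA recovers the stochastic fixture ground truth", {
  m <- nsfa_fixture_model()                     # default seed = 1
  sim <- simulate_sweeps(m, protocol_nsfa(), mode = "stochastic",
                         n_repeats = 400)
  fit <- suppressWarnings(nsfa(sim$sweeps))
  i_true <- i_single(m, -49)
  expect_equal(i_true, -0.5, tolerance = 1e-12)
  expect_lt(abs(fit$i / i_true - 1), 0.10)
  expect_lt(abs(fit$n_channels / 1000 - 1), 0.15)
  expect_lt(abs(fit$p_open / 0.8 - 1), 0.10)
  expect_gt(fit$b, 0)
  # density convention: 10 pF <-> 1000 um^2
  expect_equal(fit$channel_density_um2, fit$n_channels / 1000)
})

test_that("NSFA guards: floor, zero variance, upward parabola", {
  m <- nsfa_fixture_model()
  sim <- simulate_sweeps(m, protocol_nsfa(), mode = "stochastic",
                         n_repeats = 30)
  expect_error(nsfa(sim$sweeps), "at least 50")

  det <- simulate_sweeps(m, protocol_nsfa(), mode = "deterministic")
  det10 <- det$sweeps
  det10$sweeps <- det10$sweeps[rep(1, 60), ]
  det10$protocol$sweep_levels <- rep(41, 60)
  attr(det10$protocol, "tail_epoch") <- 3L
  expect_error(suppressWarnings(nsfa(det10)), "variance is zero")

  # fabricate anti-binomial variance (grows quadratically): must refuse
  pr <- protocol_nsfa(n_sweeps = 1)
  sim2 <- simulate_sweeps(m, pr, mode = "stochastic", n_repeats = 300,
                          seed = 4)
  s2 <- sim2$sweeps
  mu <- colMeans(s2$sweeps)
  set.seed(5)
  fake <- t(sapply(1:300, function(r)
    mu * (1 + 0.3 * rnorm(length(mu)))))      # sd prop. to |mean|
  s2$sweeps <- fake
  expect_error(suppressWarnings(nsfa(s2)), "not saturating")
})

test_that("NSFA error shrinks as sweep count grows (fixed seed family)", {
  m <- nsfa_fixture_model()
  counts <- c(100, 400)
  err <- vapply(seq_along(counts), function(j) {
    es <- vapply(1:3, function(s) {
      sim <- simulate_sweeps(m, protocol_nsfa(), mode = "stochastic",
                             n_repeats = counts[j], seed = 100 + s)
      fit <- suppressWarnings(nsfa(sim$sweeps))
      abs(fit$n_channels / 1000 - 1) + abs(fit$i / -0.5 - 1)
    }, 0)
    mean(es)
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("derivative check verifies d(sigma^2)/dI = i - 2I/N", {
  N <- 800; i <- -0.6
  p <- seq(0.75, 0.02, length.out = 120)
  I <- N * p * i
  S <- N * p * (1 - p) * i^2 + 2
  fit <- nsfa_parabola(I, S)
  chk <- nsfa_derivative_check(fit)
  expect_equal(chk$i_at_zero, fit$i)            # algebraic identity
  expect_equal(chk$root_I, fit$i * fit$n_channels / 2)
  expect_false(chk$flagged)
  expect_lt(chk$fd_discrepancy, 0.05 * abs(i))

  # heteroscedastic contamination must be flagged
  set.seed(31)
  S_bad <- S * exp(rnorm(length(S), 0, 0.6))
  fit_bad <- tryCatch(nsfa_parabola(I, S_bad), error = function(e) NULL)
  if (!is.null(fit_bad)) {
    chk_bad <- nsfa_derivative_check(fit_bad)
    expect_true(chk_bad$flagged)
  }
})
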