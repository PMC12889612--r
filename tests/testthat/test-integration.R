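pulse_drive <- function(duration = 60, fs = 3) {
  tt <- seq(1 / fs, duration, by = 1 / fs)
  list(t = tt, v = as.numeric((tt %% 2) <= 1))
}

test_that("leaky integral matches the plain recursion and its limits", {
  d <- pulse_drive()
  for (tau in c(0.5, 5, 50)) {
    expect_equal(leaky_integral(d$v, 1 / 3, tau),
                 oracle_leaky(d$v, 1 / 3, tau), tolerance = 1e-12)
  }
  # perfect-integration limit: exact Euler staircase
  big <- leaky_integral(d$v, 1 / 3, 1e6)
  expect_equal(big[length(big)], sum(d$v) / 3, tolerance = 1e-3)
  expect_true(all(diff(big) >= -1e-4))  # monotone staircase up to decay
})

test_that("noiseless time constants are recovered within 5 percent", {
  d <- pulse_drive()
  for (tau in c(2, 5, 10, 20)) {
    ft <- fit_leaky_integrator(leaky_integral(d$v, 1 / 3, tau), d$v, 3)
    expect_true(ft$converged)
    expect_lt(abs(ft$tau - tau) / tau, 0.05)
    expect_lt(abs(ft$beta - 1), 0.05)
  }
  # near-perfect integrator pins to the grid upper bound
  ft <- fit_leaky_integrator(leaky_integral(d$v, 1 / 3, 1e6), d$v, 3)
  expect_gt(ft$tau, 95)
  z <- fit_leaky_integrator(rep(0, 60), d$v, 3)
  expect_identical(z$beta, 0)
  expect_true(is.na(z$tau))
  expect_false(z$converged)
})

test_that("the fit is scale-equivariant and absorbs initial conditions", {
  d <- pulse_drive()
  y <- leaky_integral(d$v, 1 / 3, 8)
  f1 <- fit_leaky_integrator(y, d$v, 3)
  f3 <- fit_leaky_integrator(3 * y, d$v, 3)
  expect_equal(f3$tau, f1$tau, tolerance = 1e-6)
  expect_equal(f3$beta, 3 * f1$beta, tolerance = 1e-6)
  # carried-over activity decaying at tau does not bias the estimate
  carry <- 5 * exp(-d$t / 8)
  fc <- fit_leaky_integrator(y + carry, d$v, 3)
  expect_lt(abs(fc$tau - 8) / 8, 0.05)
})

test_that("noisy recovery stays within the expected relative error", {
  d <- pulse_drive()
  set.seed(5)
  errs <- unlist(lapply(c(2, 5, 10, 20), function(tau) {
    y0 <- leaky_integral(d$v, 1 / 3, tau)
    vapply(1:10, function(i) {
      ft <- fit_leaky_integrator(y0 + stats::rnorm(length(y0), 0, 0.05),
                                 d$v, 3)
      abs(ft$tau - tau) / tau
    }, numeric(1))
  }))
  expect_lte(stats::median(errs), 0.15)
})

test_that("pulse endpoints follow the half-open frame convention", {
  tf <- seq(0.1, 12, by = 0.1)
  onsets <- seq(0, 10, by = 2)
  # staircase: step of 1 per pulse, held through OFF
  stair <- rep(cumsum(rep(1, 6)), each = 20)
  ep <- pulse_endpoints(stair, tf, onsets)
  expect_equal(ep$on, 1:6)
  expect_equal(ep$off, 1:6)
  expect_equal(ep$off0, 0)
  # transient: returns to zero in each OFF period
  trans <- rep(rep(c(1, 0), each = 10), 6)
  ep2 <- pulse_endpoints(trans, tf, onsets)
  expect_equal(ep2$on, rep(1, 6))
  expect_equal(ep2$off, rep(0, 6))
  expect_error(pulse_endpoints(stair, seq(0, 12, by = 3), onsets),
               "format error")
})

test_that("leaky endpoints agree with the analytic square-pulse solution", {
  tau <- 5
  tf <- seq(0.1, 12, by = 0.1)
  v <- as.numeric(((tf - 0.05) %% 2) < 1)
  y <- leaky_integral(v, 0.1, tau)
  ep <- pulse_endpoints(y, tf, seq(0, 10, by = 2))
  oracle <- oracle_pulse_endpoints(tau)
  expect_equal(ep$on, oracle$on, tolerance = 1e-6)
  expect_equal(ep$off, oracle$off, tolerance = 1e-6)
})

test_that("inverse leakiness separates perfect, leaky, and memoryless cells", {
  expect_equal(inverse_leakiness(list(on = 1:6, off = 1:6, off0 = 0)), 1)
  expect_equal(inverse_leakiness(list(on = rep(1, 6), off = rep(0, 6),
                                      off0 = 0)), 0)
  expect_true(is.na(inverse_leakiness(list(on = rep(0, 6),
                                           off = rep(0, 6), off0 = 0))))
  # frozen closed-form value for tau = 5 s under 1 s ON / 1 s OFF drive
  tau5 <- oracle_pulse_endpoints(5)
  expect_equal(inverse_leakiness(tau5), 0.5812150044, tolerance = 1e-6)
  # monotone non-decreasing in the generating time constant
  vals <- vapply(c(0.5, 1, 2, 5, 10, 50), function(tau) {
    inverse_leakiness(oracle_pulse_endpoints(tau))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("pulse AUCs integrate the response and stay linear", {
  tf <- seq(0.05, 11.95, by = 0.1)  # frame bin centers
  rect <- as.numeric(tf > 2 & tf < 3) * 4
  expect_equal(pulse_response_auc(rect, tf, 2, window = 2), 4,
               tolerance = 0.06)
  expect_equal(pulse_response_auc(rep(0, length(tf)), tf, 2), 0)
  expect_warning(pulse_response_auc(rect, tf, 11.5, window = 2),
                 "truncated")
  # additive over disjoint windows and linear in the trace
  set.seed(8)
  y <- stats::rnorm(length(tf))
  a1 <- pulse_response_auc(y, tf, 2, window = 2)
  expect_equal(pulse_response_auc(3 * y, tf, 2, window = 2), 3 * a1,
               tolerance = 1e-9)
  # fine-grid quadrature oracle within 2 percent
  fs_hi <- 300
  tt <- seq(1 / fs_hi, 12, by = 1 / fs_hi)
  resp <- convolve_indicator(as.numeric(tt > 2 & tt <= 3), 1 / fs_hi)
  coarse <- resp[seq(100, length(tt), by = 100)]
  auc_c <- pulse_response_auc(coarse, tt[seq(100, length(tt), by = 100)],
                              2, window = 2)
  auc_f <- trapz_ref <- sum(diff(tt[tt >= 2 & tt <= 4]) *
    (resp[tt >= 2 & tt <= 4][-1] + head(resp[tt >= 2 & tt <= 4], -1)) / 2)
  expect_equal(auc_c, auc_f, tolerance = 0.02)
})

test_that("template subtraction isolates the integrated component", {
  tf <- seq(0.05, 11.95, by = 0.1)  # frame bin centers
  onsets <- seq(0, 10, by = 2)
  trans <- rep(rep(c(1, 0), each = 10), 6)
  tmpl_t <- seq(0.05, 1.95, by = 0.1)
  tmpl <- rep(c(1, 0), each = 10)
  expect_equal(pulse_integration_auc(trans, tf, onsets, tmpl, tmpl_t), 0,
               tolerance = 1e-9)
  # staircase minus six transient copies, against direct arithmetic
  stair <- rep(cumsum(rep(1, 6)), each = 20)
  got <- pulse_integration_auc(stair, tf, onsets, tmpl, tmpl_t)
  resid <- stair - rep(tmpl, 6)
  want <- sum(diff(tf) * (resid[-1] + resid[-length(resid)]) / 2)
  expect_equal(got, want, tolerance = 1e-9)
  expect_error(pulse_integration_auc(stair, tf, onsets, rep(1, 30),
                                     seq(0.05, 2.95, by = 0.1)),
               "format error")
})
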