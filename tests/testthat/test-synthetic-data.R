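test_that("closed-loop rule reproduces the feedback equation", {
  expect_equal(closed_loop_step(10, 0, 1), 10)
  # open loop: zero gain decouples the stimulus from swimming
  expect_equal(closed_loop_step(10, 5, 0), 10)
  expect_equal(closed_loop_step(10, 4, 2.5), 0)
  expect_error(closed_loop_step(NA, 1, 1), "finite")
  expect_error(closed_loop_step(10, -1, 1), "m must be >= 0")
})

test_that("latent state decays, accumulates futile vigor, and clamps in calex", {
  s <- 0.5
  for (i in 1:5000) s <- astro_state_step(s, 0, FALSE, 0.01, 2, 0.4)
  expect_lt(s, 1e-6)
  # fixed point of the recursion under constant futile vigor
  s <- 0
  for (i in 1:200000) s <- astro_state_step(s, 2, TRUE, 0.01, 5, 0.3)
  expect_equal(s, 0.3 * 2 * 5, tolerance = 0.002)
  expect_identical(astro_state_step(3, 10, TRUE, 0.1, 5, 1,
                                    mode = "calex"), 0)
  expect_error(astro_state_step(1, 1, TRUE, 0.1, -1, 1), "tau_a")
})

test_that("paradigm configuration enforces quiescence equalization", {
  expect_error(paradigm_config(pause_futile = 4), "equalization")
  expect_error(paradigm_config(probe_cap = 1), "pulse period")
  expect_silent(paradigm_config())
})

test_that("identical seeds give bitwise-identical sessions", {
  a <- simulate_session(paradigm_config(n_trials = 4),
                        small_population(), seed = 42)
  b <- simulate_session(paradigm_config(n_trials = 4),
                        small_population(), seed = 42)
  expect_identical(a$neural$dff, b$neural$dff)
  expect_identical(a$stimulus$v_stim, b$stimulus$v_stim)
  expect_identical(a$truth$trials, b$truth$trials)
  expect_identical(a$state$s, b$state$s)
})

test_that("quiescence before Probe equals 8 s on both trial types", {
  ses <- small_session()
  tr <- ses$truth$trials
  fut <- tr[tr$type == "Futile", ]
  expect_true(all(abs(fut$probe_on - fut$last_evoke_swim_off - 8) < 1e-9))
  eff <- tr[tr$type == "Effective", ]
  expect_true(all(abs(eff$probe_on - eff$last_evoke_swim_off - 8) < 1e-9))
})

test_that("state stays non-negative, higher on Futile probes, zero in calex", {
  ses <- small_session()
  expect_true(all(ses$state$s >= 0))
  tr <- ses$truth$trials
  expect_gt(min(tr$s_probe[tr$type == "Futile"]),
            max(tr$s_probe[tr$type == "Effective"]))
  cal <- small_session(seed = 102, mode = "calex")
  expect_true(all(cal$state$s == 0))
  expect_true(all(cal$truth$trials$s_probe == 0))
})

test_that("probe latencies run longer after futile swimming", {
  trs <- do.call(rbind, lapply(1:3, function(i) {
    simulate_swim_agent(paradigm_config(n_trials = 40),
                        state_params(), seed = 300 + i)$trials
  }))
  expect_gte(nrow(trs), 100)
  expect_gt(mean(trs$latency[trs$type == "Futile"]),
            mean(trs$latency[trs$type == "Effective"]))
})

test_that("ephys synthesis matches its statistical contract", {
  no_bouts <- data.frame(onset = numeric(0), offset = numeric(0),
                         vigor = numeric(0))
  tr <- synth_ephys(no_bouts, fs_ephys = 1000, noise_sd = 0.7,
                    duration = 20, seed = 1)
  expect_equal(sqrt(mean(tr$y^2)), 0.7, tolerance = 0.02)
  # a loud constant-amplitude burst has RMS a/sqrt(2)
  b <- data.frame(onset = 1, offset = 3, vigor = 1)
  tr2 <- synth_ephys(b, fs_ephys = 1000, noise_sd = 0.01, am_hz = 0,
                     amp_per_vigor = 100 * 50, duration = 5, seed = 1)
  inside <- tr2$y[1300:2700]  # past the on/off ramps
  a <- 50 * 100 * 0.01
  expect_equal(sqrt(mean(inside^2)), a / sqrt(2), tolerance = 0.02 * a)
  expect_identical(synth_ephys(b, seed = 9)$y, synth_ephys(b, seed = 9)$y)
  overlap <- data.frame(onset = c(0, 0.5), offset = c(1, 1.5),
                        vigor = c(1, 1))
  expect_error(synth_ephys(overlap), "non-overlapping")
})

test_that("indicator convolution is linear and matches its kernel", {
  dt <- 0.01
  x1 <- c(rep(0, 50), rep(1, 100), rep(0, 350))
  x2 <- c(rep(0, 300), 2, rep(0, 199))
  y12 <- convolve_indicator(x1 + x2, dt)
  expect_equal(y12, convolve_indicator(x1, dt) + convolve_indicator(x2, dt),
               tolerance = 1e-12)
  # impulse response recovers the kernel shape (one-step causal lag)
  imp <- c(1 / dt, rep(0, 499))
  tt <- (seq_along(imp) - 1) * dt
  expect_equal(convolve_indicator(imp, dt), indicator_kernel(tt),
               tolerance = 1e-6)
})

test_that("noiseless sensory cells reproduce the convolved stimulus", {
  ag <- toy_agent(s_level = 0)
  pop <- small_population(noise_sd = 0, gain_cv = 0)
  out <- synth_population(ag, pop, seed = 1, classes = "sensory_pos")
  cell <- out$dff[1, ]
  ref <- swimstate:::bin_to_frames(
    convolve_indicator(pmax(ag$v_stim, 0) / 4, 1 / ag$fs),
    ag$t, pop$fs_img, length(out$t_frames))
  expect_equal(cell, ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("noiseless integrator cells match an independent recursion oracle", {
  ag <- toy_agent(s_level = 0)
  pop <- small_population(noise_sd = 0, gain_cv = 0,
                          integrator_sensory_mix = 0)
  out <- synth_population(ag, pop, seed = 1, classes = "integrator")
  I <- oracle_leaky(pmax(ag$v_stim, 0) / 4, 1 / ag$fs, pop$tau_engaged)
  ref <- swimstate:::bin_to_frames(
    convolve_indicator(I / pop$tau_engaged, 1 / ag$fs),
    ag$t, pop$fs_img, length(out$t_frames))
  expect_equal(out$dff[1, ], ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("full state dampens sensory pulses by the configured depth", {
  pop <- small_population(noise_sd = 0, gain_cv = 0)
  lo <- synth_population(toy_agent(s_level = 0), pop, seed = 1,
                         classes = "sensory_pos")
  hi <- synth_population(toy_agent(s_level = 1), pop, seed = 1,
                         classes = "sensory_pos")
  expect_equal(max(hi$dff[1, ]) / max(lo$dff[1, ]),
               1 - pop$sensory_depth, tolerance = 1e-10)
})

test_that("unknown cell classes are rejected", {
  expect_error(synth_population(toy_agent(), small_population(),
                                classes = c("sensory_pos", "ghost")),
               "unknown class")
})
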