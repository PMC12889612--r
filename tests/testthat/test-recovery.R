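warp_inputs <- function(n_mid, fs = 3, left_len = 4, right_len = 2,
                        value = function(t) t) {
  # one trial: probe at 10 s, anchor placed so the middle has n_mid frames
  probe_on <- 10
  nl <- left_len * fs
  nr <- right_len * fs
  tt <- seq(1 / fs, 60, by = 1 / fs)
  anchor <- tt[max(which(tt >= probe_on)) ] # placeholder
  i0 <- min(which(tt >= probe_on))
  anchor <- tt[i0 + nl + n_mid + nr - 1] + 1e-6
  list(traces = list(value(tt)), t_list = list(tt),
       probe_on = probe_on, anchor = anchor)
}

test_that("time warping is the identity when the middle already fits", {
  w <- warp_inputs(n_mid = 20)
  out <- time_warp_align(w$traces, w$t_list, w$probe_on, w$anchor,
                         left_len = 4, right_len = 2, n_stu = 20, fs_img = 3)
  tt <- w$t_list[[1]]
  i0 <- min(which(tt >= 10))
  expect_equal(drop(out$matrix), tt[i0:(i0 + 12 + 20 + 6 - 1)])
  expect_equal(out$kept, 1L)
})

test_that("warping preserves constants and monotonicity", {
  wc <- warp_inputs(n_mid = 33, value = function(t) rep(4.2, length(t)))
  outc <- time_warp_align(wc$traces, wc$t_list, wc$probe_on, wc$anchor,
                          left_len = 4, right_len = 2, n_stu = 20,
                          fs_img = 3)
  expect_true(all(outc$matrix == 4.2))
  wm <- warp_inputs(n_mid = 33)
  outm <- time_warp_align(wm$traces, wm$t_list, wm$probe_on, wm$anchor,
                          left_len = 4, right_len = 2, n_stu = 20,
                          fs_img = 3)
  expect_true(all(diff(drop(outm$matrix)) > 0))
  # too-short trial excluded with a warning
  ws <- warp_inputs(n_mid = 0)
  expect_warning(
    out0 <- time_warp_align(ws$traces, ws$t_list, ws$probe_on,
                            ws$probe_on + 4 + 2, left_len = 4,
                            right_len = 2, n_stu = 20, fs_img = 3),
    "excluded")
  expect_equal(length(out0$kept), 0)
})

test_that("warp-average commutes with average-warp for equal-length trials", {
  set.seed(6)
  base <- warp_inputs(n_mid = 33)
  tt <- base$t_list[[1]]
  traces <- lapply(1:5, function(i) stats::rnorm(length(tt)))
  out <- time_warp_align(traces, rep(list(tt), 5), rep(10, 5),
                         rep(base$anchor, 5), left_len = 4,
                         right_len = 2, n_stu = 20, fs_img = 3)
  avg_then_warp <- time_warp_align(list(Reduce(`+`, traces) / 5),
                                   list(tt), 10, base$anchor,
                                   left_len = 4, right_len = 2,
                                   n_stu = 20, fs_img = 3)
  expect_equal(colMeans(out$matrix), drop(avg_then_warp$matrix),
               tolerance = 1e-12)
})

test_that("last pulse before the swim respects the period grid", {
  tr <- data.frame(probe_on = 20, latency = 13.4)
  expect_equal(last_pulse_before_swim(tr), 20 + 12)
  tr2 <- data.frame(probe_on = 20, latency = 0.5)
  expect_equal(last_pulse_before_swim(tr2), 20)
})

test_that("amplification curves rise toward the swim on generator data", {
  ses <- small_session()
  tr <- small_trials(ses)
  sens <- which(ses$truth$cells$class == "sensory_pos")
  pa <- pulse_table(ses, tr, cell_ids = sens, n_pulses = 30)
  amp <- progressive_amplification(pa, tr)
  for (cc in unique(amp$condition)) {
    a <- amp[amp$condition == cc, ]
    a <- a[a$n >= 5, ]
    if (nrow(a) >= 3) {
      expect_gt(stats::cor(a$rel_index, a$mean, method = "spearman"), 0)
    }
  }
  # amplification off (and state clamped): flat curve
  ses0 <- cached("ses_ampoff", simulate_session(
    paradigm_config(n_trials = 10),
    small_population(mode = "calex"), state_params(amp_gain = 0),
    seed = 101))
  tr0 <- build_trials(ses0$stimulus$epochs, ses0$truth$bouts,
                      paradigm_config())
  pa0 <- pulse_table(ses0, tr0,
                     cell_ids = which(ses0$truth$cells$class == "sensory_pos"),
                     n_pulses = 30)
  # drop the first two pulses, whose windows lack the steady-state
  # inter-pulse decay tail and would bias the index composition
  amp0 <- progressive_amplification(pa0[pa0$pulse_i >= 3, ], tr0)
  a0 <- amp0[amp0$condition == "Engaged" & amp0$n >= 5, ]
  slope <- stats::coef(stats::lm(mean ~ rel_index, a0))[2]
  # total drift across the curve well below 10% of the response level
  expect_lt(abs(slope) * 7, 0.1 * mean(a0$mean))
  # single trial: curve equals that trial's AUCs, SEM undefined
  one <- pa[pa$trial == pa$trial[1] & pa$cell_id == sens[1], ]
  amp1 <- progressive_amplification(one, tr[tr$trial == one$trial[1], ])
  expect_true(all(is.na(amp1$sem)))
  expect_true(all(amp1$n == 1))
})

test_that("decoder recovers noiseless informative features and fails nulls", {
  set.seed(7)
  n_tr <- 40
  lat <- stats::runif(n_tr, 5, 40)
  trial_id <- seq_len(n_tr)
  cond <- rep(c("Engaged", "Disengaged"), each = n_tr / 2)
  X <- cbind(2 * lat + 1, -0.5 * lat)  # noiseless linear features
  dec <- decode_latency(X, lat, trial_id, cond, seed = 1)
  for (cc in unique(cond)) {
    expect_gt(dec$cor[[cc]], 0.9)
  }
  # independent features: correlation within the permutation null band
  Xn <- matrix(stats::rnorm(n_tr * 5), n_tr)
  decn <- decode_latency(Xn, lat, trial_id, cond, seed = 1)
  nulls <- replicate(500, {
    k <- nrow(decn$predictions[decn$predictions$condition == "Engaged", ])
    stats::cor(stats::rnorm(k), stats::rnorm(k), method = "spearman")
  })
  expect_gt(decn$cor[["Engaged"]], stats::quantile(nulls, 0.005))
  expect_lt(decn$cor[["Engaged"]], stats::quantile(nulls, 0.995))
  # too few trials: skipped with a warning
  expect_warning(decode_latency(X[1:3, ], lat[1:3], trial_id[1:3],
                                rep("Engaged", 3), seed = 1),
                 "fewer than 4")
})

test_that("behavior-predictive selection has the nominal false-positive rate", {
  ses <- small_session()
  tr <- small_trials(ses)
  sens <- which(ses$truth$cells$class == "sensory_pos")
  pa <- pulse_table(ses, tr, cell_ids = sens, n_pulses = 30)
  ds <- decoder_samples(pa, tr)
  bp <- behavior_predictive_cells(ds$features, ds$target)
  expect_gte(mean(bp), 0.8)  # amplified cells predict recovery
  # shuffling latencies across samples destroys the selection
  set.seed(8)
  rates <- replicate(30, {
    mean(behavior_predictive_cells(ds$features, sample(ds$target)))
  })
  expect_lt(mean(rates), 0.10)
})

test_that("decoding is reproducible and seed-sensitive only in the split", {
  ses <- small_session()
  tr <- small_trials(ses)
  sens <- which(ses$truth$cells$class == "sensory_pos")
  pa <- pulse_table(ses, tr, cell_ids = sens, n_pulses = 30)
  ds <- decoder_samples(pa, tr)
  d1 <- decode_latency(ds$features, ds$target, ds$trial_id, ds$condition,
                       seed = 5)
  d2 <- decode_latency(ds$features, ds$target, ds$trial_id, ds$condition,
                       seed = 5)
  expect_identical(d1$predictions, d2$predictions)
  # train and test trials are disjoint
  expect_true(all(!duplicated(unique(d1$predictions$trial_id))))
})
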