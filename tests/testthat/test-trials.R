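toy_epochs <- function(type = "Effective", evoke_on = 5, evoke_off = 15,
                       pause = if (type == "Effective") 8 else 3,
                       probe_len = 40) {
  data.frame(trial = 1L, type = type, capsaicin = FALSE,
             pre_on = 0, evoke_on = evoke_on, evoke_off = evoke_off,
             pause_on = evoke_off, pause_off = evoke_off + pause,
             probe_on = evoke_off + pause,
             probe_off = evoke_off + pause + probe_len,
             n_pulses = probe_len / 2)
}

bouts_df <- function(onsets, dur = 0.3) {
  data.frame(onset = onsets, offset = onsets + dur)
}

test_that("trial assembly reconstructs epochs and latencies", {
  ses <- small_session()
  tr <- small_trials(ses)
  # Futile: last Evoke swim offset to Probe onset is exactly 8 s
  fut <- tr[tr$type == "Futile", ]
  truth <- ses$truth$trials
  expect_equal(fut$probe_on,
               truth$last_evoke_swim_off[truth$type == "Futile"] + 8)
  # Effective: Pause alone is the 8 s
  eff <- tr[tr$type == "Effective", ]
  expect_equal(eff$probe_on - eff$pause_on, rep(8, nrow(eff)))
  # latencies computed from bouts agree with the generator's
  expect_equal(tr$latency, truth$latency)
  expect_equal(tr$censored, truth$censored)
  bad <- ses$stimulus$epochs[, setdiff(names(ses$stimulus$epochs),
                                       "probe_on")]
  expect_error(build_trials(bad, ses$truth$bouts), "format error")
})

test_that("latency to the probe-evoked swim follows the cap and boundary rules", {
  ep <- toy_epochs()
  lat <- latency_to_probe_swim(ep, bouts_df(ep$probe_on + 12.4))
  expect_equal(lat$latency, 12.4)
  expect_false(lat$censored)
  # no probe bout: censored at the cap
  lat2 <- latency_to_probe_swim(ep, bouts_df(numeric(0)))
  expect_equal(lat2$latency, 40)
  expect_true(lat2$censored)
  # bout exactly at probe onset counts (boundary inclusive)
  lat3 <- latency_to_probe_swim(ep, bouts_df(ep$probe_on))
  expect_equal(lat3$latency, 0)
})

test_that("classification follows the engagement rules", {
  ep <- toy_epochs("Effective")
  # continuous swimming with 2 s gaps through Evoke
  on <- seq(5, 14.7, by = 2.3)
  expect_equal(classify_trial(ep, bouts_df(c(on, 14.7))), "Engaged")
  # > 3 s pause at the Evoke end
  expect_equal(classify_trial(ep, bouts_df(c(5, 7, 9, 11))), "Excluded")
  fp <- toy_epochs("Futile")
  # final 6 s of Evoke swim-free
  expect_equal(classify_trial(fp, bouts_df(c(5, 7, 8.7))), "Disengaged")
  # swimming up to the Pause transition
  expect_equal(classify_trial(fp, bouts_df(seq(5, 14.6, by = 1.2))),
               "Perseverant")
})

test_that("every random bout pattern receives exactly the oracle label", {
  set.seed(99)
  for (i in seq_len(10000)) {
    type <- sample(c("Effective", "Futile"), 1)
    ep <- toy_epochs(type)
    n <- sample(0:8, 1)
    onsets <- sort(stats::runif(n, ep$evoke_on, ep$evoke_off - 0.3))
    b <- bouts_df(onsets)
    got <- classify_trial(ep, b)
    if (n == 0) {
      expect_true(got %in% c("Disengaged", "Excluded"))
      next
    }
    gaps <- c(onsets[1] - ep$evoke_on,
              if (n > 1) onsets[-1] - (onsets[-n] + 0.3))
    want <- oracle_classify(type, gaps, ep$evoke_off - (onsets[n] + 0.3))
    expect_identical(got, want)
  }
})

test_that("dual-alignment filter keeps latencies of 20 s and above", {
  tr <- data.frame(latency = c(5, 19.9, 20, 35),
                   censored = c(FALSE, FALSE, FALSE, FALSE))
  expect_equal(filter_for_dual_alignment(tr)$latency, c(20, 35))
  expect_equal(nrow(filter_for_dual_alignment(tr[0, ])), 0)
  all20 <- data.frame(latency = c(21, 60), censored = c(FALSE, FALSE))
  expect_identical(filter_for_dual_alignment(all20), all20)
  # censored trials have no swim to align to
  cen <- data.frame(latency = 60, censored = TRUE)
  expect_equal(nrow(filter_for_dual_alignment(cen)), 0)
})

test_that("latency summaries report both censoring treatments", {
  tr <- data.frame(type = c("Effective", "Effective", "Futile", "Futile"),
                   latency = c(10, 60, 20, 60),
                   censored = c(FALSE, TRUE, FALSE, TRUE))
  s <- latency_summary(tr)
  expect_equal(s$mean[s$type == "Effective" & s$rule == "censored_at_cap"], 35)
  expect_equal(s$mean[s$type == "Effective" & s$rule == "censored_excluded"], 10)
})
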