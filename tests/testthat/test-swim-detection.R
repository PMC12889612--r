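test_that("vigor is the sliding-window standard deviation", {
  expect_error(compute_vigor(rep(1, 100), window = 0.001, fs = 1000),
               "at least 2 samples")
  expect_true(all(compute_vigor(rep(3, 500), fs = 1000)$m == 0))
  # alternating +/- a has SD about a in the interior
  a <- 2.5
  alt <- rep(c(a, -a), 250)
  vg <- compute_vigor(alt, fs = 1000)
  expect_equal(unname(stats::median(vg$m[50:450])), a, tolerance = 0.05)
  # matches the brute-force oracle everywhere, including edges
  set.seed(1)
  y <- stats::rnorm(400)
  expect_equal(compute_vigor(y, window = 0.01, fs = 1000)$m,
               naive_sliding_sd(y, 10), tolerance = 1e-9)
})

test_that("white-noise vigor recovers the noise SD", {
  set.seed(7)
  sigma <- 1.7
  vg <- compute_vigor(stats::rnorm(1e5, 0, sigma), fs = 1000)
  expect_equal(unname(stats::median(vg$m)), sigma, tolerance = 0.05 * sigma)
})

test_that("envelope transform matches a naive convolution oracle", {
  fs <- 1000
  expect_true(all(abs(smoothed_envelope(rep(5, 3000), fs)) < 1e-10))
  # fast sinusoid: the envelope is a/sqrt(2) away from the edges
  a <- 3
  tt <- seq(0, 3, by = 1 / fs)
  y <- a * sin(2 * pi * 60 * tt)
  x <- smoothed_envelope(y, fs)
  expect_equal(mean(x[800:2200]), a / sqrt(2), tolerance = 0.02 * a)
  # arbitrary trace: direct O(n k) convolution agreement at 1e-10
  set.seed(2)
  y2 <- stats::rnorm(3000) + 2 * sin(2 * pi * 40 * seq_len(3000) / fs)
  x2 <- smoothed_envelope(y2, fs)
  ref <- naive_envelope(y2, fs)
  expect_lt(max(abs(x2 - ref) / pmax(abs(ref), 1e-12)), 1e-10)
})

test_that("envelope shifts with DC offset removed and scales linearly", {
  set.seed(3)
  fs <- 1000
  y <- stats::rnorm(3000)
  x <- smoothed_envelope(y, fs)
  expect_equal(smoothed_envelope(y + 7, fs), x, tolerance = 1e-8)
  expect_equal(smoothed_envelope(3 * y, fs), 3 * x, tolerance = 1e-8)
})

test_that("automatic threshold reproduces the histogram rule", {
  # constructed bimodal sample: mode near 0.2, sparse tail to 0.8
  set.seed(4)
  x <- c(stats::rnorm(30000, 0.2, 0.05), stats::runif(4000, 0.2, 0.8))
  th <- auto_threshold(x, bout_params(c = 1.8))
  expect_equal(th, naive_threshold(x, c = 1.8), tolerance = 1e-12)
  expect_equal(th, 0.2 + 1.8 * 0.6, tolerance = 0.07)
  # c = 0 collapses to the mode
  th0 <- auto_threshold(x, bout_params(c = 0))
  expect_equal(th0, 0.2, tolerance = 0.05)
  expect_error(auto_threshold(rep(1, 2000)), "degenerate")
  expect_error(auto_threshold(stats::rnorm(10)), "degenerate")
})

test_that("threshold on pure noise envelope clears the 99th percentile", {
  set.seed(5)
  tr <- synth_ephys(data.frame(onset = numeric(0), offset = numeric(0),
                               vigor = numeric(0)),
                    fs_ephys = 1000, duration = 60, seed = 5)
  x <- smoothed_envelope(tr$y, 1000)
  expect_gt(auto_threshold(x, bout_params(c = 1.8)),
            stats::quantile(x, 0.99))
})

test_that("bout detection segments, merges, and filters runs", {
  fs <- 100
  x <- rep(0.1, 1000)
  expect_equal(nrow(detect_bouts(x, fs, th = 1)), 0)
  # three well-separated bursts
  x[101:130] <- 5; x[401:440] <- 6; x[801:830] <- 5
  b <- detect_bouts(x, fs, th = 1)
  expect_equal(nrow(b), 3)
  expect_equal(b$onset, c(1.0, 4.0, 8.0), tolerance = 0.02)
  expect_true(all(b$offset > b$onset))
  expect_true(!is.unsorted(b$onset))
  expect_true(all(b$onset[-1] >= b$offset[-nrow(b)]))
  # re-running yields the same table
  expect_identical(b, detect_bouts(x, fs, th = 1))
  # two bursts closer than merge_gap/2 fuse into one
  x2 <- rep(0.1, 1000)
  x2[101:130] <- 5
  x2[141:170] <- 5  # 0.1 s gap < 0.2 s merge_gap
  expect_equal(nrow(detect_bouts(x2, fs, th = 1)), 1)
  # sub-minimum-duration blips are dropped
  x3 <- rep(0.1, 1000)
  x3[500:502] <- 5
  expect_equal(nrow(detect_bouts(x3, fs, th = 1)), 0)
})

test_that("end-to-end detection recovers ground-truth bouts", {
  truth <- random_bout_train(11)
  tr <- synth_ephys(truth, fs_ephys = 1000, duration = 300, seed = 11)
  det <- detect_swims(tr)
  r <- detection_rates(det, truth)
  expect_gte(r["recall"], 0.99)
  expect_gte(r["precision"], 0.99)
  onset_err <- vapply(truth$onset,
                      function(o) min(abs(det$onset - o)), numeric(1))
  expect_lte(max(onset_err), 0.1)
  expect_true(all(diff(det$onset) > 0))
})
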