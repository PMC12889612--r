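# Independent brute-force oracles used to pin down the numerical
# operations; these deliberately avoid the implementation's code paths.

naive_sliding_sd <- function(y, w) {
  n <- length(y)
  half <- w %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    seg <- y[max(1, i - half):min(n, i + half)]
    out[i] <- if (length(seg) < 2) 0 else stats::sd(seg)
  }
  out
}

# direct O(n*k) centered convolution with edge renormalization
naive_smooth_conv <- function(y, kernel) {
  n <- length(y)
  k <- length(kernel)
  h <- (k - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    wsum <- 0
    for (j in -h:h) {
      ij <- i + j
      if (ij >= 1 && ij <= n) {
        w <- kernel[j + h + 1]
        acc <- acc + y[ij] * w
        wsum <- wsum + w
      }
    }
    out[i] <- acc / wsum
  }
  out
}

naive_envelope <- function(y, fs, params = bout_params()) {
  k1 <- swimstate:::smoothing_kernel(params$ker1_width, fs, params$kernel)
  k2 <- swimstate:::smoothing_kernel(params$ker2_width, fs, params$kernel)
  hp <- y - naive_smooth_conv(y, k1)
  sqrt(pmax(naive_smooth_conv(hp^2, k2), 0))
}

# histogram-based threshold recomputed from first principles
naive_threshold <- function(x, c = 1.8, rel_density = 0.01) {
  rng <- range(x)
  bw_fd <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  n_bins <- max(200, if (bw_fd > 0) ceiling(diff(rng) / bw_fd) else 200)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- numeric(n_bins)
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  idx[idx > n_bins] <- n_bins
  for (i in idx) counts[i] <- counts[i] + 1
  i_max <- which(counts == max(counts))[1]
  x_max <- centers[i_max]
  x_min <- centers[max(which(counts > rel_density * counts[i_max]))]
  x_max + c * abs(x_min - x_max)
}

# plain-loop leaky integrator recursion
oracle_leaky <- function(v, dt, tau) {
  out <- numeric(length(v))
  I <- 0
  for (k in seq_along(v)) {
    a <- exp(-dt / tau)
    I <- I * a + v[k] * tau * (1 - a)
    out[k] <- I
  }
  out
}

# continuous-time square-pulse endpoints: value at `at_on`/`at_off`
# seconds into each ON/OFF half-period, from the analytic solution
oracle_pulse_endpoints <- function(tau, n = 6, v = 1, t_on = 1, t_off = 1,
                                   at_on = 0.9, at_off = 0.9) {
  on <- off <- numeric(n)
  I <- 0
  for (i in seq_len(n)) {
    on[i] <- I * exp(-at_on / tau) + v * tau * (1 - exp(-at_on / tau))
    I_end <- I * exp(-t_on / tau) + v * tau * (1 - exp(-t_on / tau))
    off[i] <- I_end * exp(-at_off / tau)
    I <- I_end * exp(-t_off / tau)
  }
  list(on = on, off = off, off0 = 0)
}

# independent re-statement of the trial classification rules
oracle_classify <- function(type, gaps, end_gap, isi_max = 3,
                            passivity_window = 5, end_pause_max = 3) {
  if (type == "Futile") {
    if (end_gap >= passivity_window) "Disengaged" else "Perseverant"
  } else {
    if (all(gaps <= isi_max) && end_gap <= end_pause_max) "Engaged"
    else "Excluded"
  }
}

detection_rates <- function(det, truth, tol = 0.1) {
  if (nrow(det) == 0) return(c(recall = 0, precision = 0))
  hit <- vapply(truth$onset,
                function(o) any(abs(det$onset - o) <= tol), logical(1))
  good <- vapply(det$onset,
                 function(o) any(abs(truth$onset - o) <= tol), logical(1))
  c(recall = mean(hit), precision = mean(good))
}

random_bout_train <- function(seed, duration = 300, n = 30) {
  set.seed(seed)
  onsets <- sort(stats::runif(n, 1, duration - 10))
  onsets <- onsets[c(TRUE, diff(onsets) > 1.2)]
  data.frame(onset = onsets, offset = onsets + 0.3,
             vigor = stats::rlnorm(length(onsets), 0, 0.25))
}
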