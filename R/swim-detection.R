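#' Bout-detection parameters
#'
#' @param ker1_width,ker2_width smoothing-kernel timescales (s) for the
#'   envelope transform (defaults 100 ms and 20 ms).
#' @param c threshold multiplier; 1.8 suits low-noise recordings, up to
#'   5 for noisier ones.
#' @param rel_density density cutoff (relative to the mode) locating
#'   the upper edge of the noise distribution.
#' @param merge_gap candidate bouts closer than this (s) are merged.
#' @param min_duration candidates shorter than this (s) are dropped.
#' @param kernel smoothing-kernel shape, "gaussian" or "boxcar".
#' @return list of class `bout_params`.
#' @export
bout_params <- function(ker1_width = 0.100, ker2_width = 0.020,
                        c = 1.8, rel_density = 0.01,
                        merge_gap = 0.2, min_duration = 0.05,
                        kernel = c("gaussian", "boxcar")) {
  kernel <- match.arg(kernel)
  if (c < 0) stop("invalid argument: c must be >= 0", call. = FALSE)
  if (rel_density <= 0 || rel_density >= 1) {
    stop("invalid argument: rel_density must lie in (0, 1)", call. = FALSE)
  }
  assert_positive(c(ker1_width, ker2_width, merge_gap, min_duration),
                  "bout parameter widths")
  structure(as.list(environment()), class = "bout_params")
}

#' Decode swim vigor from a ventral-root trace
#'
#' Vigor is the standard deviation of the signal within a centered
#' sliding window (default 10 ms); edge windows shrink so the output
#' preserves length.
#'
#' @param trace an `ephys_trace` (list with `y`, `fs`) or numeric
#'   vector (then `fs` must be given).
#' @param window window length (s).
#' @param fs sampling rate, required when `trace` is a bare vector.
#' @return list of class `vigor_trace` with `m`, `fs`, `window`.
#' @export
compute_vigor <- function(trace, window = 0.010, fs = NULL) {
  if (is.list(trace)) { y <- trace$y; fs <- trace$fs } else y <- trace
  if (is.null(fs)) stop("fs required", call. = FALSE)
  w <- round(window * fs)
  if (w < 2) {
    stop("invalid argument: window must span at least 2 samples",
         call. = FALSE)
  }
  structure(list(m = sliding_sd(y, w), fs = fs, window = window),
            class = "vigor_trace")
}

#' Smoothed envelope of a ventral-root trace
#'
#' The transform `x = sqrt(((y - y*ker1)^2) * ker2)`: the signal is
#' high-passed by subtracting a slow (100 ms) smooth, squared, smoothed
#' again on a fast (20 ms) timescale, and square-rooted. Kernels are
#' unit-area; near the trace edges they are renormalized over the
#' in-range samples.
#'
#' @param y numeric signal.
#' @param fs sampling rate (Hz).
#' @param params a [bout_params()].
#' @return non-negative envelope, same length as `y`.
#' @export
smoothed_envelope <- function(y, fs, params = bout_params()) {
  k1 <- smoothing_kernel(params$ker1_width, fs, params$kernel)
  k2 <- smoothing_kernel(params$ker2_width, fs, params$kernel)
  hp <- y - smooth_conv(y, k1)
  sqrt(pmax(smooth_conv(hp^2, k2), 0))
}

#' Automatic envelope threshold
#'
#' Estimates the envelope density by histogram (Freedman-Diaconis bin
#' width with a floor of 200 bins), takes the mode `x_max`, finds
#' `x_min` as the highest envelope value whose density still exceeds
#' `rel_density` times the mode density, and returns
#' `th = x_max + c * |x_min - x_max|`.
#'
#' The printed form of this rule, `th = x_max + c (x_max - x_min)`,
#' yields a threshold below the mode whenever the upper density edge
#' exceeds the mode, which defeats its purpose; the absolute spread is
#' used instead.
#'
#' @param x envelope samples (>= 1000, non-degenerate).
#' @param params a [bout_params()].
#' @return threshold in envelope units.
#' @export
auto_threshold <- function(x, params = bout_params()) {
  x <- x[is.finite(x)]
  if (length(x) < 1000 || stats::sd(x) == 0) {
    stop("degenerate input: need >= 1000 envelope samples with nonzero ",
         "variance", call. = FALSE)
  }
  rng <- range(x)
  bw_fd <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  n_bins <- max(200L, if (bw_fd > 0) ceiling(diff(rng) / bw_fd) else 200L)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- hist(x, breaks = breaks, plot = FALSE)
  d <- h$counts
  centers <- h$mids
  i_max <- which(d == max(d))[1L]  # ties toward smaller x
  x_max <- centers[i_max]
  above <- which(d > params$rel_density * d[i_max])
  x_min <- centers[max(above)]
  x_max + params$c * abs(x_min - x_max)
}

#' Detect swim bouts from an envelope
#'
#' Maximal runs of envelope above threshold are candidate bouts;
#' candidates separated by less than `merge_gap` are merged and
#' candidates shorter than `min_duration` dropped. Vigor statistics
#' (peak and integrated vigor) are computed over each interval when a
#' vigor trace is supplied.
#'
#' @param x envelope samples.
#' @param fs sampling rate (Hz).
#' @param th threshold (envelope units, finite).
#' @param params a [bout_params()].
#' @param vigor optional `vigor_trace` aligned with `x`.
#' @return data frame with `onset`, `offset` (s), `peak_vigor`,
#'   `power` (integrated vigor, a.u. * s); sorted, non-overlapping.
#' @export
detect_bouts <- function(x, fs, th, params = bout_params(), vigor = NULL) {
  assert_finite(th, "th")
  above <- x > th
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- starts[r$values]
  off <- ends[r$values]
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      peak_vigor = numeric(0), power = numeric(0))
  if (!length(on)) return(empty)
  # merge candidates separated by less than merge_gap
  gap_s <- if (length(on) > 1L) (on[-1L] - off[-length(off)] - 1L) / fs
           else numeric(0)
  keep_start <- c(TRUE, gap_s >= params$merge_gap)
  grp <- cumsum(keep_start)
  on <- tapply(on, grp, min)
  off <- tapply(off, grp, max)
  dur <- (off - on + 1L) / fs
  ok <- dur >= params$min_duration
  on <- on[ok]; off <- off[ok]
  if (!length(on)) return(empty)
  onset <- (on - 1L) / fs
  offset <- off / fs
  pk <- pw <- rep(NA_real_, length(on))
  if (!is.null(vigor)) {
    for (i in seq_along(on)) {
      seg <- vigor$m[on[i]:off[i]]
      pk[i] <- max(seg)
      pw[i] <- sum(seg) / fs
    }
  }
  data.frame(onset = as.numeric(onset), offset = as.numeric(offset),
             peak_vigor = pk, power = pw)
}

#' Full swim-detection pipeline on an ephys trace
#'
#' @param trace an `ephys_trace`.
#' @param params a [bout_params()].
#' @return data frame of detected bouts (see [detect_bouts()]).
#' @export
detect_swims <- function(trace, params = bout_params()) {
  x <- smoothed_envelope(trace$y, trace$fs, params)
  th <- auto_threshold(x, params)
  vig <- compute_vigor(trace)
  detect_bouts(x, trace$fs, th, params, vigor = vig)
}
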