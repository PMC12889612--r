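#' Synthesize a ventral-root-like electrophysiological trace
#'
#' Gaussian baseline noise plus, inside each swim bout, an
#' amplitude-modulated oscillatory burst whose carrier amplitude scales
#' with the bout's vigor. The burst envelope ramps on and off over 10%
#' of the bout so onsets are sharp but not discontinuous.
#'
#' @param bouts data frame with columns `onset`, `offset` (s) and
#'   optionally `vigor` (a.u., default 1); must be sorted and
#'   non-overlapping.
#' @param fs_ephys sampling rate (Hz); 6000 matches the recording
#'   hardware, 1000 is a fast test mode.
#' @param noise_sd baseline noise SD (a.u.).
#' @param carrier_hz burst oscillation frequency (Hz, 30-80 typical).
#' @param am_hz rhythmic amplitude-modulation frequency within bursts
#'   (Hz); motor-nerve bursts wax and wane with the tail-beat rhythm
#'   rather than holding a constant amplitude.
#' @param amp_per_vigor carrier amplitude per unit vigor, in noise SD
#'   units times `noise_sd` (i.e. amplitude = vigor * amp_per_vigor *
#'   noise_sd); the burst SNR at vigor 1.
#' @param amp_jitter_sdlog lognormal sd of a per-bout amplitude factor:
#'   recorded burst amplitudes vary well beyond behavioral vigor
#'   (electrode coupling, bout type), which spreads the envelope
#'   histogram's burst mass across amplitudes.
#' @param duration trace duration (s); defaults to 1 s past the last
#'   bout.
#' @param seed RNG seed.
#' @return list of class `ephys_trace` with `y`, `fs`, `t0`.
#' @export
synth_ephys <- function(bouts, fs_ephys = 6000, noise_sd = 1,
                        carrier_hz = 60, am_hz = 15, amp_per_vigor = 5,
                        amp_jitter_sdlog = 0, duration = NULL,
                        seed = 1L) {
  if (fs_ephys <= 2 * carrier_hz) {
    stop("invalid argument: fs_ephys must exceed twice the carrier",
         call. = FALSE)
  }
  if (nrow(bouts) > 0) {
    if (is.unsorted(bouts$onset) ||
        any(bouts$onset[-1] < bouts$offset[-nrow(bouts)])) {
      stop("invalid argument: bouts must be sorted and non-overlapping",
           call. = FALSE)
    }
    if (any(bouts$offset <= bouts$onset)) {
      stop("invalid argument: bout offset must exceed onset", call. = FALSE)
    }
  }
  set.seed(seed)
  duration <- duration %||%
    (if (nrow(bouts)) max(bouts$offset) + 1 else 1)
  n <- round(duration * fs_ephys)
  y <- stats::rnorm(n, 0, noise_sd)
  vig <- bouts$vigor %||% rep(1, nrow(bouts))
  for (i in seq_len(nrow(bouts))) {
    i0 <- floor(bouts$onset[i] * fs_ephys) + 1L
    i1 <- min(n, ceiling(bouts$offset[i] * fs_ephys))
    if (i1 <= i0) next
    k <- i0:i1
    tt <- (k - i0) / fs_ephys
    dur <- tt[length(tt)]
    ramp <- pmin(1, pmin(tt, dur - tt) / (0.1 * dur))
    am <- if (am_hz > 0) {
      0.4 + 0.6 * abs(sin(pi * am_hz * tt + stats::runif(1, 0, pi)))
    } else 1
    amp <- vig[i] * amp_per_vigor * noise_sd *
      (if (amp_jitter_sdlog > 0) stats::rlnorm(1, 0, amp_jitter_sdlog)
       else 1)
    phase <- stats::runif(1, 0, 2 * pi)
    y[k] <- y[k] + amp * ramp * am * sin(2 * pi * carrier_hz * tt + phase)
  }
  structure(list(y = y, fs = fs_ephys, t0 = 0), class = "ephys_trace")
}
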