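# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("invalid argument: `%s` must be finite", what), call. = FALSE)
  }
  invisible(x)
}

assert_positive <- function(x, what) {
  assert_finite(x, what)
  if (any(x <= 0)) {
    stop(sprintf("invalid argument: `%s` must be > 0", what), call. = FALSE)
  }
  invisible(x)
}

#' Trapezoidal integral of a sampled trace
#'
#' @param t sample times (s), strictly increasing.
#' @param y sample values.
#' @return The trapezoid-rule integral of `y` over `t`.
#' @keywords internal
trapz <- function(t, y) {
  if (length(t) < 2L) return(0)
  sum(diff(t) * (y[-length(y)] + y[-1L]) / 2)
}

#' Centered sliding-window standard deviation
#'
#' Windows shrink at the edges so the output has the same length as the
#' input. Sample SD (n - 1 denominator); windows with fewer than two
#' samples yield 0.
#'
#' @param y numeric vector.
#' @param w window length in samples (>= 2).
#' @return numeric vector of the same length as `y`.
#' @keywords internal
sliding_sd <- function(y, w) {
  n <- length(y)
  half <- w %/% 2L
  idx <- seq_len(n)
  lo <- pmax(1L, idx - half)
  hi <- pmin(n, idx + half)
  cs <- cumsum(c(0, y))
  cs2 <- cumsum(c(0, y * y))
  m <- hi - lo + 1L
  s <- cs[hi + 1L] - cs[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  v <- (s2 - s * s / m) / (m - 1)
  v[m < 2L] <- 0
  sqrt(pmax(v, 0))
}

#' Rolling standard deviation over a time window
#'
#' @param y numeric trace.
#' @param fs sampling rate (Hz).
#' @param window window length (s), centered.
#' @return numeric vector, same length as `y`.
#' @export
rolling_sd <- function(y, fs, window = 4) {
  assert_positive(window, "window")
  w <- max(2L, round(window * fs))
  sliding_sd(y, w)
}

# Unit-area smoothing kernel. `width` is the kernel timescale in seconds:
# the Gaussian sigma (truncated at +/- 4 sigma) or the boxcar duration.
smoothing_kernel <- function(width, fs, shape = c("gaussian", "boxcar")) {
  shape <- match.arg(shape)
  assert_positive(width, "kernel width")
  if (shape == "gaussian") {
    h <- max(1L, ceiling(4 * width * fs))
    k <- exp(-0.5 * ((-h:h) / (width * fs))^2)
  } else {
    h <- max(1L, floor(width * fs / 2))
    k <- rep(1, 2L * h + 1L)
  }
  k / sum(k)
}

# Centered convolution with a unit-area kernel; near the edges the kernel
# is renormalized over the in-range samples so constants are preserved.
smooth_conv <- function(y, kernel) {
  n <- length(y)
  k <- length(kernel)
  if (n <= k) stop("trace shorter than smoothing kernel", call. = FALSE)
  num <- stats::filter(y, kernel, method = "convolution", sides = 2)
  den <- stats::filter(rep(1, n), kernel, method = "convolution", sides = 2)
  out <- as.numeric(num / den)
  h <- (k - 1L) %/% 2L
  for (i in which(is.na(out))) {
    j <- max(1L, i - h):min(n, i + h)
    kk <- kernel[j - i + h + 1L]
    out[i] <- sum(y[j] * kk) / sum(kk)
  }
  out
}

#' Spearman rank correlation with a p-value
#'
#' Average ranks for ties; the exact tie-free small-sample null when
#' available, otherwise the t-approximation. Degenerate (constant)
#' inputs return `rho = NA` and `p = 1`.
#'
#' @param x,y paired numeric vectors.
#' @return list with elements `rho` and `p`.
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = 1))
  }
  exact <- n < 30L && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}

# Rank-sum (Mann-Whitney) p-value: exact for combined n <= 20 without
# ties, normal approximation with continuity correction otherwise.
ranksum_p <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  if (stats::sd(c(x, y)) == 0) return(1)
  exact <- (length(x) + length(y)) <= 20L && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}

# Mean of samples falling into imaging-frame bins [k/fs, (k+1)/fs).
bin_to_frames <- function(y, t, fs_img, n_frames) {
  frame <- floor(t * fs_img) + 1L
  keep <- frame >= 1L & frame <= n_frames
  out <- rep(NA_real_, n_frames)
  sums <- tapply(y[keep], frame[keep], sum)
  cnts <- tapply(rep(1, sum(keep)), frame[keep], sum)
  idx <- as.integer(names(sums))
  out[idx] <- as.numeric(sums) / as.numeric(cnts)
  out
}

log_msg <- function(fmt, ...) {
  message(sprintf("[swimstate %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}
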