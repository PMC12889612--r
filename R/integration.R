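#' Discrete leaky integral with exact exponential-hold updates
#'
#' One-pole recursion `I_k = I_{k-1} exp(-dt/tau) + v_k tau (1 -
#' exp(-dt/tau))`, the exact solution for input held constant over each
#' step. As `tau` grows the update tends to `I_k = I_{k-1} + v_k dt`
#' (perfect integration).
#'
#' @param v input sampled at `1/dt` Hz.
#' @param dt step (s).
#' @param tau time constant (s, > 0).
#' @return integral trace, same length as `v`.
#' @export
leaky_integral <- function(v, dt, tau) {
  assert_positive(tau, "tau")
  a <- exp(-dt / tau)
  as.numeric(stats::filter(v * tau * (1 - a), a, method = "recursive"))
}

#' Fit the leaky-integrator model to a cell trace
#'
#' Fits `dF/F(t) = beta * I_tau(t) + sens * v(t) + init * exp(-t/tau)`
#' where `I_tau` is the discrete leaky integral of the flow velocity.
#' The `sens` term absorbs any direct (instantaneous) sensory response
#' so `tau` is identified from the accumulated component, and the
#' `init` term carries activity accumulated before the fit window (the
#' window opens at Probe onset, but an integrator retains part of its
#' Evoke drive through the Pause). The squared residual is minimized:
#' for each `tau` on a log-spaced grid the linear coefficients have a
#' closed-form least-squares solution, and the grid optimum is refined
#' by golden-section search on log tau. Indicator kinetics (~0.5 s)
#' are deliberately ignored, fast relative to the time constants of
#' interest. The fit is scale-equivariant: scaling the trace scales
#' `beta` and leaves `tau` unchanged. A pure leaky-integral trace is
#' recovered exactly (`sens = init = 0`).
#'
#' @param trace baseline-subtracted cell trace at imaging frames.
#' @param v flow velocity at the same frames.
#' @param fs_img frame rate (Hz).
#' @param tau_range grid range (s).
#' @param n_grid number of log-spaced grid points.
#' @return list with `beta`, `sens`, `init`, `tau`, `sse`, `converged`.
#' @export
fit_leaky_integrator <- function(trace, v, fs_img,
                                 tau_range = c(0.1, 100), n_grid = 64) {
  dt <- 1 / fs_img
  if (all(trace == 0) || stats::sd(trace) == 0) {
    return(list(beta = 0, sens = 0, init = 0, offset = 0,
                tau = NA_real_, sse = 0, converged = FALSE))
  }
  n <- length(trace)
  fit_at <- function(log_tau) {
    tau <- exp(log_tau)
    basis <- list(leaky_integral(v, dt, tau), v,
                  exp(-(seq_len(n) * dt) / tau), rep(1, n))
    for (keep in list(1:4, c(1L, 4L), 1L)) {
      X <- do.call(cbind, basis[keep])
      xtx <- crossprod(X)
      if (rcond(xtx) >= 1e-10) {
        cf0 <- numeric(4)
        cf0[keep] <- drop(solve(xtx, crossprod(X, trace)))
        return(list(beta = cf0[1], sens = cf0[2], init = cf0[3],
                    offset = cf0[4],
                    sse = sum((trace - X %*% cf0[keep])^2)))
      }
    }
    list(beta = 0, sens = 0, init = 0, offset = 0, sse = sum(trace^2))
  }
  grid <- seq(log(tau_range[1]), log(tau_range[2]), length.out = n_grid)
  sse <- vapply(grid, function(g) fit_at(g)$sse, numeric(1))
  i <- which.min(sse)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  opt <- stats::optimize(function(g) fit_at(g)$sse, c(lo, hi),
                         tol = 1e-6)
  # keep the grid point if refinement did not improve (flat boundary)
  log_tau <- if (opt$objective <= sse[i]) opt$minimum else grid[i]
  at <- fit_at(log_tau)
  list(beta = at$beta, sens = at$sens, init = at$init,
       offset = at$offset, tau = exp(log_tau), sse = at$sse,
       converged = TRUE)
}

#' Fluorescence at the last frame of each pulse ON and OFF interval
#'
#' Intervals are half-open. `off0` is the value at the last frame
#' preceding the first pulse (0 when no such frame exists).
#'
#' @param trace cell trace at frames.
#' @param t_frames frame times (s).
#' @param onsets pulse onset times (s).
#' @param pulse_on,pulse_off pulse ON/OFF durations (s).
#' @return list with vectors `on`, `off` and scalar `off0`.
#' @export
pulse_endpoints <- function(trace, t_frames, onsets,
                            pulse_on = 1, pulse_off = 1) {
  last_in <- function(a, b) {
    i <- frames_in(t_frames, a, b)
    if (!length(i)) {
      stop("format error: pulse interval [", a, ", ", b,
           ") shorter than one frame", call. = FALSE)
    }
    max(i)
  }
  on <- vapply(onsets, function(o) trace[last_in(o, o + pulse_on)],
               numeric(1))
  off <- vapply(onsets, function(o) {
    trace[last_in(o + pulse_on, o + pulse_on + pulse_off)]
  }, numeric(1))
  pre <- which(t_frames < onsets[1])
  off0 <- if (length(pre)) trace[max(pre)] else 0
  list(on = on, off = off, off0 = off0)
}

#' Inverse leakiness of integration
#'
#' Ratio of the fluorescence after the last (sixth) pulse to the
#' perfect-integrator prediction, the summed per-pulse increments:
#' `off_n / sum(on_i - off_{i-1})`. 1 for a perfect integrator, 0 for
#' a memoryless responder. A near-zero denominator (no net pulse
#' response) yields `NA` and the cell is excluded from leakiness
#' summaries.
#'
#' @param endpoints list from [pulse_endpoints()].
#' @param eps denominator tolerance.
#' @return dimensionless ratio, or `NA`.
#' @export
inverse_leakiness <- function(endpoints, eps = 1e-12) {
  on <- endpoints$on
  off <- endpoints$off
  prev_off <- c(endpoints$off0, off[-length(off)])
  den <- sum(on - prev_off)
  if (!is.finite(den) || abs(den) <= eps) return(NA_real_)
  off[length(off)] / den
}

#' Area under the curve of a single pulse response
#'
#' Trapezoidal integral of the trace over `[onset, onset + window]`
#' after subtracting the local baseline. The default baseline is the
#' linear trend through the last `n_base` frames preceding the pulse,
#' extrapolated across the window: slowly decaying activity carried
#' into the pulse (accumulated drive from earlier pulses or from the
#' Evoke epoch) is thereby cancelled and the area isolates the
#' pulse-locked response. `baseline = "pre_frame"` subtracts only the
#' value at the last pre-onset frame. Windows extending past the trace
#' are truncated with a warning.
#'
#' @param trace cell trace at frames.
#' @param t_frames frame times (s).
#' @param onset pulse onset (s).
#' @param window integration window (s); default one pulse period.
#' @param baseline "local_trend" (default) or "pre_frame".
#' @param n_base number of pre-onset frames defining the local trend.
#' @return area (dF/F * s).
#' @export
pulse_response_auc <- function(trace, t_frames, onset, window = 2,
                               baseline = c("local_trend", "pre_frame"),
                               n_base = 3) {
  baseline <- match.arg(baseline)
  if (onset + window > t_frames[length(t_frames)] + 1e-9) {
    warning("integration window truncated at end of trace")
  }
  idx <- which(t_frames >= onset & t_frames <= onset + window + 1e-9)
  if (length(idx) < 2) return(0)
  pre <- which(t_frames < onset)
  if (!length(pre)) {
    return(trapz(t_frames[idx], trace[idx]))
  }
  pre <- pre[max(1L, length(pre) - n_base + 1L):length(pre)]
  base <- if (baseline == "pre_frame" || length(pre) < 2) {
    rep(trace[max(pre)], length(idx))
  } else {
    cf <- stats::coef(stats::lm(trace[pre] ~ t_frames[pre]))
    cf[1] + cf[2] * t_frames[idx]
  }
  trapz(t_frames[idx], trace[idx] - base)
}

#' Pulse integration after removing the single-pulse response
#'
#' Subtracts a time-locked single-pulse template at each pulse onset
#' and trapezoid-integrates the residual over the first `n` pulse
#' periods: the accumulated (integrated) component of the response. A
#' memoryless cell whose every pulse response equals the template
#' leaves a residual near zero.
#'
#' @param trace baseline-centered cell trace at frames.
#' @param t_frames frame times (s).
#' @param onsets pulse onsets (s); the first `n` are used.
#' @param template single-pulse template values.
#' @param template_t template times relative to pulse onset (s).
#' @param period pulse period (s).
#' @param n number of pulses (default 6).
#' @return area (dF/F * s).
#' @export
pulse_integration_auc <- function(trace, t_frames, onsets, template,
                                  template_t, period = 2, n = 6) {
  if (max(template_t) > period + 1e-9) {
    stop("format error: template longer than one pulse period",
         call. = FALSE)
  }
  onsets <- onsets[seq_len(min(n, length(onsets)))]
  resid <- trace
  for (o in onsets) {
    idx <- frames_in(t_frames, o, o + period)
    if (!length(idx)) next
    tmpl <- stats::approx(template_t, template, xout = t_frames[idx] - o,
                          rule = 2)$y
    resid[idx] <- resid[idx] - tmpl
  }
  span <- which(t_frames >= onsets[1] &
                  t_frames <= onsets[1] + length(onsets) * period + 1e-9)
  if (length(span) < 2) return(0)
  trapz(t_frames[span], resid[span])
}

# condition labels for state comparisons: capsaicin vs control in
# chemogenetic sessions, Engaged vs Disengaged otherwise
condition_of_trials <- function(trials) {
  if (any(trials$capsaicin %||% FALSE)) {
    ifelse(trials$capsaicin, "Capsaicin", "Control")
  } else {
    ifelse(trials$label == "Engaged", "Engaged",
           ifelse(trials$label == "Disengaged", "Disengaged", NA))
  }
}

center_trial_trace <- function(trace, t_frames, trial,
                               baseline = c("pre_evoke_mean", "evoke_onset")) {
  baseline <- match.arg(baseline)
  b_idx <- if (baseline == "pre_evoke_mean") {
    frames_in(t_frames, trial$evoke_on - 2, trial$evoke_on)
  } else {
    i <- which(t_frames <= trial$evoke_on)
    if (length(i)) max(i) else integer(0)
  }
  if (!length(b_idx)) return(trace)
  trace - mean(trace[b_idx])
}

#' Per-cell, per-trial pulse-response table
#'
#' Pulse AUCs and ON/OFF endpoints for up to the first `n_pulses`
#' pulses preceding the probe-evoked swim, with traces centered on the
#' pre-Evoke baseline.
#'
#' @param session a `swim_session`.
#' @param trials trial table with `label`.
#' @param cell_ids cells to process (default: all).
#' @param n_pulses maximum pulse count per trial.
#' @param baseline baseline rule, see details in the fitting vignette.
#' @return data frame: cell_id, trial, condition, pulse_i, auc, on,
#'   off.
#' @export
pulse_table <- function(session, trials, cell_ids = NULL, n_pulses = 6,
                        baseline = "pre_evoke_mean") {
  tf <- session$neural$t_frames
  period <- 2
  cond <- condition_of_trials(trials)
  cell_ids <- cell_ids %||% seq_len(nrow(session$neural$dff))
  rows <- list()
  for (i in seq_len(nrow(trials))) {
    if (is.na(cond[i])) next
    tri <- trials[i, ]
    swim <- tri$probe_on + tri$latency
    k_max <- min(n_pulses, floor((swim - tri$probe_on) / period),
                 tri$n_pulses %||% n_pulses)
    if (k_max < 1) next
    onsets <- tri$probe_on + period * (seq_len(k_max) - 1)
    for (cid in cell_ids) {
      tr <- center_trial_trace(session$neural$dff[cid, ], tf, tri,
                               baseline)
      ep <- pulse_endpoints(tr, tf, onsets)
      auc <- vapply(onsets, function(o) {
        pulse_response_auc(tr, tf, o, window = period)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cid, trial = tri$trial, condition = cond[i],
        pulse_i = seq_len(k_max), auc = auc, on = ep$on, off = ep$off)
    }
  }
  do.call(rbind, rows)
}

#' Fit integration metrics per cell and condition
#'
#' For every requested cell, averages baseline-centered traces over the
#' early Probe epoch (first `window` seconds) across trials of each
#' condition, fits the leaky-integrator time constant, and computes the
#' inverse leakiness from pulse endpoints of the averaged trace.
#'
#' @param session a `swim_session`.
#' @param trials trial table.
#' @param cell_ids cells to fit.
#' @param window early-Probe window (s); 12 s covers six pulses.
#' @return data frame: cell_id, condition, beta, tau, sse, converged,
#'   inv_leakiness, integration_auc (template-subtraction residual) and
#'   model_auc (area of the fitted accumulated component, the robust
#'   summary on noisy session averages).
#' @export
fit_integration <- function(session, trials, cell_ids, window = 12) {
  tf <- session$neural$t_frames
  fs_img <- session$neural$fs_img
  period <- 2
  cond <- condition_of_trials(trials)
  use <- !is.na(cond) & (trials$latency > window | trials$censored)
  conds <- unique(cond[use])
  if (!length(conds)) return(NULL)
  # pass the velocity regressor through the indicator kinetics so it
  # shares the measurement's lag; leaky integration and the indicator
  # convolution commute, so tau is unaffected
  popc <- session$config$population
  vflow_f <- bin_to_frames(
    convolve_indicator(session$stimulus$v_flow, 1 / session$stimulus$fs,
                       popc$indicator_decay %||% 0.5,
                       popc$indicator_rise %||% 0.05),
    session$stimulus$t, fs_img, length(tf))
  # the fit window opens 8 s before the Probe (the equalized pre-Probe
  # quiescence): the largely drive-free stretch pins down the
  # carried-over component that would otherwise be confounded with
  # slow integration over a probe-only window
  n_pre <- 8
  n_rel <- floor((n_pre + window) * fs_img)
  t_rel <- (seq_len(n_rel) - 0.5) / fs_img - n_pre
  onsets <- period * (0:(floor(window / period) - 1))

  # condition-averaged, probe-onset-aligned traces per cell
  avg_of <- function(cc, cid) {
    segs <- list(); vsegs <- list()
    for (i in which(use & cond == cc)) {
      tri <- trials[i, ]
      fi <- frames_in(tf, tri$probe_on - n_pre, tri$probe_on + window)
      if (length(fi) < n_rel) next
      fi <- fi[seq_len(n_rel)]
      tr <- center_trial_trace(session$neural$dff[cid, ], tf, tri)
      segs[[length(segs) + 1L]] <- tr[fi]
      vsegs[[length(vsegs) + 1L]] <- vflow_f[fi]
    }
    if (length(segs) < 2) return(NULL)
    list(y = colMeans(do.call(rbind, segs)),
         v = colMeans(do.call(rbind, vsegs)))
  }

  ref_cond <- if ("Engaged" %in% conds) "Engaged" else
    if ("Control" %in% conds) "Control" else conds[1]
  tmpl_idx <- frames_in(t_rel, 0, period)

  # remove the fitted pre-window carry-over before integrating: that
  # component reflects Evoke-epoch drive, not probe-driven integration
  strip_carry <- function(av, ft) {
    if (!isTRUE(ft$converged) || !is.finite(ft$tau)) return(av$y)
    av$y - ft$offset - ft$init * exp(-(seq_len(n_rel) / fs_img) / ft$tau)
  }
  rows <- list()
  for (cid in cell_ids) {
    ref <- avg_of(ref_cond, cid)
    ref_ft <- if (!is.null(ref)) fit_leaky_integrator(ref$y, ref$v, fs_img)
    ref_adj <- if (!is.null(ref)) strip_carry(ref, ref_ft)
    for (cc in conds) {
      av <- if (cc == ref_cond) ref else avg_of(cc, cid)
      if (is.null(av)) next
      ft <- if (cc == ref_cond) ref_ft else
        fit_leaky_integrator(av$y, av$v, fs_img)
      y_adj <- if (cc == ref_cond) ref_adj else strip_carry(av, ft)
      ep <- pulse_endpoints(av$y, t_rel, onsets)
      tmpl <- if (!is.null(ref_adj)) ref_adj[tmpl_idx] else y_adj[tmpl_idx]
      int_auc <- pulse_integration_auc(y_adj, t_rel, onsets,
                                       template = tmpl,
                                       template_t = t_rel[tmpl_idx],
                                       period = period)
      model_auc <- if (isTRUE(ft$converged) && is.finite(ft$tau)) {
        trapz(t_rel, ft$beta * leaky_integral(av$v, 1 / fs_img, ft$tau))
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cid, condition = cc, beta = ft$beta, tau = ft$tau,
        sse = ft$sse, converged = ft$converged,
        inv_leakiness = inverse_leakiness(ep),
        integration_auc = int_auc, model_auc = model_auc)
    }
  }
  do.call(rbind, rows)
}
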