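#' Closed-loop stimulus update
#'
#' The virtual-reality rule coupling swimming to visual feedback: the
#' grating velocity seen by the fish is the imposed flow minus the
#' fish's motor output scaled by the motosensory gain,
#' `v_stim = v_flow - m * G_ms`. Gain zero is the open-loop (futile)
#' condition in which swimming no longer affects the stimulus.
#'
#' @param v_flow imposed flow velocity (mm/s).
#' @param m swim vigor (a.u., >= 0).
#' @param G_ms motosensory gain (mm/s per vigor unit).
#' @return stimulus velocity `v_flow - m * G_ms` (mm/s).
#' @export
closed_loop_step <- function(v_flow, m, G_ms) {
  assert_finite(c(v_flow, m, G_ms), "closed_loop_step inputs")
  if (any(m < 0)) stop("invalid argument: vigor m must be >= 0", call. = FALSE)
  v_flow - m * G_ms
}

#' One update of the latent astrocytic state
#'
#' First-order leaky integration of futile swim vigor: the state decays
#' exponentially with time constant `tau_a` and is incremented by
#' `gain_k * m * dt` whenever swimming is futile. In `calex` mode
#' (astrocytic calcium extrusion) the state is clamped at zero.
#'
#' @param s current state (>= 0).
#' @param m swim vigor (a.u.).
#' @param futile logical; is the current swimming futile?
#' @param dt step size (s).
#' @param tau_a decay time constant (s).
#' @param gain_k state increment per unit futile vigor.
#' @param mode "normal" or "calex".
#' @return updated state.
#' @export
astro_state_step <- function(s, m, futile, dt, tau_a, gain_k,
                             mode = "normal") {
  if (!is.finite(tau_a) || tau_a <= 0) {
    stop("invalid argument: tau_a must be > 0", call. = FALSE)
  }
  if (any(s < 0) || dt <= 0) {
    stop("invalid argument: need s >= 0 and dt > 0", call. = FALSE)
  }
  if (mode == "calex") return(0 * s)
  s * exp(-dt / tau_a) + ifelse(futile, gain_k * m * dt, 0)
}

round_to_grid <- function(x, fs) round(x * fs) / fs

# Engaged bout train on [from, to): gaps U(gap_min, gap_max), lognormal
# vigor; if `close_at_end`, the final bout is forced to end exactly at
# `to` (the fish swims up to the epoch transition).
gen_bout_train <- function(from, to, st, fs, close_at_end = FALSE) {
  onsets <- numeric(0)
  tcur <- from
  repeat {
    onset <- round_to_grid(tcur + stats::runif(1, st$gap_min, st$gap_max), fs)
    if (onset + st$bout_dur > to) break
    onsets <- c(onsets, onset)
    tcur <- onset + st$bout_dur
  }
  if (close_at_end) {
    forced <- round_to_grid(to - st$bout_dur, fs)
    if (length(onsets) && forced < onsets[length(onsets)] + st$bout_dur) {
      onsets <- onsets[-length(onsets)]
    }
    onsets <- c(onsets, forced)
  }
  n <- length(onsets)
  data.frame(onset = onsets,
             offset = round_to_grid(onsets + st$bout_dur, fs),
             vigor = stats::rlnorm(n,
                                   log(st$vigor_mu) - st$vigor_cv^2 / 2,
                                   st$vigor_cv))
}

# Futility accumulator advanced over one bout (grid recursion at dt).
accumulate_futility <- function(f, m, dur, dt, tau_a, gain_k) {
  for (i in seq_len(round(dur / dt))) {
    f <- f * exp(-dt / tau_a) + gain_k * m * dt
  }
  f
}

#' Simulate the swim agent through the full trial paradigm
#'
#' Generates a complete behavioral session: swim bouts, the stimulus
#' velocity under the closed-loop rule, the latent internal-state
#' trace, and per-trial records. Trials alternate Effective (closed-loop
#' Evoke) and Futile (open-loop Evoke until futility-induced passivity,
#' defined as `passivity_window` seconds without swimming). During the
#' Probe epoch the agent leakily integrates stimulus velocity with the
#' state-dependent time constant `tau(s)` and produces a probe-evoked
#' swim when the integral crosses a lognormally jittered bound, so
#' latencies are stochastically longer when the state is high. In
#' `trpv1` mode all trials are closed-loop and the state is instead
#' forced high on alternating "capsaicin" trials.
#'
#' @param paradigm a [paradigm_config()].
#' @param state a [state_params()].
#' @param seed integer RNG seed; identical seeds give bitwise-identical
#'   sessions.
#' @return list with elements `t`, `v_flow`, `v_stim`, `g_ms`, `vigor`,
#'   `s`, `readiness`, `bouts` (data frame), `trials` (data frame),
#'   `fs`, `paradigm`, `state`.
#' @export
simulate_swim_agent <- function(paradigm = paradigm_config(),
                                state = state_params(),
                                seed = 1L) {
  pc <- paradigm
  st <- state
  set.seed(seed)
  fs <- pc$fs_beh
  dt <- 1 / fs
  period <- pc$pulse_on + pc$pulse_off
  mode <- st$mode

  bouts <- list()
  trials <- list()
  evidence <- list()  # per trial: evidence trajectory and bound
  tcur <- 0
  f <- 0   # futility accumulator
  f_t <- 0 # time at which f was last updated

  if (pc$n_trials == 0) {
    stop("invalid argument: n_trials must be > 0 to simulate", call. = FALSE)
  }

  for (tr in seq_len(pc$n_trials)) {
    if (mode == "trpv1") {
      type <- "Effective"
      capsaicin <- tr %% 2 == 0
    } else {
      type <- if (tr %% 2 == 1) "Effective" else "Futile"
      capsaicin <- FALSE
    }
    pre_on <- tcur
    pre_dur <- round_to_grid(stats::runif(1, pc$pre_min, pc$pre_max), fs)
    evoke_on <- pre_on + pre_dur

    if (type == "Effective") {
      evoke_dur <- round_to_grid(stats::runif(1, pc$evoke_min, pc$evoke_max), fs)
      evoke_off <- evoke_on + evoke_dur
      tb <- gen_bout_train(pre_on, evoke_off, st, fs, close_at_end = TRUE)
      tb$futile <- FALSE
      last_swim_off <- evoke_off
      pause_dur <- pc$pause_effective
    } else {
      # pre-epoch closed-loop swimming, then open-loop Evoke
      tb_pre <- gen_bout_train(pre_on, evoke_on, st, fs)
      tb_pre$futile <- FALSE
      onsets <- numeric(0); offs <- numeric(0); vigs <- numeric(0)
      tb2 <- evoke_on
      gave_up <- FALSE
      repeat {
        onset <- round_to_grid(tb2 + stats::runif(1, st$gap_min, st$gap_max), fs)
        if (onset + st$bout_dur > evoke_on + pc$evoke_futile_max) break
        vig <- stats::rlnorm(1, log(st$vigor_mu) - st$vigor_cv^2 / 2,
                             st$vigor_cv)
        # decay since the last update, accumulate over the bout
        f <- f * exp(-(onset - f_t) / st$tau_a)
        f <- accumulate_futility(f, vig, st$bout_dur, dt, st$tau_a, st$gain_k)
        f_t <- onset + st$bout_dur
        onsets <- c(onsets, onset)
        offs <- c(offs, round_to_grid(onset + st$bout_dur, fs))
        vigs <- c(vigs, vig)
        tb2 <- onset + st$bout_dur
        if (f >= st$s_thresh) { gave_up <- TRUE; break }
      }
      tb <- rbind(tb_pre,
                  data.frame(onset = onsets, offset = offs, vigor = vigs,
                             futile = TRUE))
      if (gave_up) {
        last_swim_off <- offs[length(offs)]
        evoke_off <- round_to_grid(last_swim_off + pc$passivity_window, fs)
      } else {  # Perseverant: swam through to the Pause transition
        last_swim_off <- if (length(offs)) offs[length(offs)] else evoke_on
        evoke_off <- round_to_grid(evoke_on + pc$evoke_futile_max, fs)
      }
      pause_dur <- pc$pause_futile
    }

    pause_on <- evoke_off
    pause_off <- round_to_grid(pause_on + pause_dur, fs)
    probe_on <- pause_off
    f <- f * exp(-(probe_on - f_t) / st$tau_a)
    f_t <- probe_on

    # --- Probe: evidence integration to a noisy bound ---
    s_probe <- switch(mode,
                      normal = f,
                      calex = 0,
                      trpv1 = if (capsaicin) st$trpv1_level else 0)
    bound_i <- st$bound * stats::rlnorm(1, -st$bound_cv^2 / 2, st$bound_cv)
    n_steps <- round(pc$probe_cap * fs)
    Etr <- numeric(n_steps)
    E <- 0
    s_now <- s_probe
    cross <- NA_real_
    for (k in seq_len(n_steps)) {
      tk <- (k - 1) * dt
      on_pulse <- (tk %% period) < pc$pulse_on
      v <- if (on_pulse) pc$v_flow_probe else 0
      tau_k <- tau_of_state(s_now, st$tau_engaged, st$tau_disengaged)
      E <- E * exp(-dt / tau_k) + v * tau_k * (1 - exp(-dt / tau_k))
      Etr[k] <- E
      if (mode == "normal" || mode == "calex") {
        s_now <- s_now * exp(-dt / st$tau_a)
      }
      if (is.na(cross) && E >= bound_i) {
        cross <- tk
        break
      }
    }
    censored <- is.na(cross)
    latency <- if (censored) pc$probe_cap else cross
    probe_dur <- if (censored) pc$probe_cap else
      min(pc$probe_cap, period * ceiling((latency + st$bout_dur) / period))
    probe_dur <- round_to_grid(probe_dur, fs)
    probe_off <- probe_on + probe_dur

    if (!censored) {
      tb <- rbind(tb, data.frame(onset = round_to_grid(probe_on + latency, fs),
                                 offset = round_to_grid(probe_on + latency +
                                                          st$bout_dur, fs),
                                 vigor = stats::rlnorm(1,
                                   log(st$vigor_mu) - st$vigor_cv^2 / 2,
                                   st$vigor_cv),
                                 futile = FALSE))
    }
    tb$trial <- tr
    bouts[[tr]] <- tb
    evidence[[tr]] <- list(probe_on = probe_on, E = Etr, bound = bound_i,
                           n = if (censored) n_steps else round(cross / dt) + 1L)

    trials[[tr]] <- data.frame(
      trial = tr, type = type, capsaicin = capsaicin,
      pre_on = pre_on, evoke_on = evoke_on, evoke_off = evoke_off,
      pause_on = pause_on, pause_off = pause_off,
      probe_on = probe_on, probe_off = probe_off,
      n_pulses = round(probe_dur / period),
      latency = latency, censored = censored,
      s_probe = s_probe, bound = bound_i,
      last_evoke_swim_off = last_swim_off)

    tcur <- probe_off + pc$iti
  }

  bouts <- do.call(rbind, bouts)
  bouts <- bouts[order(bouts$onset), ]
  rownames(bouts) <- NULL
  trials <- do.call(rbind, trials)

  # --- grid traces ---
  n <- round(tcur * fs)
  tgrid <- (seq_len(n) - 1L) * dt
  v_flow <- numeric(n)
  g_ms <- rep(pc$G_ms, n)
  for (i in seq_len(nrow(trials))) {
    tri <- trials[i, ]
    seg <- function(a, b) which(tgrid >= a - dt / 2 & tgrid < b - dt / 2)
    v_flow[seg(tri$evoke_on, tri$evoke_off)] <- pc$v_flow_evoke
    if (tri$type == "Futile") g_ms[seg(tri$evoke_on, tri$evoke_off)] <- 0
    pr <- seg(tri$probe_on, tri$probe_off)
    tp <- tgrid[pr] - tri$probe_on
    v_flow[pr] <- ifelse((tp %% period) < pc$pulse_on, pc$v_flow_probe, 0)
  }
  vigor <- numeric(n)
  futile_tr <- logical(n)
  for (i in seq_len(nrow(bouts))) {
    idx <- which(tgrid >= bouts$onset[i] - dt / 2 &
                   tgrid < bouts$offset[i] - dt / 2)
    vigor[idx] <- bouts$vigor[i]
    futile_tr[idx] <- bouts$futile[i]
  }
  v_stim <- closed_loop_step(v_flow, vigor, g_ms)

  s <- numeric(n)
  if (mode != "calex") {
    decay <- exp(-dt / st$tau_a)
    sc <- 0
    inc <- st$gain_k * vigor * dt * futile_tr
    for (k in seq_len(n)) {
      sc <- sc * decay + inc[k]
      s[k] <- sc
    }
    if (mode == "trpv1") {
      for (i in which(trials$capsaicin)) {
        idx <- which(tgrid >= trials$pause_on[i] - dt / 2 &
                       tgrid < trials$probe_off[i] - dt / 2)
        s[idx] <- st$trpv1_level
      }
    }
  }

  # recovery readiness: a linear ramp over the amp_lead seconds before
  # the probe-evoked swim (0 on censored trials), the generative
  # stand-in for the progressive pre-recovery amplification
  readiness <- numeric(n)
  for (i in seq_len(nrow(trials))) {
    if (trials$censored[i]) next
    swim <- trials$probe_on[i] + trials$latency[i]
    idx <- which(tgrid >= trials$probe_on[i] - dt / 2 &
                   tgrid < trials$probe_off[i] - dt / 2)
    readiness[idx] <- pmax(0, pmin(1, 1 - (swim - tgrid[idx]) / st$amp_lead))
  }

  list(t = tgrid, v_flow = v_flow, v_stim = v_stim, g_ms = g_ms,
       vigor = vigor, s = s, readiness = readiness,
       bouts = bouts, trials = trials, fs = fs,
       paradigm = pc, state = st)
}
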