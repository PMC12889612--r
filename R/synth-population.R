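#' Calcium-indicator impulse response
#'
#' Difference-of-exponentials kernel (rise ~50 ms, decay ~500 ms)
#' normalized to unit area, so a sustained unit-rate input converges to
#' a fluorescence of 1.
#'
#' @param t times (s, >= 0).
#' @param decay,rise kernel time constants (s).
#' @return kernel values at `t`.
#' @export
indicator_kernel <- function(t, decay = 0.5, rise = 0.05) {
  assert_positive(c(decay, rise), "kernel time constants")
  (exp(-t / decay) - exp(-t / rise)) / (decay - rise)
}

#' Convolve a latent rate with the indicator kernel
#'
#' Implemented with two O(n) recursive exponential filters (exact for
#' the difference-of-exponentials kernel up to the step
#' discretization), so the operation is linear in the input.
#'
#' @param x latent rate sampled at `1/dt` Hz.
#' @param dt sample interval (s).
#' @param decay,rise kernel time constants (s).
#' @return fluorescence trace, same length as `x`.
#' @export
convolve_indicator <- function(x, dt, decay = 0.5, rise = 0.05) {
  ed <- stats::filter(x * dt, exp(-dt / decay), method = "recursive")
  er <- stats::filter(x * dt, exp(-dt / rise), method = "recursive")
  as.numeric(ed - er) / (decay - rise)
}

# Exact-hold leaky integration with a time-varying time constant.
leaky_integrate_varying <- function(v, tau, dt) {
  n <- length(v)
  out <- numeric(n)
  I <- 0
  for (k in seq_len(n)) {
    a <- exp(-dt / tau[k])
    I <- I * a + v[k] * tau[k] * (1 - a)
    out[k] <- I
  }
  out
}

POP_CLASSES <- c("sensory_pos", "sensory_neg", "integrator",
                 "motor_prep", "motor", "anti_motor", "other")

SENSORY_REGIONS <- c("TNR", "PT", "Hb", "DRN", "Cb", "IPN", "IO", "DCH")

assign_regions <- function(class) {
  n <- length(class)
  out <- character(n)
  k <- length(SENSORY_REGIONS)
  # sensory cells concentrate in early list entries, integrators in
  # late ones, giving regions a gradient of integrator fraction
  w_dec <- rev(seq_len(k)); w_inc <- seq_len(k)
  for (i in seq_len(n)) {
    out[i] <- switch(class[i],
      sensory_pos = sample(SENSORY_REGIONS, 1, prob = w_dec),
      integrator = sample(SENSORY_REGIONS, 1, prob = w_inc),
      sensory_neg = sample(SENSORY_REGIONS, 1),
      motor = sample(c("MO", "vHB"), 1),
      motor_prep = sample(c("vMB", "vHB"), 1),
      anti_motor = "L-MO",
      other = "misc")
  }
  out
}

#' Synthesize the neural population fluorescence matrix
#'
#' Builds one latent firing-rate trace per cell class from the
#' simulated behavior/stimulus/state, convolves with the indicator
#' kernel, bins to imaging frames, applies per-cell lognormal gains and
#' adds Gaussian noise. Classes: sensory-positive (pulse responses
#' dampened by the state), sensory-negative (pulse-locked dips strongly
#' suppressed by the state), integrator (leaky integration with
#' state-dependent tau), motor-preparatory (linear ramps leading swim
#' onsets), motor (vigor-driven), anti-motor (slow oscillation,
#' suppressed during swimming, with unreliable negative pulse responses
#' gated off at high state), and untuned noise cells.
#'
#' @param agent output of [simulate_swim_agent()].
#' @param pop a [population_config()].
#' @param seed RNG seed for gains, phases, reliability and noise.
#' @param classes character vector of classes to generate (default
#'   all); unknown names raise an error.
#' @return list with `dff` (cells x frames matrix), `t_frames` (frame
#'   bin centers, s), `cells` (data frame: cell_id, class, region,
#'   gain), `s_frames` (latent state per frame), `fs_img`.
#' @export
synth_population <- function(agent, pop = population_config(), seed = 1L,
                             classes = NULL) {
  classes <- classes %||% POP_CLASSES
  if (!all(classes %in% POP_CLASSES)) {
    stop("invalid argument: unknown class name(s): ",
         paste(setdiff(classes, POP_CLASSES), collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  dt <- 1 / agent$fs
  t <- agent$t
  n <- length(t)
  fs_img <- pop$fs_img
  n_frames <- floor(t[n] * fs_img)
  t_frames <- (seq_len(n_frames) - 0.5) / fs_img

  # downstream state effector: the astrocytic state acts on circuits
  # through a modulatory cascade that smooths over a couple of seconds,
  # so bout-locked state increments do not modulate responses within
  # the bout itself
  a_eff <- exp(-dt / pop$state_effector_tau)
  s_raw <- pmin(agent$s, 1)
  smod <- as.numeric(stats::filter(s_raw * (1 - a_eff), a_eff,
                                   method = "recursive", init = s_raw[1]))
  smin1 <- pmin(smod, 1)
  vpos <- pmax(agent$v_stim, 0) / agent$paradigm$v_flow_probe
  amp <- 1 + agent$state$amp_gain * agent$readiness
  swim <- agent$vigor > 0

  # probe pulse indicator (ON periods, all trials)
  pulse <- numeric(n)
  period <- agent$paradigm$pulse_on + agent$paradigm$pulse_off
  for (i in seq_len(nrow(agent$trials))) {
    tri <- agent$trials[i, ]
    idx <- which(t >= tri$probe_on - dt / 2 & t < tri$probe_off - dt / 2)
    tp <- t[idx] - tri$probe_on
    pulse[idx] <- as.numeric((tp %% period) < agent$paradigm$pulse_on)
  }

  conv_frame <- function(x) {
    f <- convolve_indicator(x, dt, pop$indicator_decay, pop$indicator_rise)
    bin_to_frames(f, t, fs_img, n_frames)
  }

  latents <- list()
  if ("sensory_pos" %in% classes) {
    latents$sensory_pos <- conv_frame(vpos * (1 - pop$sensory_depth * smin1) * amp)
  }
  if ("sensory_neg" %in% classes) {
    latents$sensory_neg <- conv_frame(
      1 - pulse * (1 - pop$negative_suppression * smin1))
  }
  if ("integrator" %in% classes) {
    tau_t <- tau_of_state(agent$s, pop$tau_engaged, pop$tau_disengaged)
    # sensory-integrative cells mix direct (state-dampened) sensory
    # drive with its leaky temporal integral: their immediate pulse
    # responses inherit the mild sensory suppression while the
    # accumulated component collapses with tau(s)
    drive <- vpos * (1 - pop$sensory_depth * smin1)
    I <- leaky_integrate_varying(drive, tau_t, dt)
    latents$integrator <- conv_frame(
      pop$integrator_sensory_mix * drive +
        (1 - pop$integrator_sensory_mix) * I / pop$tau_engaged)
  }
  if ("motor_prep" %in% classes) {
    ramp <- numeric(n)
    b <- agent$bouts
    prev_off <- -Inf
    for (i in seq_len(nrow(b))) {
      lead0 <- max(prev_off, b$onset[i] - pop$prep_ramp_lead)
      idx <- which(t >= lead0 - dt / 2 & t < b$onset[i] - dt / 2)
      if (length(idx)) {
        ramp[idx] <- (t[idx] - lead0) / pop$prep_ramp_lead
      }
      prev_off <- b$offset[i]
    }
    latents$motor_prep <- conv_frame(ramp)
  }
  if ("motor" %in% classes) {
    latents$motor <- conv_frame(agent$vigor / agent$state$vigor_mu)
  }
  if ("other" %in% classes) latents$other <- rep(0, n_frames)

  counts <- pop$class_counts[classes]
  cells <- data.frame(
    cell_id = seq_len(sum(counts)),
    class = rep(names(counts), counts),
    stringsAsFactors = FALSE)
  cells$gain <- stats::rlnorm(nrow(cells), -pop$gain_cv^2 / 2, pop$gain_cv)
  cells$region <- assign_regions(cells$class)

  dff <- matrix(0, nrow(cells), n_frames)
  for (i in seq_len(nrow(cells))) {
    cl <- cells$class[i]
    if (cl == "anti_motor") {
      phase <- stats::runif(1, 0, 2 * pi)
      osc <- 1 + 0.5 * sin(2 * pi * t / pop$lmo_period + phase)
      osc[swim] <- osc[swim] * 0.2
      # unreliable pulse-locked dips, gated off at high state
      rel <- pulse
      on_edges <- which(diff(c(0, pulse)) == 1)
      drop <- on_edges[stats::runif(length(on_edges)) > pop$lmo_reliability]
      for (e in drop) {
        j <- e
        while (j <= n && pulse[j] == 1) { rel[j] <- 0; j <- j + 1L }
      }
      lat <- osc - 0.8 * rel * (1 - smin1)
      dff[i, ] <- cells$gain[i] * conv_frame(lat)
    } else {
      dff[i, ] <- cells$gain[i] * latents[[cl]]
    }
  }
  if (pop$noise_sd > 0) {
    dff <- dff + matrix(stats::rnorm(length(dff), 0, pop$noise_sd),
                        nrow(dff))
  }
  rownames(dff) <- cells$cell_id

  list(dff = dff, t_frames = t_frames, cells = cells,
       s_frames = bin_to_frames(agent$s, t, fs_img, n_frames),
       fs_img = fs_img)
}
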