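#' Virtual-reality paradigm configuration
#'
#' Parameters of the Effective/Futile trial paradigm. Trials begin with a
#' short closed-loop settling period, an Evoke epoch (closed loop on
#' Effective trials; open loop, i.e. motosensory gain 0, on Futile
#' trials), a Pause epoch with no flow, and a Probe epoch presenting 1 s
#' forward-motion pulses alternating with 1 s of no motion. On Futile
#' trials the Pause (3 s) begins once the fish has been passive for the
#' passivity window (5 s), so pre-Probe quiescence is 8 s on both trial
#' types; on Effective trials the Pause itself lasts 8 s.
#'
#' @param v_flow_evoke grating flow speed during Evoke (mm/s).
#' @param v_flow_probe pulse flow speed during Probe (mm/s); the default
#'   is a factor 2.5 slower than `v_flow_evoke`.
#' @param G_ms motosensory gain (mm/s of visual feedback per unit vigor).
#' @param pulse_on,pulse_off Probe pulse ON/OFF durations (s).
#' @param pause_effective Pause duration on Effective trials (s).
#' @param pause_futile Pause duration on Futile trials (s).
#' @param passivity_window no-swim interval defining passivity (s).
#' @param probe_cap maximum Probe duration (s).
#' @param n_trials number of trials (alternating Effective/Futile).
#' @param isi_engaged_max maximum inter-swim interval consistent with an
#'   engaged fish (s).
#' @param pre_min,pre_max closed-loop settling duration range (s).
#' @param evoke_min,evoke_max Effective-trial Evoke duration range (s).
#' @param evoke_futile_max cap on the open-loop Evoke epoch (s); a fish
#'   still swimming at the cap yields a Perseverant trial.
#' @param iti inter-trial interval (s).
#' @param fs_beh behavioral/stimulus simulation rate (Hz).
#' @return A validated list of class `paradigm_config`.
#' @export
paradigm_config <- function(v_flow_evoke = 10,
                            v_flow_probe = v_flow_evoke / 2.5,
                            G_ms = 8,
                            pulse_on = 1,
                            pulse_off = 1,
                            pause_effective = 8,
                            pause_futile = 3,
                            passivity_window = 5,
                            probe_cap = 60,
                            n_trials = 20,
                            isi_engaged_max = 3,
                            pre_min = 3, pre_max = 6,
                            evoke_min = 10, evoke_max = 16,
                            evoke_futile_max = 40,
                            iti = 3,
                            fs_beh = 100) {
  cfg <- as.list(environment())
  durs <- c(pulse_on, pulse_off, pause_effective, pause_futile,
            passivity_window, probe_cap, iti, evoke_futile_max)
  assert_positive(durs, "paradigm durations")
  assert_finite(c(v_flow_evoke, v_flow_probe, G_ms), "velocities and gain")
  if (n_trials < 0) stop("invalid argument: n_trials must be >= 0", call. = FALSE)
  if (abs(pause_futile + passivity_window - pause_effective) > 1e-9) {
    stop("quiescence equalization violated: pause_futile + passivity_window ",
         "must equal pause_effective", call. = FALSE)
  }
  if (probe_cap < pulse_on + pulse_off) {
    stop("probe_cap must cover at least one pulse period", call. = FALSE)
  }
  structure(cfg, class = "paradigm_config")
}

#' Latent-state and swim-agent parameters
#'
#' The latent internal state `s` is a first-order leaky integrator of
#' futile swim vigor (decay `tau_a`, increment `gain_k` per unit vigor
#' per second). Giving-up (passivity) is triggered when the futility
#' accumulator crosses `s_thresh`. During the Probe epoch the agent
#' leakily integrates stimulus velocity with a state-dependent time
#' constant and initiates a swim when the integral crosses a noisy
#' bound; `bound` and `bound_cv` are calibrated so that default-mode
#' latencies bracket the Engaged/Disengaged means the paradigm is built
#' to reproduce.
#'
#' In `calex` mode the astrocytic state is clamped to zero (calcium
#' extrusion); the futility accumulator still drives scripted passivity
#' so the trial structure is matched. In `trpv1` mode the state is
#' forced to `trpv1_level` throughout Pause and Probe on "capsaicin"
#' trials regardless of behavior.
#'
#' @param tau_a state decay time constant (s).
#' @param gain_k state increment per unit futile vigor (1/s scale).
#' @param s_thresh futility threshold triggering passivity.
#' @param bound evidence bound for the probe-evoked swim (mm).
#' @param bound_cv lognormal coefficient of variation of the bound
#'   across trials.
#' @param tau_engaged,tau_disengaged integration time constants (s) used
#'   by the agent's probe evidence integrator at state 0 and 1.
#' @param bout_dur swim bout duration (s).
#' @param gap_min,gap_max inter-bout gap range while engaged (s).
#' @param vigor_mu,vigor_cv lognormal bout-vigor parameters (a.u.).
#' @param mode one of "normal", "calex", "trpv1".
#' @param trpv1_level forced state level in trpv1 mode.
#' @param amp_gain recovery-linked amplification: sensory gain grows by
#'   this factor times the recovery readiness, a linear ramp from 0 to
#'   1 over the `amp_lead` seconds preceding the probe-evoked swim.
#' @param amp_lead lead time (s) of the recovery ramp.
#' @return A validated list of class `state_params`.
#' @export
state_params <- function(tau_a = 28,
                         gain_k = 0.65,
                         s_thresh = 1,
                         bound = 18.2,
                         bound_cv = 0.15,
                         tau_engaged = 11.2,
                         tau_disengaged = 5.9,
                         bout_dur = 0.3,
                         gap_min = 0.5, gap_max = 2,
                         vigor_mu = 1, vigor_cv = 0.25,
                         mode = c("normal", "calex", "trpv1"),
                         trpv1_level = 0.9,
                         amp_gain = 0.5,
                         amp_lead = 14) {
  mode <- match.arg(mode)
  cfg <- as.list(environment())
  assert_positive(c(tau_a, bound, bout_dur, vigor_mu, s_thresh),
                  "state parameters")
  if (gap_min <= 0 || gap_max < gap_min) {
    stop("invalid argument: need 0 < gap_min <= gap_max", call. = FALSE)
  }
  structure(cfg, class = "state_params")
}

#' Synthetic neural population configuration
#'
#' Cell classes and effect sizes of the forward model producing the
#' cells-by-frames fluorescence matrix. Defaults follow the reported
#' population structure: 11% sensory-positive and 3% sensory-negative
#' cells, integration time constants of 11.2 s (Engaged) shortening to
#' 5.9 s (Disengaged), 17% sensory dampening, 82% suppression of
#' negative sensory responses, motor-preparatory ramps starting ~3 s
#' before swims, and a fast indicator (~0.5 s decay).
#'
#' @param n_cells total number of cells.
#' @param frac_sensory_pos,frac_sensory_neg fractions of sensory cells.
#' @param n_integrator,n_motor_prep,n_motor,n_anti_motor class counts;
#'   remaining cells are untuned noise cells.
#' @param tau_engaged,tau_disengaged integrator time constants (s) at
#'   state 0 and 1; tau(s) interpolates linearly.
#' @param sensory_depth fractional sensory dampening at full state.
#' @param integration_suppression reference fractional suppression of
#'   pulse integration at full state (emergent from the tau change; kept
#'   as the calibration target it parameterizes).
#' @param negative_suppression fractional suppression of negative
#'   sensory dips at full state.
#' @param state_effector_tau smoothing time constant (s) of the
#'   downstream effector translating the astrocytic state into circuit
#'   modulation.
#' @param integrator_sensory_mix weight of the direct sensory component
#'   in sensory-integrative cells (their integral component has weight
#'   one minus this); integration and sensory encoding form a
#'   continuum rather than disjoint classes.
#' @param prep_ramp_lead motor-preparatory ramp lead time (s).
#' @param indicator_decay,indicator_rise indicator kernel time
#'   constants (s).
#' @param noise_sd additive fluorescence noise SD (dF/F units).
#' @param fs_img imaging frame rate, 2 or 3 Hz.
#' @param mode generator mode, see [state_params()].
#' @param gain_cv lognormal spread of per-cell response gains.
#' @param lmo_period anti-motor slow-oscillation period (s).
#' @param lmo_reliability per-pulse probability of the anti-motor
#'   negative visual response.
#' @return A validated list of class `population_config`.
#' @export
population_config <- function(n_cells = 200,
                              frac_sensory_pos = 0.11,
                              frac_sensory_neg = 0.03,
                              n_integrator = 30,
                              n_motor_prep = 8,
                              n_motor = 30,
                              n_anti_motor = 10,
                              tau_engaged = 11.2,
                              tau_disengaged = 5.9,
                              sensory_depth = 0.17,
                              integration_suppression = 0.87,
                              negative_suppression = 0.82,
                              state_effector_tau = 2,
                              integrator_sensory_mix = 0.5,
                              prep_ramp_lead = 3,
                              indicator_decay = 0.5,
                              indicator_rise = 0.05,
                              noise_sd = 0.05,
                              fs_img = 3,
                              mode = c("normal", "calex", "trpv1"),
                              gain_cv = 0.2,
                              lmo_period = 8,
                              lmo_reliability = 0.5) {
  mode <- match.arg(mode)
  cfg <- as.list(environment())
  fr <- c(frac_sensory_pos, frac_sensory_neg, sensory_depth,
          integration_suppression, negative_suppression, lmo_reliability)
  if (any(fr < 0 | fr > 1)) {
    stop("invalid argument: fractions must lie in [0, 1]", call. = FALSE)
  }
  assert_positive(c(tau_engaged, tau_disengaged, indicator_decay,
                    indicator_rise, prep_ramp_lead), "time constants")
  if (!fs_img %in% c(2, 3)) {
    stop("invalid argument: fs_img must be 2 or 3 Hz", call. = FALSE)
  }
  n_sp <- round(frac_sensory_pos * n_cells)
  n_sn <- round(frac_sensory_neg * n_cells)
  n_other <- n_cells - n_sp - n_sn - n_integrator - n_motor_prep -
    n_motor - n_anti_motor
  if (n_other < 0) stop("class counts exceed n_cells", call. = FALSE)
  cfg$class_counts <- c(sensory_pos = n_sp, sensory_neg = n_sn,
                        integrator = n_integrator,
                        motor_prep = n_motor_prep, motor = n_motor,
                        anti_motor = n_anti_motor, other = n_other)
  structure(cfg, class = "population_config")
}

#' State-dependent integration time constant
#'
#' Linear interpolation between the Engaged and Disengaged time
#' constants; the state is clamped to [0, 1] for the mapping.
#'
#' @param s latent state value(s).
#' @param tau_engaged,tau_disengaged endpoints of the mapping (s).
#' @return time constant(s) in seconds.
#' @export
tau_of_state <- function(s, tau_engaged = 11.2, tau_disengaged = 5.9) {
  sc <- pmin(pmax(s, 0), 1)
  tau_engaged + sc * (tau_disengaged - tau_engaged)
}
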