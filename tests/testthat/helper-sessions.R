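# Cached session fixtures shared across test files; everything is
# generated in code from fixed seeds.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) assign(key, force(expr), .fixtures)
  .fixtures[[key]]
}

small_population <- function(mode = "normal", ...) {
  population_config(n_cells = 60, n_integrator = 10, n_motor_prep = 3,
                    n_motor = 10, n_anti_motor = 4, mode = mode, ...)
}

small_session <- function(seed = 101, mode = "normal", n_trials = 10) {
  cached(sprintf("ses_%s_%d_%d", mode, seed, n_trials),
         simulate_session(paradigm_config(n_trials = n_trials),
                          small_population(mode), seed = seed))
}

small_trials <- function(ses) {
  build_trials(ses$stimulus$epochs, ses$truth$bouts, paradigm_config())
}

default_cohort <- function(n_fish = 5, mode = "normal", seed = 2024) {
  cached(sprintf("cohort_%s_%d_%d", mode, n_fish, seed),
         simulate_cohort(n_fish,
                         population = population_config(mode = mode),
                         seed = seed))
}

# minimal hand-built agent for population-forward-model unit tests:
# quiescent fish, one Probe epoch of pulsed motion, prescribed state
toy_agent <- function(s_level = 0, duration = 30, probe_on = 10,
                      n_pulses = 6, fs = 100, v_probe = 4,
                      amp_gain = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  v_flow <- numeric(length(t))
  rel <- t - probe_on
  on <- rel >= 0 & rel < 2 * n_pulses & (rel %% 2) < 1
  v_flow[on] <- v_probe
  trials <- data.frame(
    trial = 1L, type = "Effective", capsaicin = FALSE,
    pre_on = 0, evoke_on = 2, evoke_off = probe_on - 8,
    pause_on = probe_on - 8, pause_off = probe_on,
    probe_on = probe_on, probe_off = probe_on + 2 * n_pulses,
    n_pulses = n_pulses, latency = 2 * n_pulses, censored = TRUE,
    s_probe = s_level, bound = 1, last_evoke_swim_off = probe_on - 8)
  st <- state_params(amp_gain = amp_gain)
  list(t = t, v_flow = v_flow, v_stim = v_flow,
       g_ms = rep(8, length(t)), vigor = numeric(length(t)),
       s = rep(s_level, length(t)), readiness = numeric(length(t)),
       bouts = data.frame(onset = numeric(0), offset = numeric(0),
                          vigor = numeric(0), futile = logical(0),
                          trial = integer(0)),
       trials = trials, fs = fs,
       paradigm = paradigm_config(), state = st)
}
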