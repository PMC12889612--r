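SESSION_SCHEMA <- "1.0"

#' Simulate a complete synthetic session
#'
#' Runs the swim agent, optionally synthesizes the ventral-root trace,
#' and generates the neural population, returning one session container
#' holding behavior, stimulus, latent state, neural data and ground
#' truth. All randomness flows from `seed` through three named
#' substreams (behavior, ephys noise, calcium noise).
#'
#' @param paradigm a [paradigm_config()].
#' @param population a [population_config()]; its `mode` is applied to
#'   the agent as well.
#' @param state a [state_params()].
#' @param seed session seed.
#' @param ephys logical; synthesize the raw electrophysiological trace
#'   (skipped by default because analyses can start from ground-truth
#'   bouts).
#' @param fs_ephys ephys sampling rate (Hz).
#' @return list of class `swim_session`.
#' @export
simulate_session <- function(paradigm = paradigm_config(),
                             population = population_config(),
                             state = state_params(),
                             seed = 1L,
                             ephys = FALSE,
                             fs_ephys = 6000) {
  state$mode <- population$mode
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 3L)
  agent <- simulate_swim_agent(paradigm, state, seed = sub[1])
  neural <- synth_population(agent, population, seed = sub[3])
  eph <- NULL
  if (ephys) {
    eph <- synth_ephys(agent$bouts, fs_ephys = fs_ephys, seed = sub[2])
  }
  truth_trials <- agent$trials
  epochs <- truth_trials[, c("trial", "type", "capsaicin", "pre_on",
                             "evoke_on", "evoke_off", "pause_on",
                             "pause_off", "probe_on", "probe_off",
                             "n_pulses")]
  structure(list(
    schema = SESSION_SCHEMA,
    seed = seed,
    behavior = list(ephys = eph, vigor = agent$vigor,
                    bouts_true = agent$bouts),
    stimulus = list(t = agent$t, v_stim = agent$v_stim,
                    v_flow = agent$v_flow, g_ms = agent$g_ms,
                    epochs = epochs, fs = agent$fs),
    state = list(s = agent$s, readiness = agent$readiness),
    neural = neural,
    truth = list(trials = truth_trials, bouts = agent$bouts,
                 cells = neural$cells),
    config = list(paradigm = unclass(paradigm),
                  population = unclass(population),
                  state = unclass(state))
  ), class = "swim_session")
}

#' Simulate a cohort of fish
#'
#' @param n_fish number of fish (independent sessions).
#' @param seed base seed; fish i uses `seed * 1000 + i`.
#' @inheritParams simulate_session
#' @return list of `swim_session` objects.
#' @export
simulate_cohort <- function(n_fish = 5,
                            paradigm = paradigm_config(),
                            population = population_config(),
                            state = state_params(),
                            seed = 1L) {
  lapply(seq_len(n_fish), function(i) {
    fish_seed <- as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
    if (fish_seed == 0L) fish_seed <- 1L
    simulate_session(paradigm, population, state, seed = fish_seed)
  })
}

#' Write a session container to disk
#'
#' Directory layout mirroring the hierarchical dataset paths
#' (`behavior/`, `stimulus/`, `state/`, `neural/`, `truth/`) with a
#' JSON manifest carrying the schema version and the resolved
#' configuration.
#'
#' @param session a `swim_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "swim_session"))
  for (d in c("behavior", "stimulus", "state", "neural", "truth")) {
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  fw <- function(x, path) data.table::fwrite(x, file.path(dir, path))
  fw(data.frame(t = session$stimulus$t, vigor = session$behavior$vigor),
     "behavior/vigor.csv")
  fw(session$behavior$bouts_true, "behavior/bouts_true.csv")
  if (!is.null(session$behavior$ephys)) {
    fw(data.frame(y = session$behavior$ephys$y), "behavior/ephys.csv")
  }
  fw(data.frame(t = session$stimulus$t, v_stim = session$stimulus$v_stim,
                v_flow = session$stimulus$v_flow,
                g_ms = session$stimulus$g_ms), "stimulus/v_stim.csv")
  fw(session$stimulus$epochs, "stimulus/epochs.csv")
  fw(data.frame(t = session$stimulus$t, s = session$state$s,
                readiness = session$state$readiness), "state/s.csv")
  fw(as.data.frame(session$neural$dff), "neural/dff.csv")
  fw(data.frame(t_frame = session$neural$t_frames,
                s_frame = session$neural$s_frames), "neural/frames.csv")
  fw(session$neural$cells, "neural/regions.csv")
  fw(session$truth$trials, "truth/trials.csv")
  manifest <- list(schema = session$schema, seed = session$seed,
                   fs_beh = session$stimulus$fs,
                   fs_img = session$neural$fs_img,
                   fs_ephys = if (!is.null(session$behavior$ephys))
                     session$behavior$ephys$fs else NULL,
                   config = session$config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a session container from disk
#'
#' Validates the schema version and the presence of every required
#' dataset before loading; a missing dataset raises an error naming its
#' path.
#'
#' @param dir session directory written by [write_session()].
#' @return a `swim_session`.
#' @export
read_session <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) {
    stop("schema error: missing dataset manifest.json", call. = FALSE)
  }
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (!identical(as.character(man$schema), SESSION_SCHEMA)) {
    stop("schema version mismatch: found ", man$schema, ", supported ",
         SESSION_SCHEMA, "; regenerate the session with this package",
         call. = FALSE)
  }
  need <- c("behavior/vigor.csv", "behavior/bouts_true.csv",
            "stimulus/v_stim.csv", "stimulus/epochs.csv", "state/s.csv",
            "neural/dff.csv", "neural/frames.csv", "neural/regions.csv",
            "truth/trials.csv")
  for (p in need) {
    if (!file.exists(file.path(dir, p))) {
      stop("schema error: missing dataset ", p, call. = FALSE)
    }
  }
  fr <- function(p) as.data.frame(data.table::fread(file.path(dir, p)))
  vig <- fr("behavior/vigor.csv")
  stim <- fr("stimulus/v_stim.csv")
  st <- fr("state/s.csv")
  frames <- fr("neural/frames.csv")
  dff <- as.matrix(fr("neural/dff.csv"))
  dimnames(dff) <- list(seq_len(nrow(dff)), NULL)
  eph <- NULL
  if (file.exists(file.path(dir, "behavior/ephys.csv"))) {
    eph <- structure(list(y = fr("behavior/ephys.csv")$y,
                          fs = man$fs_ephys, t0 = 0),
                     class = "ephys_trace")
  }
  cells <- fr("neural/regions.csv")
  structure(list(
    schema = as.character(man$schema),
    seed = man$seed,
    behavior = list(ephys = eph, vigor = vig$vigor,
                    bouts_true = fr("behavior/bouts_true.csv")),
    stimulus = list(t = stim$t, v_stim = stim$v_stim,
                    v_flow = stim$v_flow, g_ms = stim$g_ms,
                    epochs = fr("stimulus/epochs.csv"), fs = man$fs_beh),
    state = list(s = st$s, readiness = st$readiness),
    neural = list(dff = dff, t_frames = frames$t_frame,
                  cells = cells, s_frames = frames$s_frame,
                  fs_img = man$fs_img),
    truth = list(trials = fr("truth/trials.csv"),
                 bouts = fr("behavior/bouts_true.csv"),
                 cells = cells),
    config = man$config
  ), class = "swim_session")
}
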