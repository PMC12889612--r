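#' Assemble trials from a stimulus log and detected bouts
#'
#' Reconstructs per-trial epoch boundaries from the stimulus epoch log,
#' verifies their consistency (strictly increasing boundaries; on
#' Futile trials the Pause epoch must begin one passivity window after
#' the last Evoke swim offset), computes the latency to the
#' probe-evoked swim, and classifies each trial's internal-state label.
#' All intervals are half-open `[onset, offset)` in seconds from
#' session start.
#'
#' @param epochs stimulus epoch log: data frame with columns `trial`,
#'   `type`, `evoke_on`, `evoke_off`, `pause_on`, `pause_off`,
#'   `probe_on`, `probe_off` (and optionally `capsaicin`, `n_pulses`).
#' @param bouts data frame of swim bouts (`onset`, `offset`).
#' @param paradigm a [paradigm_config()].
#' @param end_pause_max maximum end-of-Evoke pause (s) tolerated on an
#'   Engaged trial: 3 (classification rule) or 3.3 (imaging-analysis
#'   selection rule).
#' @return data frame of trial records with classification `label`
#'   (`Engaged`, `Disengaged`, `Perseverant`, `Excluded`), `latency`
#'   and `censored`.
#' @export
build_trials <- function(epochs, bouts, paradigm = paradigm_config(),
                         end_pause_max = 3) {
  need <- c("trial", "type", "evoke_on", "evoke_off", "pause_on",
            "pause_off", "probe_on", "probe_off")
  if (!all(need %in% names(epochs))) {
    stop("format error: epoch log missing columns: ",
         paste(setdiff(need, names(epochs)), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(bouts) && max(bouts$offset) > max(epochs$probe_off) + 1e-6) {
    stop("format error: bouts extend past the stimulus log", call. = FALSE)
  }
  out <- epochs
  out$label <- NA_character_
  out$latency <- NA_real_
  out$censored <- NA
  for (i in seq_len(nrow(out))) {
    tri <- out[i, ]
    bd <- c(tri$evoke_on, tri$evoke_off, tri$probe_on, tri$probe_off)
    if (is.unsorted(bd, strictly = TRUE) ||
        tri$pause_on < tri$evoke_off - 1e-9 ||
        tri$pause_off > tri$probe_on + 1e-9) {
      stop("format error: epoch boundaries not increasing in trial ",
           tri$trial, call. = FALSE)
    }
    lat <- latency_to_probe_swim(tri, bouts)
    out$latency[i] <- lat$latency
    out$censored[i] <- lat$censored
    out$label[i] <- classify_trial(tri, bouts,
                                   isi_max = paradigm$isi_engaged_max,
                                   passivity_window = paradigm$passivity_window,
                                   end_pause_max = end_pause_max)
  }
  out
}

#' Classify one trial's internal-state label
#'
#' Effective trials are `Engaged` when the fish swam continuously
#' through the Evoke epoch (every inter-swim interval, including the
#' final gap to the Evoke end, at most `isi_max` / `end_pause_max`
#' seconds) and `Excluded` otherwise. Futile trials are `Disengaged`
#' when the no-swim interval at (and including) the Evoke end reached
#' the passivity window, and `Perseverant` when the fish swam through
#' to the Pause transition. Every trial receives exactly one label.
#'
#' @param trial one trial record (row with `type`, `evoke_on`,
#'   `evoke_off`).
#' @param bouts bout data frame.
#' @param isi_max maximum engaged inter-swim interval (s).
#' @param passivity_window passivity definition (s).
#' @param end_pause_max maximum end-of-Evoke pause for an Engaged
#'   trial (s).
#' @return one of "Engaged", "Disengaged", "Perseverant", "Excluded".
#' @export
classify_trial <- function(trial, bouts, isi_max = 3,
                           passivity_window = 5, end_pause_max = 3) {
  ev <- bouts[bouts$offset > trial$evoke_on &
                bouts$onset < trial$evoke_off, , drop = FALSE]
  if (nrow(ev) == 0) {
    # no swimming at all during Evoke
    return(if (trial$type == "Futile") "Disengaged" else "Excluded")
  }
  end_gap <- trial$evoke_off - max(ev$offset)
  if (trial$type == "Futile") {
    if (end_gap >= passivity_window - 1e-9) "Disengaged" else "Perseverant"
  } else {
    gaps <- c(ev$onset[1] - trial$evoke_on,
              if (nrow(ev) > 1) ev$onset[-1] - ev$offset[-nrow(ev)])
    if (all(gaps <= isi_max + 1e-9) && end_gap <= end_pause_max + 1e-9) {
      "Engaged"
    } else {
      "Excluded"
    }
  }
}

#' Latency from Probe onset to the probe-evoked swim
#'
#' The onset of the first bout at or after Probe onset (boundary
#' inclusive: a bout exactly at Probe onset counts as probe-evoked).
#' Trials without a bout before Probe offset are censored at the cap.
#'
#' @param trial trial record with `probe_on`, `probe_off`.
#' @param bouts bout data frame.
#' @return list with `latency` (s) and `censored` (logical).
#' @export
latency_to_probe_swim <- function(trial, bouts) {
  cand <- bouts$onset[bouts$onset >= trial$probe_on - 1e-9 &
                        bouts$onset < trial$probe_off]
  if (length(cand)) {
    list(latency = max(0, min(cand) - trial$probe_on), censored = FALSE)
  } else {
    list(latency = trial$probe_off - trial$probe_on, censored = TRUE)
  }
}

#' Keep trials suitable for dual-aligned (time-warped) analysis
#'
#' Retains trials with latency at least `min_latency` seconds
#' (boundary inclusive) and an observed (non-censored) probe-evoked
#' swim, so the Probe-onset-aligned and swim-aligned segments do not
#' overlap.
#'
#' @param trials trial table with `latency` and `censored`.
#' @param min_latency threshold (s).
#' @return filtered trial table.
#' @export
filter_for_dual_alignment <- function(trials, min_latency = 20) {
  trials[!is.na(trials$latency) & trials$latency >= min_latency &
           !trials$censored, , drop = FALSE]
}

#' Latency summaries with and without censored trials
#'
#' Censored latencies carry the cap value; both treatments are
#' reported.
#'
#' @param trials trial table.
#' @return data frame of mean/sd/n by trial type and censoring rule.
#' @export
latency_summary <- function(trials) {
  do.call(rbind, lapply(unique(trials$type), function(ty) {
    tt <- trials[trials$type == ty, ]
    obs <- tt[!tt$censored, ]
    data.frame(type = ty,
               rule = c("censored_at_cap", "censored_excluded"),
               mean = c(mean(tt$latency), mean(obs$latency)),
               sd = c(stats::sd(tt$latency), stats::sd(obs$latency)),
               n = c(nrow(tt), nrow(obs)))
  }))
}
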