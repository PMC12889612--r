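#' Discriminability index between two conditions
#'
#' `d' = (mu1 - mu2) / sqrt((sd1^2 + sd2^2) / 2)` with sample standard
#' deviations. Identical degenerate samples give 0; degenerate samples
#' with different means give a signed-infinity sentinel. Invariant to
#' adding a constant to all samples; swapping conditions flips the
#' sign.
#'
#' @param x1,x2 samples of condition 1 and 2 (here: Engaged and
#'   Disengaged pulse-response areas).
#' @return dimensionless d'.
#' @export
dprime <- function(x1, x2) {
  x1 <- x1[is.finite(x1)]
  x2 <- x2[is.finite(x2)]
  if (length(x1) < 2 || length(x2) < 2) return(NA_real_)
  s <- sqrt((stats::var(x1) + stats::var(x2)) / 2)
  dm <- mean(x1) - mean(x2)
  if (s == 0) {
    return(if (dm == 0) 0 else sign(dm) * Inf)
  }
  dm / s
}

#' Duration of state modulation from per-pulse responses
#'
#' Per pulse index a rank-sum test compares the two conditions'
#' response distributions across trials; the duration of modulation is
#' the time (relative to Probe onset) of the first pulse from which the
#' conditions are indistinguishable (p >= alpha) for that pulse and all
#' later tested pulses. 0 when indistinguishable from the first pulse,
#' the probed length when always distinguishable. Requiring the
#' indistinguishability to be sustained avoids flicker from isolated
#' significant pulses.
#'
#' @param auc1,auc2 trials x pulses matrices of pulse AUCs per
#'   condition.
#' @param period pulse period (s).
#' @param alpha significance level.
#' @return duration (s), or `NA` with fewer than 2 trials per
#'   condition.
#' @export
modulation_duration <- function(auc1, auc2, period = 2, alpha = 0.05) {
  if (is.null(dim(auc1)) || is.null(dim(auc2)) ||
      nrow(auc1) < 2 || nrow(auc2) < 2) {
    return(NA_real_)
  }
  n_p <- min(ncol(auc1), ncol(auc2))
  p <- vapply(seq_len(n_p), function(i) {
    ranksum_p(auc1[, i], auc2[, i])
  }, numeric(1))
  ns <- !is.na(p) & p >= alpha
  sustained <- rev(cumprod(rev(ns))) == 1
  first <- which(sustained)
  if (!length(first)) return(n_p * period)
  (first[1] - 1) * period
}

#' Fraction of state-dependent cells at a time point
#'
#' Percentage of cells whose fluorescence snapshots differ between the
#' two conditions by rank-sum test at level `alpha`.
#'
#' @param snap1,snap2 cells x trials matrices of dF/F snapshots.
#' @param alpha significance level.
#' @return percentage in [0, 100].
#' @export
fraction_state_dependent <- function(snap1, snap2, alpha = 0.05) {
  if (ncol(snap1) < 2 || ncol(snap2) < 2) {
    stop("need >= 2 trials per condition", call. = FALSE)
  }
  p <- vapply(seq_len(nrow(snap1)), function(i) {
    ranksum_p(snap1[i, ], snap2[i, ])
  }, numeric(1))
  100 * mean(p < alpha, na.rm = TRUE)
}

#' Fraction of state-dependent cells along the Probe epoch
#'
#' Evaluates [fraction_state_dependent()] on a grid of times aligned to
#' Probe onset or to the probe-evoked swim.
#'
#' @param session a `swim_session`.
#' @param trials trial table.
#' @param offsets time offsets (s) from the alignment point.
#' @param align "probe_on" or "swim" (offsets then negative).
#' @param alpha significance level.
#' @return data frame with `offset` and `fraction` (percent).
#' @export
state_dependence_profile <- function(session, trials, offsets,
                                     align = c("probe_on", "swim"),
                                     alpha = 0.05) {
  align <- match.arg(align)
  tf <- session$neural$t_frames
  cond <- condition_of_trials(trials)
  conds <- stats::na.omit(unique(cond))
  stopifnot(length(conds) == 2)
  snap_at <- function(off) {
    sn <- lapply(conds, function(cc) {
      idx <- which(cond == cc & (align == "probe_on" | !trials$censored))
      cols <- vapply(idx, function(i) {
        t0 <- if (align == "probe_on") trials$probe_on[i] else
          trials$probe_on[i] + trials$latency[i]
        fi <- which(tf <= t0 + off)
        if (!length(fi)) NA_integer_ else max(fi)
      }, integer(1))
      session$neural$dff[, cols[!is.na(cols)], drop = FALSE]
    })
    fraction_state_dependent(sn[[1]], sn[[2]], alpha)
  }
  data.frame(offset = offsets,
             fraction = vapply(offsets, snap_at, numeric(1)))
}

#' Modulation depth versus regional integrator prevalence
#'
#' Spearman correlation and OLS slope across regions between the mean
#' modulation depth (d') and the fraction of sensory cells with long
#' integration time constants.
#'
#' @param region_dprime per-region mean d'.
#' @param region_frac_long per-region fraction of sensory cells with
#'   tau above the long-decay threshold (4 s).
#' @return list with `rho`, `p`, `slope`; `NA`s with fewer than 4
#'   regions or degenerate input.
#' @export
depth_integration_regression <- function(region_dprime, region_frac_long) {
  ok <- is.finite(region_dprime) & is.finite(region_frac_long)
  if (sum(ok) < 4) return(list(rho = NA_real_, p = NA_real_,
                               slope = NA_real_))
  st <- spearman_test(region_frac_long[ok], region_dprime[ok])
  slope <- unname(stats::coef(stats::lm(region_dprime[ok] ~
                                          region_frac_long[ok]))[2])
  list(rho = st$rho, p = st$p, slope = slope)
}

#' Two-way fixed-effects ANOVA across fish and trial type
#'
#' `measure ~ fish + type + fish:type`; the trial-type p-value is the
#' reported statistic. A measure with zero variance returns p = 1 for
#' every term by convention; a design with an empty fish-by-type cell
#' raises a rank-deficiency error.
#'
#' @param df data frame with columns `measure`, `fish`, `type`.
#' @return list with `p_fish`, `p_type`, `p_interaction`.
#' @export
anova_trialtype <- function(df) {
  stopifnot(all(c("measure", "fish", "type") %in% names(df)))
  df$fish <- factor(df$fish)
  df$type <- factor(df$type)
  if (nlevels(df$fish) < 2 || nlevels(df$type) < 2) {
    stop("rank deficiency: need >= 2 fish and both trial types",
         call. = FALSE)
  }
  if (any(table(df$fish, df$type) == 0)) {
    stop("rank deficiency: empty fish-by-type cell", call. = FALSE)
  }
  if (stats::sd(df$measure) == 0) {
    return(list(p_fish = 1, p_type = 1, p_interaction = 1))
  }
  a <- stats::anova(stats::lm(measure ~ fish * type, data = df))
  p <- a$`Pr(>F)`
  list(p_fish = p[1], p_type = p[2], p_interaction = p[3])
}

#' Sensory gating analysis of anti-motor (L-MO-like) cells
#'
#' Rolling standard deviation of each trace over a 4 s window, and a
#' paired comparison of the mean pulse-locked response in an early
#' Probe window versus a late (pre-recovery) window across cells; in
#' the Disengaged state the negative visual responses are gated off
#' early and reappear before recovery.
#'
#' @param traces cells x frames matrix of anti-motor cell traces.
#' @param t_frames frame times (s).
#' @param fs_img frame rate (Hz).
#' @param pulse_onsets pulse onset times (s).
#' @param early_win,late_win two non-overlapping `[start, end)` windows
#'   (s).
#' @param sd_window rolling-SD window (s).
#' @return list with `rolling_sd` (matrix), `early`, `late` (per-cell
#'   mean pulse AUC per window), `p` (paired signed-rank).
#' @export
lmo_gating <- function(traces, t_frames, fs_img, pulse_onsets,
                       early_win, late_win, sd_window = 4) {
  if (early_win[2] > late_win[1] && late_win[2] > early_win[1]) {
    stop("invalid argument: early and late windows overlap",
         call. = FALSE)
  }
  rsd <- t(apply(traces, 1L, rolling_sd, fs = fs_img,
                 window = sd_window))
  mean_auc <- function(win) {
    ons <- pulse_onsets[pulse_onsets >= win[1] & pulse_onsets < win[2]]
    vapply(seq_len(nrow(traces)), function(i) {
      if (!length(ons)) return(NA_real_)
      mean(vapply(ons, function(o) {
        pulse_response_auc(traces[i, ], t_frames, o)
      }, numeric(1)))
    }, numeric(1))
  }
  early <- mean_auc(early_win)
  late <- mean_auc(late_win)
  ok <- is.finite(early) & is.finite(late)
  p <- if (sum(ok) >= 2 && any(early[ok] != late[ok])) {
    suppressWarnings(stats::wilcox.test(early[ok], late[ok],
                                        paired = TRUE)$p.value)
  } else {
    NA_real_
  }
  list(rolling_sd = rsd, early = early, late = late, p = p)
}

#' Per-cell and per-region modulation summary
#'
#' d' (condition 1 minus condition 2 pulse AUCs of the first six
#' pulses) and duration of modulation per cell, aggregated over regions
#' for cells flagged sensory.
#'
#' @param pulses pulse table from [pulse_table()].
#' @param tuning tuning table from [classify_cells()].
#' @param cond1,cond2 condition names (defaults Engaged/Disengaged).
#' @param alpha significance level for the duration rule.
#' @return list with `cells` (cell_id, region, dprime, duration_s) and
#'   `regions` (region aggregates over sensory-flagged cells).
#' @export
modulation_summary <- function(pulses, tuning,
                               cond1 = "Engaged", cond2 = "Disengaged",
                               alpha = 0.05) {
  ids <- unique(pulses$cell_id)
  res <- lapply(ids, function(cid) {
    pc <- pulses[pulses$cell_id == cid, ]
    m1 <- tapply(pc$auc[pc$condition == cond1],
                 list(pc$trial[pc$condition == cond1],
                      pc$pulse_i[pc$condition == cond1]), mean)
    m2 <- tapply(pc$auc[pc$condition == cond2],
                 list(pc$trial[pc$condition == cond2],
                      pc$pulse_i[pc$condition == cond2]), mean)
    dp <- dprime(pc$auc[pc$condition == cond1],
                 pc$auc[pc$condition == cond2])
    dur <- modulation_duration(m1, m2, alpha = alpha)
    data.frame(cell_id = cid, dprime = dp, duration_s = dur)
  })
  cells <- do.call(rbind, res)
  cells <- merge(cells, tuning[, c("cell_id", "region", "sensory_pos",
                                   "sensory_neg")], by = "cell_id")
  sens <- cells[cells$sensory_pos | cells$sensory_neg, ]
  regions <- NULL
  if (nrow(sens)) {
    regions <- do.call(rbind, lapply(split(sens, sens$region), function(d) {
      q <- stats::quantile(d$dprime[is.finite(d$dprime)],
                           c(0.25, 0.75), na.rm = TRUE)
      data.frame(region = d$region[1], n = nrow(d),
                 mean_dprime = mean(d$dprime[is.finite(d$dprime)]),
                 q1 = q[1], q3 = q[2],
                 mean_duration = mean(d$duration_s, na.rm = TRUE))
    }))
    rownames(regions) <- NULL
  }
  list(cells = cells[, c("cell_id", "region", "dprime", "duration_s")],
       regions = regions)
}
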