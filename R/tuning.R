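frames_in <- function(t_frames, a, b) {
  which(t_frames >= a & t_frames < b)
}

#' Sensory tuning by rank correlation with the pulse series
#'
#' Spearman correlation between each cell's fluorescence and the
#' stimulus velocity over the early Probe epoch (first 6 pulses, 12 s),
#' concatenated across non-swimming trials (trials whose probe-evoked
#' swim came after the window). No multiple-comparison correction is
#' applied; population statistics are formed across fish.
#'
#' @param dff cells x frames matrix.
#' @param t_frames frame times (s).
#' @param v_stim_frames stimulus velocity binned to frames.
#' @param trials trial table from [build_trials()].
#' @param window correlation window from Probe onset (s).
#' @param alpha significance level.
#' @return data frame: `cell_id`, `sensory_rho`, `sensory_p`,
#'   `sensory_pos`, `sensory_neg`.
#' @export
sensory_correlation <- function(dff, t_frames, v_stim_frames, trials,
                                window = 12, alpha = 0.05) {
  use <- trials[trials$latency > window | trials$censored, , drop = FALSE]
  if (nrow(use) < 3) {
    stop("need >= 3 non-swimming trials for sensory correlation",
         call. = FALSE)
  }
  idx <- unlist(lapply(seq_len(nrow(use)), function(i) {
    frames_in(t_frames, use$probe_on[i], use$probe_on[i] + window)
  }))
  v <- v_stim_frames[idx]
  res <- apply(dff[, idx, drop = FALSE], 1L, function(y) {
    st <- spearman_test(y, v)
    c(st$rho, st$p)
  })
  rho <- res[1L, ]
  p <- res[2L, ]
  data.frame(cell_id = seq_len(nrow(dff)),
             sensory_rho = rho, sensory_p = p,
             sensory_pos = !is.na(rho) & p < alpha & rho > 0,
             sensory_neg = !is.na(rho) & p < alpha & rho < 0)
}

#' Motor tuning by rank correlation with swim vigor
#'
#' Spearman correlation between fluorescence and swim vigor during
#' open-loop Evoke windows (gain 0, constant flow), where stimulus
#' velocity is decoupled from swimming. The vigor regressor is passed
#' through the indicator kinetics before frame binning so the
#' comparison is made at the measurement's temporal resolution, and
#' samples are restricted to the actively swimming span of each window
#' (m > 0): the passive tail, where the internal state is at its peak,
#' would otherwise induce spurious vigor correlations in any
#' state-modulated cell. Cells with significantly negative correlation
#' are flagged `motor_neg` (anti-motor, the lateral medulla oblongata
#' phenotype).
#'
#' @param dff cells x frames matrix.
#' @param t_frames frame times (s).
#' @param vigor_frames indicator-convolved vigor binned to frames.
#' @param trials trial table; open-loop windows are the Evoke epochs of
#'   Futile trials.
#' @param alpha significance level.
#' @param raw_vigor_frames optional raw frame-binned vigor used to
#'   truncate each window at the last swimming frame.
#' @param onset_skip seconds dropped from the start of each window:
#'   the epoch-transition transient is shared by stimulus- and
#'   motor-locked signals alike and would otherwise correlate every
#'   responsive cell with vigor.
#' @return data frame: `cell_id`, `motor_rho`, `motor_p`, `motor`,
#'   `motor_neg`.
#' @export
motor_correlation <- function(dff, t_frames, vigor_frames, trials,
                              alpha = 0.05, raw_vigor_frames = NULL,
                              onset_skip = 1.5) {
  fut <- trials[trials$type == "Futile", , drop = FALSE]
  if (nrow(fut) == 0) {
    stop("no open-loop Evoke windows in the trial table", call. = FALSE)
  }
  idx <- unlist(lapply(seq_len(nrow(fut)), function(i) {
    fi <- frames_in(t_frames, fut$evoke_on[i] + onset_skip,
                    fut$evoke_off[i])
    if (!is.null(raw_vigor_frames)) {
      swimming <- which(raw_vigor_frames[fi] > 0)
      if (!length(swimming)) return(integer(0))
      fi <- fi[seq_len(max(swimming))]
    }
    fi
  }))
  v <- vigor_frames[idx]
  res <- apply(dff[, idx, drop = FALSE], 1L, function(y) {
    st <- spearman_test(y, v)
    c(st$rho, st$p)
  })
  rho <- res[1L, ]
  p <- res[2L, ]
  data.frame(cell_id = seq_len(nrow(dff)),
             motor_rho = rho, motor_p = p,
             motor = !is.na(rho) & p < alpha & rho > 0,
             motor_neg = !is.na(rho) & p < alpha & rho < 0)
}

#' Detect motor-preparatory cells
#'
#' For each window length (3-7 s immediately preceding the probe-evoked
#' swim, Engaged trials only), the Spearman correlation between
#' fluorescence and time relative to the swim (negative, increasing
#' toward the swim) is computed on samples concatenated across trials:
#' cells ramping up toward the swim correlate positively, decaying
#' cells negatively. A cell is flagged when, for every window length,
#' its correlation is positive with p below `alpha` and within the top
#' `top_frac` of cells (among positive correlations).
#'
#' @param dff cells x frames matrix.
#' @param t_frames frame times (s).
#' @param trials trial table with `label`, `latency`, `censored`.
#' @param windows window lengths (s).
#' @param alpha significance level.
#' @param top_frac top fraction of the population retained per window.
#' @return data frame with `cell_id`, `motor_prep` flag and per-window
#'   correlations `prep_rho_<w>`.
#' @export
detect_motor_prep <- function(dff, t_frames, trials, windows = 3:7,
                              alpha = 0.05, top_frac = 0.05) {
  eng <- trials[trials$label == "Engaged" & !trials$censored, ,
                drop = FALSE]
  n_cells <- nrow(dff)
  out <- data.frame(cell_id = seq_len(n_cells),
                    motor_prep = rep(FALSE, n_cells))
  rho_mat <- matrix(NA_real_, n_cells, length(windows))
  p_mat <- matrix(NA_real_, n_cells, length(windows))
  for (j in seq_along(windows)) {
    w <- windows[j]
    ok <- eng[eng$latency >= w, , drop = FALSE]
    if (nrow(ok) == 0) next
    idx <- integer(0)
    trel <- numeric(0)
    for (i in seq_len(nrow(ok))) {
      swim <- ok$probe_on[i] + ok$latency[i]
      fi <- frames_in(t_frames, swim - w, swim)
      idx <- c(idx, fi)
      trel <- c(trel, t_frames[fi] - swim)
    }
    if (length(idx) < 5) next
    res <- apply(dff[, idx, drop = FALSE], 1L, function(y) {
      st <- spearman_test(y, trel)
      c(st$rho, st$p)
    })
    rho_mat[, j] <- res[1L, ]
    p_mat[, j] <- res[2L, ]
  }
  if (all(is.na(rho_mat))) {
    for (j in seq_along(windows)) {
      out[[paste0("prep_rho_", windows[j])]] <- NA_real_
    }
    return(out)
  }
  n_keep <- ceiling(top_frac * n_cells)
  flag <- rep(TRUE, n_cells)
  for (j in seq_along(windows)) {
    rho <- rho_mat[, j]
    p <- p_mat[, j]
    pos <- !is.na(rho) & rho > 0
    cutoff <- if (sum(pos) > n_keep) {
      sort(rho[pos], decreasing = TRUE)[n_keep]
    } else {
      0
    }
    flag <- flag & pos & !is.na(p) & p < alpha & rho >= cutoff
  }
  out$motor_prep <- flag
  for (j in seq_along(windows)) {
    out[[paste0("prep_rho_", windows[j])]] <- rho_mat[, j]
  }
  out
}

#' Onset of motor-preparatory activity before the swim
#'
#' The latest pre-swim time at which the swim-aligned average trace
#' first exceeds baseline mean + 2 baseline SD and stays above it until
#' the swim.
#'
#' @param avg_trace swim-aligned average trace.
#' @param t_rel times relative to the swim (s, negative, increasing).
#' @param baseline baseline samples (e.g. the pre-trial period).
#' @return onset in seconds before the swim, or `NA` if the trace never
#'   exceeds the criterion.
#' @export
prep_onset_time <- function(avg_trace, t_rel, baseline) {
  thr <- mean(baseline) + 2 * stats::sd(baseline)
  above <- avg_trace > thr
  if (!any(above)) return(NA_real_)
  below <- which(!above)
  start <- if (length(below)) max(below) + 1L else 1L
  if (start > length(t_rel)) return(NA_real_)
  -t_rel[start]
}

#' Classify all cells of a session
#'
#' Runs sensory, motor and motor-preparatory classification and merges
#' the results with the cell region table.
#'
#' @param session a `swim_session`.
#' @param trials trial table from [build_trials()].
#' @param alpha significance level shared by the tests.
#' @return the cell-tuning data frame.
#' @export
classify_cells <- function(session, trials, alpha = 0.05) {
  nf <- length(session$neural$t_frames)
  vstim_f <- bin_to_frames(session$stimulus$v_stim, session$stimulus$t,
                           session$neural$fs_img, nf)
  vig_raw <- bin_to_frames(session$behavior$vigor, session$stimulus$t,
                           session$neural$fs_img, nf)
  popc <- session$config$population
  dt <- 1 / session$stimulus$fs
  vig_conv <- bin_to_frames(
    convolve_indicator(session$behavior$vigor, dt,
                       popc$indicator_decay %||% 0.5,
                       popc$indicator_rise %||% 0.05),
    session$stimulus$t, session$neural$fs_img, nf)
  sens <- sensory_correlation(session$neural$dff, session$neural$t_frames,
                              vstim_f, trials, alpha = alpha)
  mot <- if (any(trials$type == "Futile")) {
    motor_correlation(session$neural$dff, session$neural$t_frames,
                      vig_conv, trials, alpha = alpha,
                      raw_vigor_frames = vig_raw)
  } else {
    # no open-loop window (e.g. chemogenetic paradigm): motor tuning
    # cannot be dissociated from the stimulus, leave unflagged
    data.frame(cell_id = seq_len(nrow(session$neural$dff)),
               motor_rho = NA_real_, motor_p = NA_real_,
               motor = FALSE, motor_neg = FALSE)
  }
  prep <- detect_motor_prep(session$neural$dff, session$neural$t_frames,
                            trials, alpha = alpha)
  out <- cbind(session$neural$cells[, c("cell_id", "region")],
               sens[, -1L], mot[, -1L], prep[, -1L, drop = FALSE])
  rownames(out) <- NULL
  out
}
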