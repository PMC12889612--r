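#' Dual-aligned time-warped trial matrix
#'
#' Each trial's trace is represented by a left segment aligned to Probe
#' onset (copied verbatim), a right segment aligned to the last pulse
#' before the probe-evoked swim (copied verbatim), and a middle segment
#' linearly resampled to `n_stu` scaled-time-unit bins, so trials of
#' unequal duration can be averaged bin-wise. Constant traces remain
#' constant and monotone segments stay monotone under the linear
#' resampling. Trials too short to leave a non-empty middle segment are
#' excluded with a warning.
#'
#' @param traces list of per-trial traces (frame vectors).
#' @param t_list list of per-trial frame times (s).
#' @param probe_on per-trial Probe onsets (s).
#' @param anchor per-trial right-alignment times (s): the onset of the
#'   last pulse preceding the probe-evoked swim.
#' @param left_len,right_len segment lengths (s).
#' @param n_stu number of middle bins.
#' @param fs_img frame rate (Hz).
#' @return list with `matrix` (trials x bins), `segment` (per-column
#'   labels "left"/"stu"/"right"), `kept` (indices of included trials).
#' @export
time_warp_align <- function(traces, t_list, probe_on, anchor,
                            left_len = 8, right_len = 4, n_stu = 20,
                            fs_img = 3) {
  nl <- round(left_len * fs_img)
  nr <- round(right_len * fs_img)
  rows <- list()
  kept <- integer(0)
  for (i in seq_along(traces)) {
    tt <- t_list[[i]]
    y <- traces[[i]]
    li <- which(tt >= probe_on[i])[seq_len(nl)]
    ri_all <- which(tt < anchor[i])
    if (anyNA(li) || length(ri_all) < nr) {
      warning("trial ", i, " too short for dual alignment; excluded")
      next
    }
    ri <- ri_all[(length(ri_all) - nr + 1L):length(ri_all)]
    mid <- setdiff(seq(max(li) + 1L, min(ri) - 1L), integer(0))
    if (max(li) + 1L > min(ri) - 1L) {
      warning("trial ", i, " too short for dual alignment; excluded")
      next
    }
    ym <- y[mid]
    stu <- if (length(ym) == n_stu) {
      ym  # identity warp
    } else if (length(ym) == 1L) {
      rep(ym, n_stu)
    } else {
      stats::approx(seq_along(ym), ym, xout = seq(1, length(ym),
                                                  length.out = n_stu))$y
    }
    rows[[length(rows) + 1L]] <- c(y[li], stu, y[ri])
    kept <- c(kept, i)
  }
  if (!length(rows)) {
    return(list(matrix = matrix(numeric(0), 0, nl + n_stu + nr),
                segment = rep(c("left", "stu", "right"),
                              c(nl, n_stu, nr)),
                kept = kept))
  }
  list(matrix = do.call(rbind, rows),
       segment = rep(c("left", "stu", "right"), c(nl, n_stu, nr)),
       kept = kept)
}

#' Last pulse onset preceding the probe-evoked swim
#'
#' @param trial trial record with `probe_on`, `latency`.
#' @param period pulse period (s).
#' @return onset time (s) of the final pulse whose onset precedes the
#'   swim.
#' @export
last_pulse_before_swim <- function(trial, period = 2) {
  swim <- trial$probe_on + trial$latency
  k <- floor((swim - trial$probe_on) / period - 1e-12)
  trial$probe_on + period * max(0, k)
}

#' Pulse-response amplification approaching the probe-evoked swim
#'
#' Mean and SEM of pulse AUC as a function of pulse index relative to
#' the probe-evoked swim (index -1 is the last pulse before the swim),
#' per condition.
#'
#' @param pulses pulse table with `cell_id`, `trial`, `condition`,
#'   `pulse_i`, `auc`.
#' @param trials trial table (for swim times).
#' @param period pulse period (s).
#' @param max_index most negative index retained.
#' @return data frame: condition, rel_index, mean, sem, n.
#' @export
progressive_amplification <- function(pulses, trials, period = 2,
                                      max_index = 7) {
  sw <- trials[, c("trial", "probe_on", "latency", "censored")]
  d <- merge(pulses, sw, by = "trial")
  d <- d[!d$censored, ]
  n_before <- floor(d$latency / period)  # pulses before the swim
  d$rel_index <- d$pulse_i - n_before - 1L
  d <- d[d$rel_index < 0 & d$rel_index >= -max_index, ]
  if (!nrow(d)) return(NULL)
  agg <- do.call(rbind, lapply(split(d, list(d$condition, d$rel_index),
                                     drop = TRUE), function(g) {
    data.frame(condition = g$condition[1], rel_index = g$rel_index[1],
               mean = mean(g$auc),
               sem = if (nrow(g) > 1) stats::sd(g$auc) / sqrt(nrow(g))
                     else NA_real_,
               n = nrow(g))
  }))
  rownames(agg) <- NULL
  agg[order(agg$condition, agg$rel_index), ]
}

#' Select behavior-predictive cells
#'
#' Cells whose single-pulse responses correlate negatively with the
#' latency from that pulse to the probe-evoked swim (Spearman rho < 0,
#' p < alpha): responses grow as the swim approaches.
#'
#' @param features samples x cells matrix of pulse responses.
#' @param latency_from_pulse per-sample time from the pulse to the
#'   swim (s).
#' @param alpha significance level.
#' @return logical vector over cells.
#' @export
behavior_predictive_cells <- function(features, latency_from_pulse,
                                      alpha = 0.05) {
  vapply(seq_len(ncol(features)), function(j) {
    st <- spearman_test(features[, j], latency_from_pulse)
    !is.na(st$rho) && st$rho < 0 && st$p < alpha
  }, logical(1))
}

#' Decode probe-evoked swim latency from pulse responses
#'
#' Gradient-boosted regression (100 trees, learning rate 0.1, depth 3
#' -- the library defaults of the reference regressor) trained per
#' condition on a seeded, condition-stratified random half of the
#' trials and tested on the other half. Features are the responses of
#' behavior-predictive cells to the nth pulse before the swim
#' (0 < n < 8); the target is the latency from that pulse to the swim.
#'
#' @param features samples x cells matrix.
#' @param target per-sample latency to swim (s).
#' @param trial_id per-sample trial identifier.
#' @param condition per-sample condition label.
#' @param seed split seed.
#' @return list with `predictions` (data frame: trial_id, condition,
#'   predicted_s, actual_s) and `cor` (per-condition Spearman rank
#'   correlation of predicted vs actual on test data).
#' @export
decode_latency <- function(features, target, trial_id, condition,
                           seed = 1L) {
  set.seed(seed)
  preds <- list()
  for (cc in unique(condition)) {
    sel <- condition == cc
    tr_ids <- unique(trial_id[sel])
    if (length(tr_ids) < 4) {
      warning("condition ", cc, ": fewer than 4 trials; skipped")
      next
    }
    train_ids <- sample(tr_ids, floor(length(tr_ids) / 2))
    tr_sel <- sel & trial_id %in% train_ids
    te_sel <- sel & !trial_id %in% train_ids
    X <- as.matrix(features)
    fit <- xgboost::xgb.train(
      params = list(eta = 0.1, max_depth = 3,
                    objective = "reg:squarederror"),
      data = xgboost::xgb.DMatrix(X[tr_sel, , drop = FALSE],
                                  label = target[tr_sel]),
      nrounds = 100)
    yhat <- stats::predict(fit,
                           xgboost::xgb.DMatrix(X[te_sel, , drop = FALSE]))
    preds[[cc]] <- data.frame(trial_id = trial_id[te_sel],
                              condition = cc, predicted_s = yhat,
                              actual_s = target[te_sel])
  }
  if (!length(preds)) return(list(predictions = NULL, cor = NULL))
  predictions <- do.call(rbind, preds)
  cors <- vapply(split(predictions, predictions$condition), function(d) {
    suppressWarnings(stats::cor(d$predicted_s, d$actual_s,
                                method = "spearman"))
  }, numeric(1))
  list(predictions = predictions, cor = cors)
}

#' Build decoder features from a pulse table
#'
#' One sample per (trial, pulse) pair for the 1st-7th pulse before the
#' probe-evoked swim; features are per-cell AUCs, the target the
#' latency from the pulse onset to the swim.
#'
#' @param pulses pulse table.
#' @param trials trial table.
#' @param period pulse period (s).
#' @return list with `features` (samples x cells), `target`,
#'   `trial_id`, `condition`.
#' @export
decoder_samples <- function(pulses, trials, period = 2) {
  sw <- trials[, c("trial", "latency", "censored")]
  d <- merge(pulses, sw, by = "trial")
  d <- d[!d$censored, ]
  n_before <- floor(d$latency / period)
  d$rel <- n_before + 1L - d$pulse_i  # nth pulse before swim
  d <- d[d$rel >= 1 & d$rel <= 7, ]
  d$lat_from_pulse <- d$latency - (d$pulse_i - 1L) * period
  key <- paste(d$trial, d$pulse_i)
  cells <- sort(unique(d$cell_id))
  ukey <- unique(key)
  X <- matrix(NA_real_, length(ukey), length(cells),
              dimnames = list(ukey, cells))
  X[cbind(match(key, ukey), match(d$cell_id, cells))] <- d$auc
  first <- d[!duplicated(key), ]
  list(features = X, target = first$lat_from_pulse,
       trial_id = first$trial,
       condition = first$condition)
}
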