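#!/usr/bin/env Rscript
# Recovery dynamics: dual-aligned time-warped averages, progressive
# pulse-response amplification, and gradient-boosted decoding of the
# probe-evoked swim latency from sensory pulse responses.

library(swimstate)

preds <- list(); amp_all <- list()
for (dir in Sys.glob("results/sessions/fish*")) {
  ses <- read_session(dir)
  tr <- read_units_csv(file.path("results",
                                 paste0("trials_", basename(dir), ".csv")))
  tun <- read_units_csv(file.path("results",
                                  paste0("tuning_", basename(dir), ".csv")))
  sens <- tun$cell_id[tun$sensory_pos]
  pa <- pulse_table(ses, tr, cell_ids = sens, n_pulses = 30)

  amp <- progressive_amplification(pa, tr)
  amp$fish <- basename(dir)
  amp_all[[dir]] <- amp

  # warped average of the mean sensory trace over dual-aligned trials
  ok <- filter_for_dual_alignment(tr)
  if (nrow(ok) >= 2) {
    mtrace <- colMeans(ses$neural$dff[sens, , drop = FALSE])
    warped <- time_warp_align(
      traces = replicate(nrow(ok), mtrace, simplify = FALSE),
      t_list = replicate(nrow(ok), ses$neural$t_frames,
                         simplify = FALSE),
      probe_on = ok$probe_on,
      anchor = vapply(seq_len(nrow(ok)), function(i) {
        last_pulse_before_swim(ok[i, ])
      }, numeric(1)))
    write_units_csv(
      data.frame(segment = warped$segment,
                 mean = colMeans(warped$matrix)),
      file.path("results", paste0("warped_", basename(dir), ".csv")),
      "mean dF/F per warped bin")
  }

  ds <- decoder_samples(pa, tr)
  bp <- behavior_predictive_cells(ds$features, ds$target)
  if (sum(bp) >= 1) {
    dec <- decode_latency(ds$features[, bp, drop = FALSE], ds$target,
                          ds$trial_id, ds$condition, seed = 7)
    dec$predictions$fish <- basename(dir)
    preds[[dir]] <- dec$predictions
  }
}
write_units_csv(do.call(rbind, amp_all), "results/amplification.csv",
                "mean/sem pulse AUC in dF/F*s by index relative to swim")
all_p <- do.call(rbind, preds)
write_units_csv(all_p, "results/decoder_predictions.csv",
                "predicted/actual latency in s")
for (cc in unique(all_p$condition)) {
  d <- all_p[all_p$condition == cc, ]
  message(sprintf("decoder rank correlation (%s): %.2f", cc,
                  cor(d$predicted_s, d$actual_s, method = "spearman")))
}
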