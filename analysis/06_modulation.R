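#!/usr/bin/env Rscript
# State-modulation depth (d'), duration, per-region aggregates, the
# depth-vs-integration regression, the state-dependent-fraction
# profile, and the across-fish two-way ANOVA on latency.

library(swimstate)

cells_all <- list(); lat_all <- list()
for (dir in Sys.glob("results/sessions/fish*")) {
  ses <- read_session(dir)
  tr <- read_units_csv(file.path("results",
                                 paste0("trials_", basename(dir), ".csv")))
  tun <- read_units_csv(file.path("results",
                                  paste0("tuning_", basename(dir), ".csv")))
  ids <- tun$cell_id[tun$sensory_pos | tun$sensory_neg]
  pt <- pulse_table(ses, tr, cell_ids = ids)
  ms <- modulation_summary(pt, tun)
  ms$cells$fish <- basename(dir)
  cells_all[[dir]] <- ms$cells
  write_units_csv(ms$cells, file.path("results",
    paste0("modulation_", basename(dir), ".csv")),
    "dprime dimensionless; duration_s in s")
  if (!is.null(ms$regions)) {
    write_units_csv(ms$regions, file.path("results",
      paste0("regions_", basename(dir), ".csv")), "mean_dprime unitless")
  }
  prof <- rbind(
    cbind(align = "probe_on",
          state_dependence_profile(ses, tr, c(1, 3, 5), "probe_on")),
    cbind(align = "swim",
          state_dependence_profile(ses, tr, c(-5, -3, -1), "swim")))
  write_units_csv(prof, file.path("results",
    paste0("state_fraction_", basename(dir), ".csv")),
    "offset in s; fraction in percent")
  lat_all[[dir]] <- data.frame(fish = basename(dir), measure = tr$latency,
                               type = tr$type)
}
cells <- do.call(rbind, cells_all)
message(sprintf("median d' %.2f; %.0f%% of modulated cells d' > 0",
                median(cells$dprime, na.rm = TRUE),
                100 * mean(cells$dprime > 0, na.rm = TRUE)))
a <- anova_trialtype(do.call(rbind, lat_all))
message(sprintf("two-way ANOVA on latency: trial-type p = %.2g", a$p_type))
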