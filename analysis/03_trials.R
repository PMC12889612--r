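#!/usr/bin/env Rscript
# Assemble epochs into trials, classify engagement labels, and
# summarize probe-swim latencies for every simulated fish.

library(swimstate)

pcfg <- paradigm_config()
for (dir in Sys.glob("results/sessions/*")) {
  ses <- read_session(dir)
  tr <- build_trials(ses$stimulus$epochs, ses$truth$bouts, pcfg)
  write_units_csv(tr, file.path("results",
                                paste0("trials_", basename(dir), ".csv")),
                  "epoch times and latency in s from session start")
}

trials <- do.call(rbind, lapply(Sys.glob("results/trials_fish*.csv"),
                                read_units_csv))
print(table(trials$type, trials$label))
print(latency_summary(trials))
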