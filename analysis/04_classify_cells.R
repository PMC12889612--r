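#!/usr/bin/env Rscript
# Functional cell classification: sensory (Spearman vs stimulus),
# motor (vs vigor in open loop), motor-preparatory (multi-window
# pre-swim ramps). Compares flags against generator ground truth.

library(swimstate)

for (dir in Sys.glob("results/sessions/fish*")) {
  ses <- read_session(dir)
  tr <- read_units_csv(file.path("results",
                                 paste0("trials_", basename(dir), ".csv")))
  tun <- classify_cells(ses, tr)
  tun$true_class <- ses$truth$cells$class
  write_units_csv(tun, file.path("results",
                                 paste0("tuning_", basename(dir), ".csv")),
                  "rho dimensionless; p unadjusted")
  message(basename(dir), ": ",
          sum(tun$sensory_pos), " sensory+, ", sum(tun$sensory_neg),
          " sensory-, ", sum(tun$motor), " motor, ",
          sum(tun$motor_prep), " preparatory")
}
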