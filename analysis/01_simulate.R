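#!/usr/bin/env Rscript
# Simulate the default cohort: 3 fish, 20 alternating Effective/Futile
# trials each, plus an astrocyte-silenced (calex) control cohort.
# Writes session containers under results/sessions/.

library(swimstate)

seed <- 20260923L
dir.create("results/sessions", recursive = TRUE, showWarnings = FALSE)

cohort <- simulate_cohort(3, seed = seed)
for (i in seq_along(cohort)) {
  write_session(cohort[[i]], sprintf("results/sessions/fish%02d", i))
}
calex <- simulate_cohort(3, population = population_config(mode = "calex"),
                         seed = seed + 500L)
for (i in seq_along(calex)) {
  write_session(calex[[i]], sprintf("results/sessions/calex%02d", i))
}

lat <- do.call(rbind, lapply(cohort, function(s) s$truth$trials))
message(sprintf(
  "simulated %d + %d sessions; mean latency Effective %.1f s, Futile %.1f s",
  length(cohort), length(calex),
  mean(lat$latency[lat$type == "Effective"]),
  mean(lat$latency[lat$type == "Futile"])))
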