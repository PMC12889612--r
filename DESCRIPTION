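Package: swimstate
Title: Internal-State Modulation of Sensorimotor Processing in Larval
    Zebrafish Virtual-Reality Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of futility-induced internal-state
    transitions in larval zebrafish performing a visual motion
    accumulation task in closed- and open-loop virtual reality.  Provides
    a synthetic-session generator (fictive ventral-root traces, stimulus
    logs, a latent astrocytic state variable, and calcium-indicator
    fluorescence for sensory, integrator, motor-preparatory, motor, and
    anti-motor cell populations), adaptive-threshold swim-bout detection,
    trial structuring and engagement classification, Spearman-based
    functional cell classification, leaky-integrator time-constant
    fitting with inverse-leakiness quantification, d-prime
    state-modulation mapping, time-warped trial alignment, and
    gradient-boosted decoding of probe-evoked swim latency.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
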