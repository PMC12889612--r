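#' Run the full analysis pipeline on synthetic cohorts
#'
#' Simulates a cohort, structures trials, classifies cells, fits
#' integration metrics, quantifies state modulation and runs the
#' latency decoder, returning a report of headline statistics. With an
#' output directory the per-stage tables are written as CSV (with a
#' units header comment) and the report as JSON.
#'
#' @param config list with optional elements `paradigm`
#'   ([paradigm_config()]), `population` ([population_config()]),
#'   `state` ([state_params()]), `n_fish` (default 3) and `use_ephys`
#'   (detect bouts from a synthesized ventral-root trace instead of
#'   ground truth; default FALSE).
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @return report list (invisibly when writing to disk).
#' @export
run_pipeline <- function(config = list(), seed = 1L, out_dir = NULL) {
  pc <- config$paradigm %||% paradigm_config()
  pop <- config$population %||% population_config()
  st <- config$state %||% state_params()
  n_fish <- config$n_fish %||% 3L
  if (pc$n_trials == 0) {
    stop("config error: n_trials must be > 0", call. = FALSE)
  }
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tic <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_msg("stage %-16s %6.1f s", name,
            as.numeric(difftime(Sys.time(), tic, units = "secs")))
    out
  }

  sessions <- stage("simulate",
                    simulate_cohort(n_fish, pc, pop, st, seed = seed))

  per_fish <- stage("structure+classify", lapply(seq_along(sessions),
    function(i) {
      ses <- sessions[[i]]
      bouts <- if (isTRUE(config$use_ephys)) {
        detect_swims(synth_ephys(ses$truth$bouts, fs_ephys = 1000,
                                 seed = seed + i))
      } else {
        ses$truth$bouts
      }
      trials <- build_trials(ses$stimulus$epochs, bouts, pc)
      tuning <- classify_cells(ses, trials)
      sens_ids <- tuning$cell_id[tuning$sensory_pos | tuning$sensory_neg]
      int_ids <- ses$truth$cells$cell_id[
        ses$truth$cells$class == "integrator"]
      pulse_ids <- union(sens_ids, int_ids)
      pulses <- pulse_table(ses, trials, cell_ids = pulse_ids)
      # decoder and amplification need the pulses near the swim too
      pulses_all <- pulse_table(ses, trials, cell_ids = sens_ids,
                                n_pulses = 30)
      fits <- fit_integration(ses, trials, cell_ids = pulse_ids)
      list(fish = i, session = ses, trials = trials, tuning = tuning,
           pulses = pulses, pulses_all = pulses_all, fits = fits)
    }))

  report <- stage("summarize", {
    trials_all <- do.call(rbind, lapply(per_fish, function(f) {
      cbind(fish = f$fish, f$trials)
    }))
    lat <- latency_summary(trials_all)
    conds <- unique(condition_of_trials(trials_all))
    conds <- conds[!is.na(conds)]
    c1 <- conds[1]; c2 <- if (length(conds) > 1) conds[2] else conds[1]

    med_tau <- function(cc) {
      stats::median(unlist(lapply(per_fish, function(f) {
        int_ids <- f$session$truth$cells$cell_id[
          f$session$truth$cells$class == "integrator"]
        f$fits$tau[f$fits$condition == cc &
                     f$fits$cell_id %in% int_ids]
      })), na.rm = TRUE)
    }
    dps <- unlist(lapply(per_fish, function(f) {
      if (is.null(f$pulses)) return(NULL)
      sens <- f$tuning$cell_id[f$tuning$sensory_pos | f$tuning$sensory_neg]
      ms <- modulation_summary(f$pulses[f$pulses$cell_id %in% sens, ],
                               f$tuning, cond1 = c1, cond2 = c2)
      ms$cells$dprime
    }))
    dec_cor <- tryCatch({
      f1 <- per_fish[[1]]
      ds <- decoder_samples(f1$pulses_all, f1$trials)
      bp <- behavior_predictive_cells(ds$features, ds$target)
      if (sum(bp) >= 1) {
        dec <- decode_latency(ds$features[, bp, drop = FALSE], ds$target,
                              ds$trial_id, ds$condition, seed = seed)
        dec$cor
      } else NULL
    }, error = function(e) NULL)

    list(
      seed = seed, n_fish = n_fish, mode = pop$mode,
      latency = lat,
      median_tau_cond1 = med_tau(c1),
      median_tau_cond2 = med_tau(c2),
      conditions = c(c1, c2),
      median_dprime = stats::median(dps[is.finite(dps)], na.rm = TRUE),
      frac_dprime_pos = mean(dps[is.finite(dps)] > 0, na.rm = TRUE),
      median_dprime_near_zero =
        abs(stats::median(dps[is.finite(dps)], na.rm = TRUE)) <= 0.1,
      decoder_cor = dec_cor,
      wall_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (f in per_fish) {
      pre <- file.path(out_dir, sprintf("fish%02d", f$fish))
      write_units_csv(f$trials, paste0(pre, "_trials.csv"),
        "trial times in s from session start; latency in s")
      write_units_csv(f$tuning, paste0(pre, "_tuning.csv"),
        "rho dimensionless; p unadjusted")
      if (!is.null(f$pulses)) {
        write_units_csv(f$pulses, paste0(pre, "_pulses.csv"),
          "auc in dF/F*s; on/off in dF/F")
      }
      if (!is.null(f$fits)) {
        write_units_csv(f$fits, paste0(pre, "_integration.csv"),
          "tau in s; beta in dF/F per mm; inv_leakiness dimensionless")
      }
    }
    rep_out <- report
    rep_out$wall_s <- NULL  # keep report reproducible bit-for-bit
    jsonlite::write_json(rep_out, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    return(invisible(report))
  }
  report
}

#' Write a CSV with a units header comment
#'
#' @param df data frame.
#' @param path output path.
#' @param units free-text unit declaration placed in a `#` comment on
#'   the first line.
#' @return `path`, invisibly.
#' @export
write_units_csv <- function(df, path, units) {
  con <- file(path, "w")
  writeLines(paste0("# units: ", units), con)
  close(con)
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a CSV written by [write_units_csv()]
#'
#' @param path file path.
#' @return data frame (the units comment is skipped).
#' @export
read_units_csv <- function(path) {
  as.data.frame(data.table::fread(path, skip = 1L))
}
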