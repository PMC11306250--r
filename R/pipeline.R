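# End-to-end orchestration: simulate -> detect -> dwell/stroke ->
# ensemble/stiffness -> Bell fits, with per-stage seed streams and a report
# mirroring the single-molecule rate table (variant x parameter).

#' Per-stage seed stream
#'
#' Deterministically derives independent stage seeds from one global seed so
#' each stage is individually reproducible.  Kept below 2^31.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @export
stage_seed <- function(seed, stage) {
  stages <- c(states10 = 11L, states100 = 13L, trace = 17L, stiffness = 19L,
              loadsweep = 23L, stoppedflow = 29L, misc = 31L)
  off <- stages[[stage]] %||% 37L
  as.integer((as.numeric(seed) * 2654435L + off * 97L) %% 2147483647L)
}

#' Run configuration
#'
#' @param variant variant name (see [myo6_variant()]).
#' @param seed global seed.
#' @param atp_levels ATP concentrations (mM) for the dwell-kinetics stage.
#' @param n_events_kinetics target events per ATP level (state-sequence
#'   stage).
#' @param n_events_trace target events for the Langevin working-stroke stage.
#' @param n_events_stiffness target events for the forcing/stiffness stage.
#' @param load_offsets trap static offsets (nm) for the load sweep; NULL
#'   disables the sweep.
#' @param n_events_load events per load bin.
#' @param out_dir optional output directory; when given, the resolved config,
#'   event tables and the report are written there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(variant = "S267E", seed = 1L,
                       atp_levels = c(0.01, 0.1),
                       n_events_kinetics = 1000,
                       n_events_trace = 300,
                       n_events_stiffness = 50,
                       load_offsets = NULL,
                       n_events_load = 200,
                       out_dir = NULL) {
  structure(list(variant = variant, seed = as.integer(seed),
                 atp_levels = atp_levels,
                 n_events_kinetics = n_events_kinetics,
                 n_events_trace = n_events_trace,
                 n_events_stiffness = n_events_stiffness,
                 load_offsets = load_offsets,
                 n_events_load = n_events_load,
                 out_dir = out_dir), class = "run_config")
}

# duration needed for ~n complete events
events_duration <- function(n, rates, cond) {
  n * (1 / rates$k_att + mean_attached_time(rates, cond)) * 1.1 + 5
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes, for one variant: (1) state-sequence simulation at each ATP level
#' and cumulative dwell fitting + ATP classification (k1_0, k2_0); (2) a
#' Langevin trace without forcing, event detection and the Gaussian
#' working-stroke fit (series-compliance corrected); (3) a forcing-protocol
#' trace and the ensemble stiffness time course (plateaus, transition rates);
#' (4, optional) a load sweep with Bell fits of both branches; plus the
#' closed-form model summary.
#'
#' @param config a [run_config()].
#' @return List of class `myotrap_report` with per-stage results and a
#'   one-row `report` data.frame (variant, k1, k2, W/S, kappa_pre,
#'   kappa_rigor, d1, d2, duty, stall force).
#' @export
run_pipeline <- function(config) {
  v <- myo6_variant(config$variant)
  rates <- v$rates; mech <- v$mech
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  # 1. dwell kinetics at each ATP level (state-sequence layer)
  fits <- list(); dwell_sets <- list()
  kin <- stage("dwell-kinetics", {
    for (i in seq_along(config$atp_levels)) {
      atp <- config$atp_levels[i]
      cond <- conditions(atp)
      dur <- events_duration(config$n_events_kinetics, rates, cond)
      traj <- simulate_state_sequence(rates, cond, dur,
        seed = stage_seed(config$seed, if (i == 1) "states10" else "states100"))
      ev <- attached_events(traj)
      dwell_sets[[i]] <- ev$dwells
      fits[[i]] <- cumulative_dwell_fit(ev$dwells)
    }
    classify_rates(fits, config$atp_levels, dwells = dwell_sets)
  })
  # 2. working stroke from a Langevin trace (no forcing protocol)
  cond_ws <- conditions(max(config$atp_levels))
  ws <- stage("working-stroke", {
    dur <- events_duration(config$n_events_trace, rates, cond_ws)
    traj <- simulate_state_sequence(rates, cond_ws, dur,
                                    seed = stage_seed(config$seed, "trace"))
    cfg <- sim_config(dur, forcing_amp = 0,
                      seed = stage_seed(config$seed, "trace"))
    trace <- simulate_trap_trace(traj, mech, cfg, cond_ws)
    evs <- detect_events(trace)
    gf <- displacement_gaussian_fit(evs$displacement_ws)
    duty <- apparent_duty_and_onrate(evs)
    list(fit = gf, events = evs, duty = duty,
         ws = gf$xc / trace$metadata$compliance_rigor)
  })
  # 3. stiffness time course (forcing protocol)
  stiff <- stage("stiffness", {
    dur <- events_duration(config$n_events_stiffness, rates, cond_ws)
    traj <- simulate_state_sequence(rates, cond_ws, dur,
                                    seed = stage_seed(config$seed, "stiffness"))
    cfg <- sim_config(dur, seed = stage_seed(config$seed, "stiffness"))
    trace <- simulate_trap_trace(traj, mech, cfg, cond_ws)
    evs <- detect_events(trace)
    ensemble_stiffness(trace, evs)
  })
  # 4. optional load sweep (state-sequence layer, known entry loads)
  bell <- NULL
  if (!is.null(config$load_offsets)) {
    bell <- stage("load-sweep", {
      atp <- max(config$atp_levels)
      cond <- conditions(atp)
      evs <- lapply(seq_along(config$load_offsets), function(j) {
        off <- config$load_offsets[j]
        traj <- simulate_state_sequence(rates, cond,
          events_duration(config$n_events_load, rates, cond),
          seed = stage_seed(config$seed, "loadsweep") + j,
          mech = mech, static_offset = off)
        ev <- attached_events(traj)
        data.frame(dwell = ev$dwells, mean_load = ev$load)
      })
      all_ev <- do.call(rbind, evs)
      rng <- range(all_ev$mean_load)
      edges <- seq(rng[1] - 1e-6, rng[2] + 1e-6,
                   length.out = length(config$load_offsets) + 1)
      bins <- bin_events_by_load(all_ev, edges)
      load_resolved_bell(bins, atp)
    })
  }
  report <- data.frame(
    variant = config$variant,
    k1_s = kin$k1_0, k2_mM_s = kin$k2_0,
    ws_nm = ws$ws,
    kappa_pre = stiff$plateau_pre, kappa_rigor = stiff$plateau_rigor,
    d1_nm = if (!is.null(bell)) bell$bell_k1$d else NA_real_,
    d2_nm = if (!is.null(bell)) bell$bell_k2$d else NA_real_,
    duty = ws$duty$duty,
    stall_pN = ws$ws * stiff$plateau_rigor)
  out <- structure(list(report = report, kinetics = kin, dwell_fits = fits,
                        working_stroke = ws, stiffness = stiff, bell = bell,
                        config = config), class = "myotrap_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(config = unclass(config),
           package = as.character(utils::packageVersion("myotrap"))),
      file.path(config$out_dir, "config.json"), auto_unbox = TRUE,
      digits = NA, null = "null")
    utils::write.table(report, file.path(config$out_dir, "report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_events(ws$events, file.path(config$out_dir, "events.tsv"))
  }
  out
}

#' @export
print.myotrap_report <- function(x, ...) {
  cat("<myotrap_report>\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
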