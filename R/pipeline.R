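#' Default analysis configuration
#'
#' Every numeric default of the pipeline in one place. Values trace to the
#' experiment's protocol: 30-500 Hz / 6 Hz EMG conditioning, 6 Hz
#' kinematics (order 6) and GRF (order 4) low-pass, 20 N contact
#' threshold, 50-step windows, 5 representative steps, 40 ms
#' electromechanical delay, 2% EMG constraint band, 15-35% / 65-85%
#' stance peak windows.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    emg_band = c(30, 500), band_order = 4L,
    env_cutoff = 6, env_order = 4L,
    kin_cutoff = 6, kin_order = 6L,
    grf_cutoff = 6, grf_order = 4L,
    grf_threshold = 20, min_stance = 0.3,
    window_size = 50L, n_rep_steps = 5L,
    emg_delay = 0.040, emg_tolerance = 0.02,
    stance_grid_n = 101L,
    early_window = c(15, 35), late_window = c(65, 85),
    w_res = 1000,
    constrain_groups = "gastrocnemius",
    apply_emg_constraints = TRUE,
    groups = NULL  # NULL -> default_muscle_groups()
  )
}

# Normalized envelopes, stance windows and per-step stance means for one
# trial. Returns list(env, windows, means, rate).
trial_stance_means <- function(trial, config) {
  analog <- trial$analog
  rate <- analog$rate
  envs <- list()
  for (ch in trial$emg_channels) {
    x <- ts_channel(analog, ch)
    if (trial$emg_is_envelope) {
      envs[[ch]] <- x
    } else {
      mvc <- trial$meta$mvc_values[[ch]]
      if (is.null(mvc) || !is.finite(mvc))
        stop("no MVC value for channel ", ch)
      envs[[ch]] <- normalize_emg(
        process_emg(x, rate, band = config$emg_band,
                    band_order = config$band_order,
                    env_cutoff = config$env_cutoff,
                    env_order = config$env_order), mvc)
    }
  }
  vgrf <- filtfilt_zp(butter_design(config$grf_order, config$grf_cutoff, rate, "low"),
                      ts_channel(analog, "vertical_grf"))
  w <- segment_steps(vgrf, rate, config$grf_threshold, config$min_stance)
  means <- matrix(NA_real_, nrow(w), length(envs),
                  dimnames = list(NULL, names(envs)))
  for (s in seq_len(nrow(w)))
    for (ch in names(envs))
      means[s, ch] <- stance_mean(envs[[ch]], w[s, ])
  list(env = envs, windows = w, means = means, rate = rate)
}

# Map an analog-rate stance window onto another sampling rate via time.
convert_window_rate <- function(w, from_rate, to_rate, n_to) {
  onset <- floor((w$onset - 1) / from_rate * to_rate) + 1L
  offset <- min(n_to + 1L, ceiling((w$offset - 1) / from_rate * to_rate) + 1L)
  list(onset = onset, offset = offset,
       duration = (offset - onset) / to_rate)
}

# Static-optimization contact-force analysis for a set of representative
# steps of one trial. Returns per-step curves, metrics and stance-mean
# gastrocnemius activations/EMG.
model_steps <- function(trial, stance, step_rows, model, config,
                        emg_factor = NULL) {
  mech <- trial$mech
  if (is.null(mech)) stop("msk stage: trial has no mechanics channels")
  mech_f <- lowpass_kinematics(mech, c("hip_angle", "knee_angle", "ankle_angle"),
                               config$kin_cutoff, config$kin_order)
  ng <- config$stance_grid_n
  grid <- seq(0, 100, length.out = ng)
  groups <- config$groups %||% default_muscle_groups()
  gas_ch <- intersect(groups$gastrocnemius, names(stance$env))
  gas_env <- Reduce(`+`, stance$env[gas_ch]) / length(gas_ch)
  gas_del <- apply_emg_delay(gas_env, stance$rate, config$emg_delay)

  out <- list()
  for (k in seq_along(step_rows)) {
    w <- stance$windows[step_rows[k], ]
    wm <- convert_window_rate(w, stance$rate, mech$rate, n_samples(mech))
    ang <- cbind(hip = resample_stance(ts_channel(mech_f, "hip_angle"), wm, ng),
                 knee = resample_stance(ts_channel(mech_f, "knee_angle"), wm, ng),
                 ankle = resample_stance(ts_channel(mech_f, "ankle_angle"), wm, ng))
    mom <- cbind(hip = resample_stance(ts_channel(mech, "hip_moment"), wm, ng),
                 knee = resample_stance(ts_channel(mech, "knee_moment"), wm, ng),
                 ankle = resample_stance(ts_channel(mech, "ankle_moment"), wm, ng))
    interseg <- resample_stance(ts_channel(mech, "knee_axial_interseg"), wm, ng)
    emg_grid <- resample_stance(gas_del, w, ng)

    constraints <- NULL
    if (!is.null(emg_factor) && isTRUE(config$apply_emg_constraints))
      constraints <- list(gastrocnemius =
                            build_emg_constraints(emg_grid, emg_factor,
                                                  config$emg_tolerance))
    sol <- solve_static_optimization(model, mom, ang, constraints)
    curve <- knee_contact_force(model, sol, interseg, trial$meta$body_mass,
                                stance_duration = w$duration, grid = grid)
    out[[k]] <- list(
      sol = sol, curve = curve,
      peaks = peak_metrics(curve),
      impulse = contact_impulse(curve),
      gas_act_mean = mean(sol$activations[, "gastrocnemius"]),
      gas_emg_mean = mean(emg_grid),
      angles = ang, moments = mom)
  }
  out
}

mean_metrics <- function(steps) {
  c(early_peak = mean(vapply(steps, function(s) s$peaks[["early_peak"]], 0)),
    late_peak = mean(vapply(steps, function(s) s$peaks[["late_peak"]], 0)),
    impulse = mean(vapply(steps, function(s) s$impulse, 0)))
}

#' Run the full analysis for one participant
#'
#' Stages, in order: EMG conditioning and normalization, GRF filtering and
#' step segmentation, per-step stance means, group percent changes from
#' baseline, 50-step window selection (gastrocnemius + vasti objective),
#' representative-step selection, electromechanical delay, unconstrained
#' baseline static optimization, EMG-to-activation scale-factor
#' calibration, EMG-constrained feedback static optimization, knee contact
#' force and its peak/impulse metrics.
#'
#' @param participant A `synthetic_participant` or an equivalent list with
#'   `baseline` ([gait_trial()]), `feedback` (list of trials) and
#'   `participant_id`.
#' @param config Configuration list; see [default_config()].
#' @param model Optional [msk_model()]; built from the participant's
#'   anthropometry when `NULL`.
#' @return Object of class `participant_result`.
#' @export
run_participant <- function(participant, config = default_config(),
                            model = NULL) {
  pid <- participant$participant_id %||% "participant"
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(pid, " [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  groups <- config$groups %||% default_muscle_groups()

  base_st <- stage("signal_processing", trial_stance_means(participant$baseline, config))
  base_groups <- stage("grouping", group_emg(base_st$means, groups))
  baseline_group_means <- colMeans(base_groups)

  fb_st <- list(); records <- NULL
  for (t in seq_along(participant$feedback)) {
    st <- stage("signal_processing", trial_stance_means(participant$feedback[[t]], config))
    fb_st[[t]] <- st
    gm <- stage("grouping", group_emg(st$means, groups))
    rec <- step_records(gm, baseline_group_means, trial = t)
    records <- if (is.null(records)) rec else rbind(records, rec)
  }
  class(records) <- c("trial_step_records", "data.frame")

  win_gas <- stage("window_selection", best_gastroc_window(records, config$window_size))
  win_sel <- stage("window_selection", gastroc_vasti_window(records, config$window_size))

  # representative steps: feedback uses the selected window's mean key;
  # baseline uses the baseline trial's own mean
  sel_rows_local <- stage("window_selection",
                          representative_steps(win_sel$records, config$n_rep_steps))
  sel_rows <- seq(win_sel$start_step, win_sel$end_step)[sel_rows_local]
  base_records <- step_records(base_groups, baseline_group_means, trial = 0L)
  base_rows <- stage("window_selection",
                     representative_steps(base_records, config$n_rep_steps))

  result <- list(participant_id = pid,
                 baseline_group_means = baseline_group_means,
                 records = records,
                 best_gastroc_window = win_gas,
                 selected_window = win_sel,
                 pct_change = c(gastrocnemius = win_sel$mean_gastroc_pct,
                                vasti = win_sel$mean_vasti_pct),
                 group_pct_change = colMeans(
                   win_sel$records[, paste0(names(groups), "_pct"), drop = FALSE],
                   na.rm = TRUE),
                 rep_steps = list(baseline = base_rows, feedback = sel_rows))

  if (!is.null(participant$baseline$mech)) {
    meta <- participant$baseline$meta
    if (is.null(model))
      model <- msk_model(meta$body_mass, meta$height, w_res = config$w_res)

    # which feedback trial each selected row belongs to
    sel_trials <- records$trial[sel_rows]
    base_steps <- stage("msk", model_steps(participant$baseline, base_st,
                                           base_rows, model, config))
    factor <- stage("msk", emg_scale_factor(
      vapply(base_steps, function(s) s$gas_act_mean, 0),
      vapply(base_steps, function(s) s$gas_emg_mean, 0)))

    fb_steps <- list()
    for (k in seq_along(sel_rows)) {
      t <- sel_trials[k]
      rows_t <- which(records$trial == t)
      local_row <- match(sel_rows[k], rows_t)
      fb_steps[[k]] <- stage("msk", model_steps(
        participant$feedback[[t]], fb_st[[t]], local_row, model, config,
        emg_factor = factor))[[1]]
    }
    bm <- mean_metrics(base_steps); fm <- mean_metrics(fb_steps)
    result$emg_scale_factor <- factor
    result$model_steps <- list(baseline = base_steps, feedback = fb_steps)
    result$contact <- list(
      baseline = bm, feedback = fm,
      delta = fm - bm,
      late_peak_pct = 100 * (fm[["late_peak"]] - bm[["late_peak"]]) /
        bm[["late_peak"]])
  }
  class(result) <- "participant_result"
  result
}

#' @export
print.participant_result <- function(x, ...) {
  cat(sprintf("<participant_result> %s: gastroc %+.1f%%, vasti %+.1f%%\n",
              x$participant_id, x$pct_change[["gastrocnemius"]],
              x$pct_change[["vasti"]]))
  if (!is.null(x$contact))
    cat(sprintf("  late peak %+.3f BW (%+.1f%%), early peak %+.3f BW, impulse %+.3f BW.s\n",
                x$contact$delta[["late_peak"]], x$contact$late_peak_pct,
                x$contact$delta[["early_peak"]], x$contact$delta[["impulse"]]))
  invisible(x)
}

#' Run the analysis and statistics for a cohort
#'
#' Runs [run_participant()] on everyone, then the statistics layer: the two
#' primary outcomes (gastrocnemius EMG, late-stance contact peak) are
#' tested without multiplicity correction; all exploratory outcomes share
#' one Benjamini-Hochberg family.
#'
#' @param cohort A `synthetic_cohort`, or a list of participant bundles.
#' @param config See [default_config()].
#' @return Object of class `cohort_report`: `participants` (results),
#'   `outcomes` (per-participant data.frame), `tests`, `summary`.
#' @export
run_cohort <- function(cohort, config = default_config()) {
  participants <- if (inherits(cohort, "synthetic_cohort")) cohort$participants
                  else cohort
  results <- lapply(participants, run_participant, config = config)
  n <- length(results)

  has_contact <- !vapply(results, function(r) is.null(r$contact), TRUE)
  getp <- function(f) vapply(results, f, 0)
  outcomes <- data.frame(
    participant_id = vapply(results, `[[`, "", "participant_id"),
    gastroc_pct = getp(function(r) r$pct_change[["gastrocnemius"]]),
    vasti_pct = getp(function(r) r$pct_change[["vasti"]]))
  grp_names <- names(results[[1]]$group_pct_change)
  for (g in grp_names)
    outcomes[[paste0(sub("_pct$", "", g), "_change")]] <-
      getp(function(r) r$group_pct_change[[g]])
  if (all(has_contact)) {
    for (m in c("early_peak", "late_peak", "impulse")) {
      outcomes[[paste0(m, "_base")]] <- getp(function(r) r$contact$baseline[[m]])
      outcomes[[paste0(m, "_fb")]] <- getp(function(r) r$contact$feedback[[m]])
      outcomes[[paste0(m, "_delta")]] <- getp(function(r) r$contact$delta[[m]])
    }
  }

  tests <- list(); warn <- character(0)
  if (n >= 2) {
    # primary outcomes, uncorrected
    tests$gastroc_emg <- paired_compare(
      rep(0, n), outcomes$gastroc_pct, outcome = "gastrocnemius EMG change (%)")
    if (all(has_contact))
      tests$late_peak <- paired_compare(outcomes$late_peak_base,
                                        outcomes$late_peak_fb,
                                        outcome = "late-stance peak (BW)")
    # exploratory family, BH-adjusted together
    expl <- list(vasti_emg = list(rep(0, n), outcomes$vasti_pct,
                                  "vasti EMG change (%)"))
    if (all(has_contact)) {
      expl$early_peak <- list(outcomes$early_peak_base, outcomes$early_peak_fb,
                              "early-stance peak (BW)")
      expl$impulse <- list(outcomes$impulse_base, outcomes$impulse_fb,
                           "contact impulse (BW.s)")
    }
    etests <- lapply(expl, function(e) paired_compare(e[[1]], e[[2]], e[[3]]))
    padj <- bh_adjust(vapply(etests, `[[`, 0, "p"))
    for (i in seq_along(etests)) etests[[i]]$p_adj <- padj[i]
    tests <- c(tests, etests)
  } else {
    warn <- c(warn, "fewer than 2 participants: descriptive report only")
  }

  deltas <- data.frame(gastroc_pct = outcomes$gastroc_pct,
                       vasti_pct = outcomes$vasti_pct)
  if (all(has_contact)) {
    deltas$late_peak <- outcomes$late_peak_delta
    deltas$early_peak <- outcomes$early_peak_delta
    deltas$impulse <- outcomes$impulse_delta
  }
  summary <- cohort_summary(deltas)

  structure(list(participants = results, outcomes = outcomes,
                 tests = tests, summary = summary, warnings = warn),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> n=%d participants\n", nrow(x$outcomes)))
  for (t in x$tests) {
    cat(sprintf("  %-32s mean %+8.3f +/- %.3f  p=%.4g%s\n",
                t$outcome, t$mean_diff, t$sd_diff, t$p,
                if (is.finite(t$p_adj)) sprintf(" (adj %.4g)", t$p_adj) else ""))
  }
  invisible(x)
}

#' Write the cohort report tables to CSV
#'
#' @param report A `cohort_report`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "outcomes.csv")
  utils::write.csv(report$outcomes, p1, row.names = FALSE)
  tests <- do.call(rbind, lapply(report$tests, function(t)
    data.frame(outcome = t$outcome, test = t$test, statistic = t$statistic,
               p = t$p, p_adj = t$p_adj, mean_diff = t$mean_diff,
               sd_diff = t$sd_diff, n = t$n)))
  p2 <- file.path(dir, "tests.csv")
  utils::write.csv(tests, p2, row.names = FALSE)
  p3 <- file.path(dir, "summary.csv")
  utils::write.csv(report$summary, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
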