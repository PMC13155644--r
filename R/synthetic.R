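#' Parameters of the synthetic gait cohort
#'
#' The generator's defaults encode the experimental conditions the analysis
#' targets: a 13-participant cohort walking six-minute feedback trials with
#' a mean true gastrocnemius reduction of 25% (between-participant SD 15%,
#' truncated at zero), vasti compensation proportional to the achieved
#' reduction, and a fraction `gamma` of the gastrocnemius reduction
#' transmitted to the late-stance ankle and knee moments.
#'
#' @param n_participants Cohort size (default 13).
#' @param steps_per_trial Feedback-leg steps per six-minute feedback trial
#'   (default 150, ~1.1 s stride at ~0.4 s swing).
#' @param baseline_steps Steps in the two-minute baseline trial (default 50).
#' @param trials_per_session Feedback trials generated (default 3).
#' @param analog_rate EMG/GRF sampling rate in Hz. Must exceed 1000 Hz in
#'   raw mode (default 2000 raw, 200 envelope).
#' @param mech_rate Kinematics/kinetics rate in Hz (default 100).
#' @param stance_mean,stance_sd Stance duration distribution in s.
#' @param swing_mean Swing duration in s.
#' @param mu_r,sigma_r True mean and between-participant SD of the
#'   gastrocnemius reduction, in percent (defaults 25, 15).
#' @param step_sd Within-participant per-step SD of the realized reduction,
#'   in percentage points (default 4).
#' @param vasti_step_sd Within-participant per-step SD of the vasti
#'   compensation noise, independent of the `kappa` coupling, in percentage
#'   points (default 12). Without it the vasti envelope would be perfectly
#'   collinear with the gastrocnemius reduction and the joint
#'   gastrocnemius-plus-vasti window objective would be degenerate.
#' @param ar1_phi AR(1) coefficient of the step-to-step reduction noise.
#' @param kappa_mean,kappa_sd Vasti compensation coefficient distribution:
#'   the vasti amplitude gains `kappa * realized reduction` (defaults 1.5,
#'   0.5, putting the mean vasti increase near +38% at a 25% reduction).
#' @param cocontraction0_mean,cocontraction0_sd Participant-level transient
#'   co-contraction: extra vasti amplitude (fraction, default mean 0.3)
#'   present at the start of training and decaying with the same learning
#'   curve as the reduction, reflecting the elevated co-contraction typical
#'   of early motor learning.
#' @param gamma Moment-coupling gain in `[0, 1]` (default 0.5).
#' @param amp_jitter Multiplicative per-step amplitude jitter SD.
#' @param noise_floor Additive envelope noise floor (fraction of MVC).
#' @param emg_mode `"envelope"` (channels are already normalized envelopes)
#'   or `"raw"` (band-limited carrier noise modulated by the envelope, in
#'   volts, to exercise the full conditioning chain).
#' @param modeling Generate mechanics channels (angles, moments,
#'   intersegmental axial knee force)?
#' @param learning_tau Trial constant of the saturating-exponential
#'   learning curve; the default reaches 95% of the true reduction by the
#'   end of trial 2.
#' @param seed Integer seed; fixed seed gives bit-identical cohorts.
#' @return List of class `cohort_params`.
#' @export
cohort_params <- function(n_participants = 13L,
                          steps_per_trial = 150L,
                          baseline_steps = 50L,
                          trials_per_session = 3L,
                          analog_rate = NULL,
                          mech_rate = 100,
                          stance_mean = 0.65, stance_sd = 0.03,
                          swing_mean = 0.45,
                          mu_r = 25, sigma_r = 15,
                          step_sd = 4, vasti_step_sd = 12, ar1_phi = 0.7,
                          kappa_mean = 1.5, kappa_sd = 0.5,
                          cocontraction0_mean = 0.3, cocontraction0_sd = 0.1,
                          gamma = 0.5,
                          amp_jitter = 0.03,
                          noise_floor = 0.003,
                          emg_mode = c("envelope", "raw"),
                          modeling = TRUE,
                          learning_tau = 2 / log(20),
                          seed = 1L) {
  emg_mode <- match.arg(emg_mode)
  if (is.null(analog_rate))
    analog_rate <- if (emg_mode == "raw") 2000 else 200
  if (emg_mode == "raw" && analog_rate <= 1000)
    stop("raw EMG synthesis requires analog_rate > 1000 Hz")
  stopifnot(sigma_r >= 0, step_sd >= 0, kappa_sd >= 0,
            gamma >= 0, gamma <= 1, stance_sd >= 0, n_participants >= 1)
  structure(as.list(environment()), class = "cohort_params")
}

# Gaussian bump on the percent-stance axis (p in [0, 1]).
bump <- function(p, center, width) exp(-(p - center)^2 / (2 * width^2))

# Envelope templates: amplitude (fraction of MVC), center, width on [0, 1].
# Centers lead the corresponding moment lobes by ~6% stance (the 40 ms
# electromechanical delay at a 0.65 s stance), so that the delayed EMG
# aligns with the static-optimization activation waveform.
muscle_templates <- function() {
  data.frame(
    muscle = c("gastroc_med", "gastroc_lat", "soleus", "vastus_med",
               "vastus_lat", "biceps_fem", "semitend", "rectus_fem",
               "tib_ant"),
    amp    = c(0.35, 0.30, 0.40, 0.25, 0.22, 0.28, 0.25, 0.12, 0.20),
    center = c(0.66, 0.66, 0.64, 0.16, 0.16, 0.06, 0.06, 0.25, 0.05),
    width  = c(0.16, 0.16, 0.16, 0.12, 0.12, 0.10, 0.10, 0.12, 0.08)
  )
}

# Vertical GRF template in body weights.
grf_shape <- function(p) {
  (0.95 * bump(p, 0.27, 0.13) + 0.98 * bump(p, 0.75, 0.13) + 0.30) *
    sin(pi * pmin(pmax(p, 0), 1))^0.3
}

# Intersegmental axial knee force template in body weights (compression +).
interseg_shape <- function(p) {
  (0.80 * bump(p, 0.27, 0.14) + 0.85 * bump(p, 0.75, 0.14) + 0.35) *
    sin(pi * pmin(pmax(p, 0), 1))^0.3
}

# Sagittal angle templates in degrees (hip flexion, knee extension and
# ankle plantarflexion positive). `dorsi_shift` adds early-stance
# dorsiflexion proportional to the realized reduction.
angle_templates <- function(p, dorsi_shift = 0) {
  list(hip = 20 - 35 * p,
       knee = -(8 + 12 * bump(p, 0.18, 0.10) + 30 * bump(p, 1.0, 0.10)),
       ankle = -14 * bump(p, 0.60, 0.25) + 20 * bump(p, 0.95, 0.08) -
         dorsi_shift * bump(p, 0.25, 0.15))
}

# Moment templates in N·m; late-stance lobes scale with (1 - gamma * red).
moment_templates <- function(p, mass, red = 0, gamma = 0) {
  late <- 1 - gamma * red
  list(hip = mass * (-0.60 * bump(p, 0.15, 0.15) + 0.40 * bump(p, 0.85, 0.15)),
       knee = mass * (0.45 * bump(p, 0.20, 0.12) - 0.30 * late * bump(p, 0.78, 0.12)),
       ankle = mass * (1.40 * late * bump(p, 0.72, 0.16) - 0.15 * bump(p, 0.05, 0.06)))
}

# Saturating-exponential learning curve: trial t (1-based), within-trial
# progress u in [0, 1]; 0 for the baseline trial.
learning_curve <- function(trial, u, tau) 1 - exp(-(trial - 1 + u) / tau)

# Generate one trial (baseline or feedback) for a participant.
# reductions: per-step realized gastroc reduction (fraction), NULL for baseline.
# vasti_noise: per-step additive vasti amplitude noise, independent of the
# kappa coupling (zero for baseline).
gen_trial <- function(params, meta, reductions, kappa, emg_mode, modeling,
                      vasti_noise = NULL) {
  tpl <- muscle_templates()
  n_steps <- if (is.null(reductions)) params$baseline_steps
             else length(reductions)
  stance <- pmax(0.4, stats::rnorm(n_steps, params$stance_mean, params$stance_sd))
  swing <- pmax(0.3, stats::rnorm(n_steps, params$swing_mean, 0.02))
  lead <- 0.4
  onset_t <- lead + cumsum(c(0, (stance + swing)[-n_steps]))
  total <- lead + sum(stance + swing) + 0.4

  rate <- params$analog_rate
  n <- ceiling(total * rate)
  time <- (seq_len(n) - 1) / rate
  jit <- matrix(1 + stats::rnorm(n_steps * nrow(tpl), 0, params$amp_jitter),
                n_steps, nrow(tpl))

  env <- matrix(0, n, nrow(tpl), dimnames = list(NULL, tpl$muscle))
  grf <- numeric(n)
  gas <- grepl("^gastroc", tpl$muscle)
  vas <- grepl("^vastus", tpl$muscle)
  for (s in seq_len(n_steps)) {
    i0 <- floor(onset_t[s] * rate) + 1L
    i1 <- min(n, floor((onset_t[s] + stance[s]) * rate))
    p <- (time[i0:i1] - onset_t[s]) / stance[s]
    red <- if (is.null(reductions)) 0 else reductions[s]
    nu <- if (is.null(vasti_noise)) 0 else vasti_noise[s]
    fac <- rep(1, nrow(tpl))
    fac[gas] <- max(0.05, 1 - red)
    fac[vas] <- max(0.05, 1 + kappa * red + nu)
    for (m in seq_len(nrow(tpl)))
      env[i0:i1, m] <- tpl$amp[m] * fac[m] * jit[s, m] *
        bump(p, tpl$center[m], tpl$width[m])
    grf[i0:i1] <- meta$body_mass * 9.81 * grf_shape(p)
  }
  env <- env + abs(matrix(stats::rnorm(n * nrow(tpl), 0, params$noise_floor),
                          n, nrow(tpl)))

  if (emg_mode == "raw") {
    # carrier: unit-variance band-limited white noise, modulated by the
    # envelope and scaled into volts by each muscle's MVC value
    bp <- butter_design(4L, c(30, 500), rate, "band")
    mvc <- meta$mvc_values
    for (m in seq_len(ncol(env))) {
      carrier <- filtfilt_zp(bp, stats::rnorm(n))
      carrier <- carrier / stats::sd(carrier)
      env[, m] <- carrier * env[, m] * mvc[[tpl$muscle[m]]]
    }
  }

  channels <- c(stats::setNames(lapply(seq_len(ncol(env)), function(m) env[, m]),
                                tpl$muscle),
                list(vertical_grf = grf))
  analog <- gait_ts(time, channels, rate = rate)

  mech <- NULL
  if (modeling) {
    mrate <- params$mech_rate
    nm <- ceiling(total * mrate)
    mtime <- (seq_len(nm) - 1) / mrate
    mch <- list(hip_angle = numeric(nm), knee_angle = numeric(nm),
                ankle_angle = numeric(nm), hip_moment = numeric(nm),
                knee_moment = numeric(nm), ankle_moment = numeric(nm),
                knee_axial_interseg = numeric(nm))
    for (s in seq_len(n_steps)) {
      i0 <- floor(onset_t[s] * mrate) + 1L
      i1 <- min(nm, floor((onset_t[s] + stance[s]) * mrate))
      p <- (mtime[i0:i1] - onset_t[s]) / stance[s]
      red <- if (is.null(reductions)) 0 else reductions[s]
      ang <- angle_templates(p, dorsi_shift = 12 * red)
      mom <- moment_templates(p, meta$body_mass, red = red,
                              gamma = params$gamma)
      mch$hip_angle[i0:i1] <- ang$hip
      mch$knee_angle[i0:i1] <- ang$knee
      mch$ankle_angle[i0:i1] <- ang$ankle
      mch$hip_moment[i0:i1] <- mom$hip
      mch$knee_moment[i0:i1] <- mom$knee
      mch$ankle_moment[i0:i1] <- mom$ankle
      # intersegmental axial force is held at its baseline template in
      # feedback trials: changes in contact force flow through the muscles
      mch$knee_axial_interseg[i0:i1] <-
        meta$body_mass * 9.81 * interseg_shape(p)
    }
    mech <- gait_ts(mtime, mch, rate = mrate)
  }

  gait_trial(analog = analog, mech = mech, meta = meta,
             emg_channels = tpl$muscle,
             emg_is_envelope = (emg_mode == "envelope"))
}

#' Generate one synthetic participant
#'
#' One baseline trial plus `trials_per_session` feedback trials with known
#' per-step realized gastrocnemius reductions (the ground truth). The
#' realized reduction of step `s` in trial `t` is
#' `r_i * learning(t, s) + AR(1) noise`; the vasti envelope gains
#' `kappa_i` times the realized reduction; the late-stance ankle and knee
#' moment lobes shrink by `gamma` times the realized reduction.
#'
#' @param params A [cohort_params()].
#' @param participant_seed Integer seed for this participant.
#' @param participant_id Identifier string.
#' @param r True reduction as a fraction (e.g. 0.25); drawn from the
#'   truncated normal `TN(mu_r, sigma_r) / 100` when `NULL`.
#' @param kappa Vasti compensation coefficient; drawn when `NULL`.
#' @return List of class `synthetic_participant`: `participant_id`,
#'   `baseline` ([gait_trial()]), `feedback` (list of trials), `truth`
#'   (list: `r`, `kappa`, `steps` data.frame with per-step realized
#'   reductions), `meta`.
#' @export
generate_participant <- function(params, participant_seed,
                                 participant_id = "P01",
                                 r = NULL, kappa = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(as.integer(participant_seed))
  if (is.null(r)) {
    repeat {
      r <- stats::rnorm(1, params$mu_r, params$sigma_r) / 100
      if (r >= 0) break
    }
  }
  if (is.null(kappa)) kappa <- max(0, stats::rnorm(1, params$kappa_mean,
                                                   params$kappa_sd))
  c0 <- max(0, stats::rnorm(1, params$cocontraction0_mean,
                            params$cocontraction0_sd))
  mass <- max(45, stats::rnorm(1, 78.2, 17.4))
  height <- max(1.4, stats::rnorm(1, 1.75, 0.12))
  tpl <- muscle_templates()
  mvc <- stats::setNames(rep(2e-3, nrow(tpl)), tpl$muscle)  # 2 mV MVC envelope
  meta_b <- trial_meta(participant_id, 2L, "baseline", mass, height,
                       treadmill_speed = max(0.5, stats::rnorm(1, 0.99, 0.19)),
                       mvc_values = mvc)

  baseline <- gen_trial(params, meta_b, reductions = NULL, kappa = kappa,
                        emg_mode = params$emg_mode, modeling = params$modeling)

  feedback <- vector("list", params$trials_per_session)
  truth_steps <- list()
  for (t in seq_len(params$trials_per_session)) {
    ns <- params$steps_per_trial
    u <- seq_len(ns) / ns
    L <- learning_curve(t, u, params$learning_tau)
    ar1 <- function(ns, sd_marg) {
      x <- numeric(ns)
      sdq <- sd_marg * sqrt(1 - params$ar1_phi^2)
      for (s in seq_len(ns))
        x[s] <- if (s == 1) stats::rnorm(1, 0, sd_marg)
                else params$ar1_phi * x[s - 1] + stats::rnorm(1, 0, sdq)
      x
    }
    eps <- ar1(ns, params$step_sd / 100)
    # vasti amplitude noise plus the early-learning co-contraction transient
    nu <- ar1(ns, params$vasti_step_sd / 100) + c0 * (1 - L)
    realized <- r * L + eps
    meta_f <- meta_b; meta_f$trial_kind <- "feedback"
    feedback[[t]] <- gen_trial(params, meta_f, reductions = realized,
                               kappa = kappa, emg_mode = params$emg_mode,
                               modeling = params$modeling,
                               vasti_noise = nu)
    truth_steps[[t]] <- data.frame(trial = t, step = seq_len(ns),
                                   realized_reduction = realized)
  }
  structure(list(participant_id = participant_id,
                 baseline = baseline, feedback = feedback,
                 truth = list(r = r, kappa = kappa, cocontraction0 = c0,
                              steps = do.call(rbind, truth_steps)),
                 meta = meta_b),
            class = "synthetic_participant")
}

#' Generate a synthetic cohort
#'
#' Independent participants with true reductions drawn from the truncated
#' normal `TN(mu_r, sigma_r^2; r >= 0)`. A fixed seed yields a
#' bit-identical cohort.
#'
#' @param params A [cohort_params()].
#' @return List of class `synthetic_cohort`: `participants` (list of
#'   [generate_participant()] outputs), `truth` (data.frame of
#'   per-participant `r` and `kappa`), `params`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(as.integer(params$seed))
  n <- params$n_participants
  seeds <- sample.int(2^31 - 2, n)
  participants <- vector("list", n)
  for (i in seq_len(n)) {
    participants[[i]] <- generate_participant(
      params, seeds[i], participant_id = sprintf("P%02d", i))
  }
  truth <- data.frame(
    participant_id = vapply(participants, `[[`, "", "participant_id"),
    r = vapply(participants, function(p) p$truth$r, 0),
    kappa = vapply(participants, function(p) p$truth$kappa, 0))
  structure(list(participants = participants, truth = truth, params = params),
            class = "synthetic_cohort")
}

#' Theoretical mean of the truncated reduction distribution
#'
#' Mean of `TN(mu_r, sigma_r^2; r >= 0)` in percent: the expected value of a
#' participant's true reduction under the generator, used by recovery tests
#' as the exact target (truncation at zero shifts the mean above `mu_r`).
#'
#' @param mu_r,sigma_r Generator parameters in percent.
#' @return Expected reduction in percent.
#' @export
truncated_mean_reduction <- function(mu_r, sigma_r) {
  if (sigma_r == 0) return(mu_r)
  alpha <- -mu_r / sigma_r
  mu_r + sigma_r * stats::dnorm(alpha) / (1 - stats::pnorm(alpha))
}

#' Write a synthetic participant's trials to disk in pipeline formats
#'
#' @param participant A `synthetic_participant`.
#' @param dir Output directory (created if needed).
#' @param dialect `"sto_mot"` or `"csv"`.
#' @return Invisibly, the written file paths.
#' @export
write_participant <- function(participant, dir, dialect = c("sto_mot", "csv")) {
  dialect <- match.arg(dialect)
  ext <- if (dialect == "csv") "csv" else "sto"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(trial, tag) {
    p1 <- file.path(dir, sprintf("%s_%s_analog.%s",
                                 participant$participant_id, tag, ext))
    write_timeseries(trial$analog, p1, dialect)
    ps <- p1
    if (!is.null(trial$mech)) {
      p2 <- file.path(dir, sprintf("%s_%s_mech.%s",
                                   participant$participant_id, tag, ext))
      write_timeseries(trial$mech, p2, dialect)
      ps <- c(ps, p2)
    }
    ps
  }
  paths <- c(paths, emit(participant$baseline, "baseline"))
  for (t in seq_along(participant$feedback))
    paths <- c(paths, emit(participant$feedback[[t]], sprintf("feedback%d", t)))
  tr <- file.path(dir, sprintf("%s_ground_truth.csv", participant$participant_id))
  utils::write.csv(participant$truth$steps, tr, row.names = FALSE)
  invisible(c(paths, tr))
}
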