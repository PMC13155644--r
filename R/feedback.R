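#' Feedback controller state
#'
#' Holds the baseline stance-mean gastrocnemius EMG value and the current
#' adaptive goal (percent reduction from baseline, one of 10/20/30).
#'
#' @param baseline_value Stance-mean normalized gastrocnemius EMG of the
#'   baseline trial (> 0).
#' @param goal Current goal in percent reduction; 10, 20 or 30.
#' @param trial_index Number of feedback trials already completed.
#' @return Object of class `feedback_state`.
#' @export
feedback_state <- function(baseline_value, goal = 10, trial_index = 0L) {
  if (!is.numeric(baseline_value) || baseline_value <= 0)
    stop("`baseline_value` must be > 0")
  if (!goal %in% c(10, 20, 30)) stop("`goal` must be 10, 20 or 30")
  structure(list(baseline_value = baseline_value, goal = goal,
                 trial_index = as.integer(trial_index)),
            class = "feedback_state")
}

#' Percent change of a step's EMG from baseline
#'
#' @param step_mean Stance-mean normalized EMG of the step.
#' @param baseline_value Baseline stance-mean EMG (> 0).
#' @return Percent change; negative values are reductions.
#' @export
percent_change <- function(step_mean, baseline_value) {
  if (!is.numeric(baseline_value) || any(baseline_value <= 0))
    stop("`baseline_value` must be > 0")
  100 * (step_mean - baseline_value) / baseline_value
}

#' Number of haptic vibrations for one step
#'
#' Two vibrations when the step's average EMG stays above 95% of baseline
#' (reduction of 5% or less), one vibration for a reduction between 5% and
#' the current goal, none once the reduction reaches the goal. Boundary
#' handling: exactly -5% earns one vibration; exactly -goal earns none.
#'
#' @param pct Percent change from baseline (vectorized).
#' @param goal Current goal (10, 20 or 30).
#' @return Integer vector in `{0, 1, 2}`.
#' @export
vibration_count <- function(pct, goal) {
  if (!all(goal %in% c(10, 20, 30))) stop("`goal` must be 10, 20 or 30")
  ifelse(pct > -5, 2L, ifelse(pct <= -goal, 0L, 1L))
}

# Moving averages of x over contiguous windows of length w; empty when n < w.
moving_average <- function(x, w) {
  n <- length(x)
  if (n < w) return(numeric(0))
  cs <- cumsum(c(0, x))
  (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
}

#' Advance the adaptive goal after a feedback trial
#'
#' If any within-trial moving average of the per-step percent changes over
#' `window` consecutive steps meets or beats the current goal, the goal is
#' tightened by 10 percentage points for the next trial, up to the 30%
#' maximum. Goal changes only take effect at trial boundaries.
#'
#' @param state A [feedback_state()].
#' @param trial_pcts Per-step percent changes of the completed trial.
#' @param window Moving-average window in steps (default 50).
#' @return Updated [feedback_state()].
#' @export
update_goal <- function(state, trial_pcts, window = 50L) {
  stopifnot(inherits(state, "feedback_state"), window >= 1)
  ma <- moving_average(trial_pcts, window)
  achieved <- length(ma) > 0 && any(ma <= -state$goal)
  goal <- if (achieved) min(state$goal + 10, 30) else state$goal
  feedback_state(state$baseline_value, goal, state$trial_index + 1L)
}

#' Session qualification check
#'
#' Session 1 qualifies a participant (for session 2) at an average 10%
#' reduction over `window` consecutive steps; session 2's early-finish
#' criterion is a 20% average reduction. Windows never span trial
#' boundaries.
#'
#' @param session 1 or 2.
#' @param all_trial_pcts List of per-trial numeric vectors of per-step
#'   percent changes.
#' @param window Moving-average window in steps (default 50).
#' @return List with `qualified` (logical), `best_window_avg` (minimum
#'   moving average in percent, `NA` if no trial has `window` steps) and
#'   `criterion` (the reduction threshold used, in percent).
#' @export
assess_qualification <- function(session, all_trial_pcts, window = 50L) {
  stopifnot(session %in% c(1, 2), window >= 1)
  crit <- if (session == 1) 10 else 20
  mas <- unlist(lapply(all_trial_pcts, moving_average, w = window))
  if (length(mas) == 0L)
    return(list(qualified = FALSE, best_window_avg = NA_real_, criterion = crit))
  best <- min(mas)
  list(qualified = best <= -crit, best_window_avg = best, criterion = crit)
}

#' Replay a full feedback session
#'
#' Runs the per-step vibration feedback and the adaptive goal progression
#' over a sequence of feedback trials, stopping early once the session's
#' qualification criterion has been met and the minimum trial count reached
#' (3 trials in session 1, 2 in session 2), or after 5 trials at most.
#'
#' @param trials List of numeric vectors: per-step stance-mean normalized
#'   gastrocnemius EMG for each available feedback trial (up to 5).
#' @param state0 Initial [feedback_state()] (goal 10, or 20 in session 2 for
#'   participants who reached the 30% goal in session 1).
#' @param session 1 or 2.
#' @param window Moving-average window in steps.
#' @param min_trials,max_trials Session trial-count rules; defaults follow
#'   the session number.
#' @return A `session_log`: list with `steps` (data.frame: trial,
#'   step_index, percent_change, vibrations, goal), `goal_by_trial`,
#'   `qualified`, `best_window_avg`, `n_trials_run`.
#' @export
run_session <- function(trials, state0, session = 1, window = 50L,
                        min_trials = if (session == 1) 3L else 2L,
                        max_trials = 5L) {
  stopifnot(inherits(state0, "feedback_state"), session %in% c(1, 2))
  if (length(trials) < 1L || length(trials) > max_trials)
    stop("between 1 and ", max_trials, " trials expected")
  state <- state0
  rows <- list()
  goal_by_trial <- integer(0)
  pcts_so_far <- list()
  n_run <- 0L
  for (ti in seq_along(trials)) {
    means <- trials[[ti]]
    if (length(means) == 0L) {
      warning("trial ", ti, " has no steps; skipped")
      next
    }
    n_run <- n_run + 1L
    pct <- percent_change(means, state$baseline_value)
    vib <- vibration_count(pct, state$goal)
    rows[[length(rows) + 1L]] <- data.frame(
      trial = ti, step_index = seq_along(means) - 1L,
      percent_change = pct, vibrations = vib, goal = state$goal)
    goal_by_trial <- c(goal_by_trial, state$goal)
    pcts_so_far[[length(pcts_so_far) + 1L]] <- pct
    state <- update_goal(state, pct, window)
    qual <- assess_qualification(session, pcts_so_far, window)
    if (qual$qualified && n_run >= min_trials) break
  }
  qual <- assess_qualification(session, pcts_so_far, window)
  structure(list(steps = do.call(rbind, rows),
                 goal_by_trial = goal_by_trial,
                 final_goal = state$goal,
                 qualified = qual$qualified,
                 best_window_avg = qual$best_window_avg,
                 n_trials_run = n_run),
            class = "session_log")
}

#' Write a session log to CSV
#'
#' @param log A `session_log` from [run_session()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  utils::write.csv(log$steps, path, row.names = FALSE)
  invisible(path)
}
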