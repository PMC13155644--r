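#' Uniformly sampled multi-channel time series
#'
#' The basic container for trial data: a strictly uniform time grid plus a
#' named set of equal-length channels (EMG in volts, ground reaction forces
#' in N, angles in degrees, moments in N·m, depending on the trial).
#'
#' @param time Numeric vector of sample times in seconds, strictly increasing
#'   with constant spacing.
#' @param channels Named list of numeric vectors, all the same length as
#'   `time`.
#' @param rate Sampling rate in Hz; inferred from `time` when `NULL`.
#' @return An object of class `gait_ts` with fields `time`, `channels`,
#'   `rate`.
#' @export
gait_ts <- function(time, channels, rate = NULL) {
  if (!is.numeric(time) || length(time) < 1L) stop("`time` must be non-empty numeric")
  if (!is.list(channels) || length(channels) == 0L)
    stop("`channels` must be a non-empty named list")
  nm <- names(channels)
  if (is.null(nm) || any(nm == "")) stop("all channels must be named")
  if (anyDuplicated(nm)) stop("duplicate channel names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  n <- length(time)
  bad <- which(vapply(channels, length, 1L) != n)
  if (length(bad))
    stop("channel length mismatch: ", paste(nm[bad], collapse = ", "))
  if (n > 1L) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("time must be strictly increasing (index ",
                           which(dt <= 0)[1], ")")
    if (max(dt) - min(dt) > 1e-9 + 1e-9 * dt[1]) {
      off <- which.max(abs(dt - dt[1]))
      stop("non-uniform sampling at index ", off,
           ": dt = ", signif(dt[off], 8), " vs ", signif(dt[1], 8))
    }
    inferred <- 1 / dt[1]
  } else {
    inferred <- rate
    if (is.null(inferred)) stop("`rate` required for single-sample series")
  }
  rate <- if (is.null(rate)) inferred else rate
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be positive")
  if (n > 1L && abs(rate - inferred) > 1e-6 * rate)
    stop("declared rate ", rate, " Hz inconsistent with time spacing (",
         signif(inferred, 8), " Hz)")
  structure(list(time = as.numeric(time),
                 channels = lapply(channels, as.numeric),
                 rate = as.numeric(rate)),
            class = "gait_ts")
}

#' @export
print.gait_ts <- function(x, ...) {
  cat(sprintf("<gait_ts> %d samples @ %g Hz, %d channel(s)\n",
              length(x$time), x$rate, length(x$channels)))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

n_samples <- function(ts) length(ts$time)

ts_channel <- function(ts, name) {
  if (!name %in% names(ts$channels))
    stop("channel not found: ", name)
  ts$channels[[name]]
}

#' Trial metadata
#'
#' Participant- and trial-level constants: anthropometry, treadmill speed and
#' the per-muscle maximum-voluntary-contraction (MVC) normalization values.
#'
#' @param participant_id Character id.
#' @param session Integer, 1 or 2.
#' @param trial_kind `"baseline"` or `"feedback"`.
#' @param body_mass Body mass in kg (> 0).
#' @param height Height in m (> 0).
#' @param treadmill_speed Belt speed in m/s.
#' @param mvc_values Named numeric vector, muscle -> MVC envelope value in
#'   volts (>= 0).
#' @return Object of class `trial_meta`.
#' @export
trial_meta <- function(participant_id, session, trial_kind, body_mass, height,
                       treadmill_speed = NA_real_, mvc_values = numeric(0)) {
  session <- as.integer(session)
  if (!session %in% c(1L, 2L)) stop("`session` must be 1 or 2")
  trial_kind <- match.arg(trial_kind, c("baseline", "feedback"))
  if (!is.numeric(body_mass) || body_mass <= 0) stop("`body_mass` must be > 0")
  if (!is.numeric(height) || height <= 0) stop("`height` must be > 0")
  if (length(mvc_values) && (is.null(names(mvc_values)) || any(mvc_values < 0)))
    stop("`mvc_values` must be named and non-negative")
  structure(list(participant_id = as.character(participant_id),
                 session = session, trial_kind = trial_kind,
                 body_mass = body_mass, height = height,
                 treadmill_speed = treadmill_speed,
                 mvc_values = mvc_values),
            class = "trial_meta")
}
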