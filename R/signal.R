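#' EMG conditioning chain
#'
#' Standard surface-EMG envelope extraction: zero-phase band-pass
#' (30-500 Hz, 4th order Butterworth), full-wave rectification, then
#' zero-phase low-pass (6 Hz, 4th order Butterworth). Both stages run
#' forward-backward, so no net phase shift is introduced.
#'
#' @param raw Raw EMG in volts.
#' @param rate Sampling rate in Hz; must exceed 1000 Hz so the 500 Hz band
#'   edge stays below Nyquist.
#' @param band Band-pass edges in Hz.
#' @param band_order,env_order Design orders of the two Butterworth stages.
#' @param env_cutoff Envelope low-pass cutoff in Hz.
#' @return Non-negative envelope in volts, same length as `raw`.
#' @export
process_emg <- function(raw, rate, band = c(30, 500), band_order = 4L,
                        env_cutoff = 6, env_order = 4L) {
  if (rate <= 2 * band[2])
    stop("sampling rate ", rate, " Hz too low for a ", band[2],
         " Hz band edge; lower the upper band edge in the configuration")
  if (anyNA(raw)) stop("NA/NaN in raw EMG")
  bp <- butter_design(band_order, band, rate, "band")
  lp <- butter_design(env_order, env_cutoff, rate, "low")
  env <- filtfilt_zp(lp, abs(filtfilt_zp(bp, raw)))
  pmax(env, 0)
}

#' Normalize an EMG envelope by its MVC value
#'
#' Division by the muscle's maximum-voluntary-contraction envelope value.
#' Values above 1 are retained: walking can exceed the MVC effort and
#' clipping would bias percent-change statistics.
#'
#' @param envelope Envelope in volts.
#' @param mvc_max MVC envelope value in volts (> 0).
#' @return Dimensionless normalized envelope (fraction of MVC).
#' @export
normalize_emg <- function(envelope, mvc_max) {
  if (!is.numeric(mvc_max) || length(mvc_max) != 1L || mvc_max <= 0)
    stop("`mvc_max` must be a single positive number")
  envelope / mvc_max
}

#' Low-pass filter kinematic channels (6 Hz, 6th order, zero phase)
#'
#' @param ts A [gait_ts()].
#' @param channels Channels to filter; defaults to all.
#' @param cutoff Cutoff in Hz.
#' @param order Design order.
#' @return The filtered [gait_ts()].
#' @export
lowpass_kinematics <- function(ts, channels = names(ts$channels),
                               cutoff = 6, order = 6L) {
  lowpass_ts(ts, channels, cutoff, order)
}

#' Low-pass filter ground-reaction-force channels (6 Hz, 4th order, zero phase)
#'
#' @inheritParams lowpass_kinematics
#' @return The filtered [gait_ts()].
#' @export
lowpass_grf <- function(ts, channels = names(ts$channels),
                        cutoff = 6, order = 4L) {
  lowpass_ts(ts, channels, cutoff, order)
}

lowpass_ts <- function(ts, channels, cutoff, order) {
  stopifnot(inherits(ts, "gait_ts"))
  if (ts$rate <= 2 * cutoff)
    stop("sampling rate ", ts$rate, " Hz must exceed twice the ", cutoff,
         " Hz cutoff")
  lp <- butter_design(order, cutoff, ts$rate, "low")
  for (nm in channels) ts$channels[[nm]] <- filtfilt_zp(lp, ts_channel(ts, nm))
  ts
}

#' Segment stance phases from the vertical ground reaction force
#'
#' Steps are detected as contiguous runs where the vertical GRF exceeds a
#' force threshold. Windows are half-open sample intervals
#' `[onset, offset)` (1-based onsets; the sample at `offset` is swing).
#' Runs shorter than `min_stance` seconds are discarded as debounce.
#'
#' @param vgrf Vertical GRF in N.
#' @param rate Sampling rate in Hz.
#' @param threshold Contact threshold in N (> 0), default 20 N.
#' @param min_stance Minimum stance duration in s, default 0.3 s.
#' @return A data.frame of class `stance_windows` with columns `onset`,
#'   `offset`, `duration`; zero rows when nothing crosses the threshold.
#' @export
segment_steps <- function(vgrf, rate, threshold = 20, min_stance = 0.3) {
  if (threshold <= 0) stop("`threshold` must be > 0")
  above <- vgrf > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  onset <- starts[keep]
  offset <- ends[keep] + 1L  # half-open
  dur <- (offset - onset) / rate
  ok <- dur >= min_stance
  out <- data.frame(onset = onset[ok], offset = offset[ok],
                    duration = dur[ok])
  class(out) <- c("stance_windows", "data.frame")
  out
}

check_window <- function(w, n) {
  onset <- w[["onset"]]; offset <- w[["offset"]]
  if (length(onset) != 1L || length(offset) != 1L)
    stop("expected a single stance window")
  if (offset <= onset) stop("empty stance window")
  if (onset < 1L || offset > n + 1L)
    stop("stance window [", onset, ", ", offset, ") outside signal of length ", n)
  c(onset, offset)
}

#' Mean of a signal over one stance window
#'
#' @param x Numeric signal (e.g. a normalized EMG envelope).
#' @param w One row of [segment_steps()] output (list/data.frame with `onset`,
#'   `offset`).
#' @return Arithmetic mean of `x` over `[onset, offset)`.
#' @export
stance_mean <- function(x, w) {
  b <- check_window(w, length(x))
  mean(x[b[1]:(b[2] - 1L)])
}

#' Resample a stance window onto a percent-stance grid
#'
#' Linear interpolation of the samples in `[onset, offset)` onto `n` evenly
#' spaced points spanning 0-100% of the window; the first and last samples
#' are preserved exactly.
#'
#' @param x Numeric signal.
#' @param w Stance window (`onset`, `offset`).
#' @param n Number of grid points (>= 2); default 101 (0, 1, ..., 100%).
#' @return Numeric vector of length `n`.
#' @export
resample_stance <- function(x, w, n = 101L) {
  if (n < 2L) stop("`n` must be >= 2")
  b <- check_window(w, length(x))
  seg <- x[b[1]:(b[2] - 1L)]
  if (length(seg) == 1L) return(rep(seg, n))
  stats::approx(seq_along(seg), seg, n = n)$y
}

#' Shift an envelope later in time by an electromechanical delay
#'
#' Muscle force lags the EMG signal; a 40 ms delay is the conventional
#' correction before comparing EMG with model activations. The leading gap
#' is padded by holding the first value, avoiding a spurious onset
#' transient.
#'
#' @param x Envelope.
#' @param rate Sampling rate in Hz.
#' @param delay Delay in seconds (>= 0), default 0.040.
#' @return Shifted envelope, same length.
#' @export
apply_emg_delay <- function(x, rate, delay = 0.040) {
  if (delay < 0) stop("`delay` must be >= 0")
  k <- round(delay * rate)
  if (k == 0) return(x)
  n <- length(x)
  if (k >= n) return(rep(x[1], n))
  c(rep(x[1], k), x[1:(n - k)])
}
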