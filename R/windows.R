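#' Default muscle grouping
#'
#' Medial and lateral vasti, medial and lateral gastrocnemii, and biceps
#' femoris plus semitendinosus are averaged into their muscle groups;
#' soleus, tibialis anterior and rectus femoris stand alone.
#'
#' @return Named list: group -> member channel names.
#' @export
default_muscle_groups <- function() {
  list(gastrocnemius    = c("gastroc_med", "gastroc_lat"),
       soleus           = "soleus",
       vasti            = c("vastus_med", "vastus_lat"),
       hamstrings       = c("biceps_fem", "semitend"),
       tibialis_anterior = "tib_ant",
       rectus_femoris   = "rectus_fem")
}

#' Average per-muscle stance means into muscle groups
#'
#' @param per_muscle Named numeric vector (one step) or a matrix/data.frame
#'   with one column per muscle (rows = steps).
#' @param groups Named list of member muscles per group; see
#'   [default_muscle_groups()]. Groups with no member present are dropped
#'   unless `strict`.
#' @param strict Error when a requested group has no member channel present.
#' @return Named vector or matrix of per-group unweighted means.
#' @export
group_emg <- function(per_muscle, groups = default_muscle_groups(),
                      strict = TRUE) {
  vecin <- is.null(dim(per_muscle))
  m <- if (vecin) matrix(per_muscle, 1, dimnames = list(NULL, names(per_muscle)))
       else as.matrix(per_muscle)
  out <- matrix(NA_real_, nrow(m), 0)
  for (g in names(groups)) {
    members <- intersect(groups[[g]], colnames(m))
    if (length(members) == 0L) {
      if (strict) stop("no member muscle present for group: ", g)
      next
    }
    out <- cbind(out, rowMeans(m[, members, drop = FALSE]))
    colnames(out)[ncol(out)] <- g
  }
  if (vecin) out[1, ] else out
}

#' Per-step records of group EMG and percent change from baseline
#'
#' @param group_means Matrix (steps x groups) of stance-mean normalized EMG
#'   for the feedback steps.
#' @param baseline_group_means Named vector of baseline-trial group means
#'   (mean over all baseline steps).
#' @param trial Optional per-step trial id (windows never span trials).
#' @return data.frame of class `trial_step_records` with columns
#'   `step_index`, `trial`, `<group>_mean`, `<group>_pct`.
#' @export
step_records <- function(group_means, baseline_group_means, trial = 1L) {
  g <- colnames(group_means)
  stopifnot(!is.null(g), all(g %in% names(baseline_group_means)))
  out <- data.frame(step_index = seq_len(nrow(group_means)) - 1L,
                    trial = rep_len(trial, nrow(group_means)))
  for (nm in g) {
    out[[paste0(nm, "_mean")]] <- group_means[, nm]
    base <- baseline_group_means[[nm]]
    out[[paste0(nm, "_pct")]] <-
      if (is.finite(base) && base > 0) percent_change(group_means[, nm], base)
      else NA_real_
  }
  class(out) <- c("trial_step_records", "data.frame")
  out
}

# Shared scan: minimize the mean of `objective` over all length-w windows
# that stay within one trial; ties broken toward the earliest start.
scan_windows <- function(records, w, objective) {
  n <- nrow(records)
  if (n < w) stop("need at least ", w, " step records, got ", n)
  best <- NULL
  for (tr in unique(records$trial)) {
    idx <- which(records$trial == tr)
    if (length(idx) < w) next
    x <- objective[idx]
    ma <- moving_average(x, w)
    j <- which.min(ma)             # which.min takes the first minimum: earliest
    cand <- list(start = idx[j], end = idx[j] + w - 1L, value = ma[j])
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (is.null(best))
    stop("no trial holds ", w, " consecutive steps")
  best
}

selected_window <- function(records, best, w) {
  rows <- best$start:best$end
  structure(list(start_step = best$start, end_step = best$end,
                 size = w,
                 records = records[rows, , drop = FALSE],
                 mean_gastroc_pct = mean(records$gastrocnemius_pct[rows]),
                 mean_vasti_pct = mean(records$vasti_pct[rows]),
                 objective = best$value),
            class = "selected_window")
}

#' Window with the greatest gastrocnemius reduction
#'
#' Scans all `w`-step windows (within a trial) and returns the one with the
#' most negative mean gastrocnemius percent change.
#'
#' @param records A `trial_step_records` data.frame.
#' @param w Window size in steps (default 50).
#' @return A `selected_window` (start/end row indices into `records`,
#'   per-group window means, objective value).
#' @export
best_gastroc_window <- function(records, w = 50L) {
  best <- scan_windows(records, w, records$gastrocnemius_pct)
  selected_window(records, best, w)
}

#' Window minimizing gastrocnemius plus vasti percent change
#'
#' The analysis window: maximizes gastrocnemius reduction while penalizing
#' vasti compensation by minimizing the sum of the two groups' mean percent
#' changes.
#'
#' @inheritParams best_gastroc_window
#' @return A `selected_window`.
#' @export
gastroc_vasti_window <- function(records, w = 50L) {
  best <- scan_windows(records, w,
                       records$gastrocnemius_pct + records$vasti_pct)
  selected_window(records, best, w)
}

#' Representative steps closest to a target gastrocnemius level
#'
#' Picks the `k` steps whose key value (stance-mean gastrocnemius EMG by
#' default) lies nearest the target -- the mean key over the window for
#' feedback steps, or the baseline-trial mean for baseline steps. Ties go
#' to the lower step index.
#'
#' @param records Step records of the window (or baseline trial).
#' @param k Number of steps (default 5).
#' @param key Column used as the key (default `"gastrocnemius_mean"`).
#' @param target Target value; defaults to the mean key over `records`.
#' @return Integer row indices into `records`, in increasing index order.
#' @export
representative_steps <- function(records, k = 5L, key = "gastrocnemius_mean",
                                 target = NULL) {
  n <- nrow(records)
  if (k > n) stop("k = ", k, " exceeds the ", n, " available steps")
  vals <- records[[key]]
  if (is.null(vals)) stop("key column not found: ", key)
  if (is.null(target)) target <- mean(vals)
  d <- abs(vals - target)
  ord <- order(d, seq_len(n))       # stable: ties -> lower index
  sort(ord[seq_len(k)])
}
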