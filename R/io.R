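#' Read a trial time series from disk
#'
#' Reads either a comma-separated table or a motion/storage (`.sto`/`.mot`)
#' dialect file: an optional key=value header terminated by an `endheader`
#' line, then a tab-delimited table whose first column is time in seconds.
#' Uniform sampling is validated on load.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension), `"sto_mot"` or `"csv"`.
#' @return A [gait_ts()].
#' @export
read_timeseries <- function(path, dialect = c("auto", "sto_mot", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "sto_mot"
  if (dialect == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
  } else {
    lines <- readLines(path)
    hdr_end <- match("endheader", trimws(lines))
    skip <- if (is.na(hdr_end)) 0L else hdr_end
    df <- utils::read.delim(path, skip = skip, check.names = FALSE)
  }
  nm <- names(df)
  if (anyDuplicated(nm))
    stop("duplicate column names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (ncol(df) < 2L) stop("need a time column plus at least one channel")
  gait_ts(time = df[[1L]], channels = as.list(df[-1L]))
}

#' Write a trial time series to disk
#'
#' Inverse of [read_timeseries()]; full double precision is written so that a
#' write/read round trip reproduces every channel to 1e-9 relative.
#'
#' @param ts A [gait_ts()].
#' @param path Output path.
#' @param dialect `"sto_mot"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, dialect = c("sto_mot", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ts, "gait_ts"))
  if (length(ts$channels) == 0L) stop("empty channel map")
  df <- data.frame(time = ts$time, check.names = FALSE)
  for (nm in names(ts$channels)) df[[nm]] <- ts$channels[[nm]]
  ok <- tryCatch({
    if (dialect == "csv") {
      con <- file(path, "w")
      on.exit(close(con), add = TRUE)
      utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                       con, row.names = FALSE, quote = FALSE)
    } else {
      con <- file(path, "w")
      on.exit(close(con), add = TRUE)
      writeLines(c(basename(path),
                   "version=1",
                   sprintf("nRows=%d", nrow(df)),
                   sprintf("nColumns=%d", ncol(df)),
                   "inDegrees=yes",
                   "endheader"), con)
      utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                         con, sep = "\t", row.names = FALSE, quote = FALSE)
    }
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

required_channels <- function(trial_kind, modeling = FALSE) {
  base <- c("vertical_grf")
  if (modeling)
    base <- c(base, "ankle_angle", "knee_angle", "hip_angle",
              "ankle_moment", "knee_moment", "hip_moment", "knee_axial_interseg")
  base
}

#' Load and validate one trial bundle from a configuration entry
#'
#' A configuration entry is a list (typically parsed from JSON) naming the
#' analog file (EMG + vertical GRF on one uniform grid), optionally the
#' mechanics file (angles, moments and intersegmental axial knee force on a
#' second grid), a channel-name map, and the trial metadata including MVC
#' values.
#'
#' @param entry List with elements `analog_file`, optional `mech_file`,
#'   optional `channel_map` (named list, canonical name -> file column),
#'   `meta` (arguments for [trial_meta()]), optional `emg_channels`
#'   (canonical names of EMG channels), optional `dialect`.
#' @param base_dir Directory that relative file paths are resolved against.
#' @return Object of class `gait_trial`: list with `analog`, `mech` (or
#'   `NULL`) and `meta`.
#' @export
load_trial <- function(entry, base_dir = ".") {
  stopifnot(is.list(entry), !is.null(entry$analog_file), !is.null(entry$meta))
  dialect <- entry$dialect %||% "auto"
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  analog <- read_timeseries(resolve(entry$analog_file), dialect)
  if (!is.null(entry$channel_map)) {
    cm <- entry$channel_map
    idx <- match(unlist(cm), names(analog$channels))
    hit <- !is.na(idx)
    names(analog$channels)[idx[hit]] <- names(cm)[hit]
  }
  mech <- NULL
  if (!is.null(entry$mech_file))
    mech <- read_timeseries(resolve(entry$mech_file), dialect)
  meta <- do.call(trial_meta, entry$meta)

  need <- required_channels(meta$trial_kind, modeling = FALSE)
  missing_ch <- setdiff(need, names(analog$channels))
  if (length(missing_ch))
    stop("missing required channel(s): ", paste(missing_ch, collapse = ", "))
  emg_ch <- entry$emg_channels %||%
    setdiff(names(analog$channels), c("vertical_grf"))
  if (length(emg_ch) == 0L) stop("missing required channel(s): EMG")
  if (!is.null(mech)) {
    need_m <- setdiff(required_channels(meta$trial_kind, modeling = TRUE),
                      "vertical_grf")
    missing_m <- setdiff(need_m, names(mech$channels))
    if (length(missing_m))
      stop("missing required channel(s): ", paste(missing_m, collapse = ", "))
    if (is.na(meta$body_mass) || is.na(meta$height))
      stop("body_mass and height are required for modeling trials")
  }
  gait_trial(analog = analog, mech = mech, meta = meta, emg_channels = emg_ch)
}

#' Construct a trial bundle
#'
#' @param analog [gait_ts()] holding raw or enveloped EMG plus `vertical_grf`.
#' @param mech Optional [gait_ts()] with angles, moments and
#'   `knee_axial_interseg`.
#' @param meta A [trial_meta()].
#' @param emg_channels Canonical names of the EMG channels within `analog`.
#' @param emg_is_envelope Logical; `TRUE` when the EMG channels are already
#'   rectified low-pass envelopes (e.g. from the synthetic generator's
#'   envelope mode) and the band-pass/rectify stage should be skipped.
#' @return Object of class `gait_trial`.
#' @export
gait_trial <- function(analog, mech = NULL, meta, emg_channels,
                       emg_is_envelope = FALSE) {
  stopifnot(inherits(analog, "gait_ts"), inherits(meta, "trial_meta"))
  structure(list(analog = analog, mech = mech, meta = meta,
                 emg_channels = emg_channels,
                 emg_is_envelope = isTRUE(emg_is_envelope)),
            class = "gait_trial")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a trial configuration file
#'
#' A JSON file with a `trials` array of [load_trial()] entries (file paths
#' resolved relative to the config file) and an optional `config` object
#' overriding [default_config()] values.
#'
#' @param path Path to the JSON configuration.
#' @return List with `trials` (list of loaded [gait_trial()] bundles) and
#'   `config` (merged configuration list).
#' @export
read_trial_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(spec$trials)) stop("config must contain a `trials` array")
  base_dir <- dirname(normalizePath(path))
  trials <- lapply(spec$trials, function(entry) {
    entry$meta <- lapply(entry$meta, function(v)
      if (is.list(v)) unlist(v) else v)
    load_trial(entry, base_dir)
  })
  config <- utils::modifyList(default_config(),
                              lapply(spec$config %||% list(), unlist))
  list(trials = trials, config = config)
}
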