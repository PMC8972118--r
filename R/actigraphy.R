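#' Euclidean norm minus one (ENMO) in non-overlapping epochs
#'
#' Per sample the vector magnitude of the three axes is computed and 1 g
#' (1000 mg) subtracted; negative values are truncated to zero (the metric's
#' usual convention, configurable via `truncate`), and the per-sample values
#' are averaged within consecutive non-overlapping epochs.
#'
#' @param signal a `raw_accel` (columns `time`, `x_mg`, `y_mg`, `z_mg`).
#' @param epoch_length epoch length in seconds.
#' @param truncate truncate negative per-sample ENMO to 0 before averaging.
#' @return A `data.frame` of class `enmo_series` with columns `epoch_start`
#'   (seconds) and `enmo` (mg); attribute `epoch_length`.
#' @export
compute_enmo <- function(signal, epoch_length = 5, truncate = TRUE) {
  if (!nrow(signal)) stop_("empty accelerometer signal")
  v <- sqrt(signal$x_mg^2 + signal$y_mg^2 + signal$z_mg^2) - 1000
  if (any(!is.finite(v))) stop_("non-finite accelerometer samples")
  if (truncate) v <- pmax(v, 0)
  epoch <- floor((signal$time - signal$time[1]) / epoch_length)
  enmo <- as.vector(rowsum(v, epoch) / tabulate(epoch + 1L))
  structure(data.frame(epoch_start = signal$time[1] +
                         sort(unique(epoch)) * epoch_length,
                       enmo = enmo),
            epoch_length = epoch_length,
            class = c("enmo_series", "data.frame"))
}

#' Score nonwear from per-axis variability in sliding windows
#'
#' For each sliding window an axis is flagged when both its standard
#' deviation and its value range fall below the thresholds; the window's
#' score is the number of flagged axes (0-3). Downstream, windows scoring
#' above the cutoff (default 1, i.e. two or more static axes) are treated as
#' nonwear.
#'
#' @param signal a `raw_accel`.
#' @param window_minutes sliding window length.
#' @param step_minutes step between window starts.
#' @param std_threshold_mg per-axis standard-deviation threshold (mg).
#' @param range_threshold_mg per-axis value-range threshold (mg).
#' @return A `data.frame` of class `nonwear_scores` with columns
#'   `window_start` (seconds) and `score`; attributes `window_minutes`,
#'   `step_minutes`.
#' @export
score_nonwear <- function(signal, window_minutes = 60, step_minutes = 15,
                          std_threshold_mg = 13, range_threshold_mg = 50) {
  fs <- attr(signal, "sampling_rate") %||% (1 / stats::median(diff(signal$time)))
  win_n <- round(window_minutes * 60 * fs)
  step_n <- round(step_minutes * 60 * fs)
  if (win_n < 2) stop_("window contains fewer than 2 samples")
  if (win_n > nrow(signal)) stop_("window longer than the recording")
  starts <- seq(1L, nrow(signal) - win_n + 1L, by = step_n)
  ax <- as.matrix(signal[c("x_mg", "y_mg", "z_mg")])
  score <- vapply(starts, function(i) {
    w <- ax[i:(i + win_n - 1L), , drop = FALSE]
    sds <- apply(w, 2, stats::sd)
    rngs <- apply(w, 2, function(col) diff(range(col)))
    sum(sds < std_threshold_mg & rngs < range_threshold_mg)
  }, integer(1))
  structure(data.frame(window_start = signal$time[starts], score = score),
            window_minutes = window_minutes, step_minutes = step_minutes,
            class = c("nonwear_scores", "data.frame"))
}

#' Average ENMO over the hour before each beep, excluding nonwear
#'
#' Epochs that fall inside any sliding window scoring above `score_cutoff`
#' are treated as nonwear. The activity summary for a beep is the mean ENMO
#' over the wear epochs in the half-open pre-beep window `[t - window, t)`;
#' it is missing when the window has no overlapping data or when wear
#' coverage falls below `min_coverage` of the window (in particular, a fully
#' nonwear window is always missing).
#'
#' @param enmo an `enmo_series` from [compute_enmo()].
#' @param nonwear a `nonwear_scores` from [score_nonwear()]; `NULL` for no
#'   exclusion.
#' @param beeps beep times, seconds on the recording clock (sorted).
#' @param score_cutoff windows scoring strictly above this are nonwear.
#' @param window_seconds length of the pre-beep window.
#' @param min_coverage minimum fraction of the window that must be covered
#'   by wear epochs.
#' @return A `data.frame` of class `beep_activity`: `beep_time`,
#'   `mean_enmo` (mg, `NA` when excluded), `coverage`, `nonwear_excluded`.
#' @export
summarize_prebeep <- function(enmo, nonwear, beeps, score_cutoff = 1,
                              window_seconds = 3600, min_coverage = 0.5) {
  if (is.unsorted(beeps)) stop_("beeps must be sorted")
  ep_len <- attr(enmo, "epoch_length")
  wear <- rep(TRUE, nrow(enmo))
  if (!is.null(nonwear)) {
    win_s <- attr(nonwear, "window_minutes") * 60
    bad <- nonwear$window_start[nonwear$score > score_cutoff]
    for (b in bad)
      wear[enmo$epoch_start >= b & enmo$epoch_start < b + win_s] <- FALSE
  }
  n_expected <- window_seconds / ep_len
  out <- lapply(beeps, function(tb) {
    inwin <- enmo$epoch_start >= tb - window_seconds & enmo$epoch_start < tb
    n_in <- sum(inwin)
    use <- inwin & wear
    coverage <- sum(use) / n_expected
    data.frame(beep_time = tb,
               mean_enmo = if (coverage >= min_coverage) mean(enmo$enmo[use])
                           else NA_real_,
               coverage = coverage,
               nonwear_excluded = n_in > 0 && sum(use) == 0)
  })
  structure(do.call(rbind, out), class = c("beep_activity", "data.frame"))
}

#' Write per-beep activity summaries as CSV
#'
#' The file (`subject_id`, `timestamp`, `mean_enmo`) merges onto the EMA
#' table on `(subject_id, timestamp)`.
#'
#' @param activity a `beep_activity` plus a `subject_id` column, or a list
#'   of them.
#' @param path file path.
#' @export
write_activity_csv <- function(activity, path) {
  if (!is.data.frame(activity)) activity <- do.call(rbind, activity)
  if (inherits(activity$timestamp, "POSIXct"))
    activity$timestamp <- format(activity$timestamp, "%Y-%m-%dT%H:%M:%OS3Z",
                                 tz = "UTC")
  utils::write.csv(activity, path, row.names = FALSE, na = "")
  invisible(path)
}
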