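#' Describe the segment structure of a synthetic accelerometer recording
#'
#' Segments are half-open intervals `[start, end)` in seconds that must be
#' disjoint and cover the full duration. Three segment types are supported:
#' `rest` (device worn, wearer sedentary: gravity orientation plus slow
#' posture drift and sensor noise), `activity` (band-limited movement bursts
#' on top of rest), and `nonwear` (device off wrist: static orientation with
#' only sensor noise, so per-axis standard deviation and range sit below the
#' nonwear thresholds by construction).
#'
#' @param segments data.frame with columns `start`, `end` (seconds) and
#'   `type` in `c("rest", "activity", "nonwear")`.
#' @param sampling_rate Hz; the emulated device supports 10-100 Hz.
#' @param noise_sd sensor noise SD during wear, milligravity.
#' @param nonwear_noise_sd sensor noise SD while off wrist, milligravity.
#' @param drift_amp posture-drift amplitudes per axis (mg) during wear.
#' @return An object of class `accel_profile`.
#' @export
accel_profile <- function(segments, sampling_rate = 10, noise_sd = 5,
                          nonwear_noise_sd = 2, drift_amp = c(40, 40, 20)) {
  if (sampling_rate < 10 || sampling_rate > 100)
    stop_("sampling_rate %g Hz outside device range 10-100 Hz", sampling_rate)
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "type") %in% names(segments)))
  segments <- segments[order(segments$start), , drop = FALSE]
  if (any(segments$end <= segments$start)) stop_("empty or inverted segment")
  if (!all(segments$type %in% c("rest", "activity", "nonwear")))
    stop_("unknown segment type")
  gaps <- segments$start[-1] - segments$end[-nrow(segments)]
  if (nrow(segments) > 1 && any(abs(gaps) > 1e-9))
    stop_("segments must be disjoint and cover the duration without gaps")
  if (abs(segments$start[1]) > 1e-9) stop_("first segment must start at 0")
  structure(list(segments = segments, sampling_rate = sampling_rate,
                 duration = segments$end[nrow(segments)],
                 noise_sd = noise_sd, nonwear_noise_sd = nonwear_noise_sd,
                 drift_amp = drift_amp),
            class = "accel_profile")
}

#' Draw a random wear/activity/nonwear segmentation
#'
#' Convenience generator for recovery experiments: the recording is split
#' into chunks of 20-60 minutes whose types are sampled with the given
#' probabilities (adjacent chunks of equal type are merged).
#'
#' @param duration_hours total recording length.
#' @param type_probs sampling probabilities for rest/activity/nonwear chunks.
#' @param seed integer RNG seed.
#' @inheritParams accel_profile
#' @return An `accel_profile`.
#' @export
random_accel_profile <- function(duration_hours = 6,
                                 type_probs = c(rest = 0.45, activity = 0.3,
                                                nonwear = 0.25),
                                 sampling_rate = 10, seed = 1, ...) {
  with_seed(seed, {
    total <- duration_hours * 3600
    starts <- 0
    repeat {
      nxt <- starts[length(starts)] + stats::runif(1, 20, 60) * 60
      if (nxt >= total - 600) break
      starts <- c(starts, nxt)
    }
    ends <- c(starts[-1], total)
    type <- sample(names(type_probs), length(starts), replace = TRUE,
                   prob = type_probs)
    seg <- data.frame(start = starts, end = ends, type = type)
    keep <- c(TRUE, seg$type[-1] != seg$type[-nrow(seg)])
    merged <- seg[keep, , drop = FALSE]
    merged$end <- c(merged$start[-1], total)
    accel_profile(merged, sampling_rate = sampling_rate, ...)
  })
}

#' Simulate a raw triaxial accelerometer recording
#'
#' Emits `duration * sampling_rate` samples in milligravity. Worn segments
#' carry the gravity vector (0, 0, 1000) mg plus slow sinusoidal posture
#' drift and white sensor noise; activity segments add 1-3.5 Hz movement
#' bursts; nonwear segments are static apart from low-level sensor noise.
#'
#' @param profile an [accel_profile()].
#' @param seed integer RNG seed.
#' @return A `data.frame` of class `raw_accel` with columns `time` (seconds
#'   from recording start), `x_mg`, `y_mg`, `z_mg`; attributes
#'   `sampling_rate` and `profile`.
#' @export
generate_raw_accel <- function(profile, seed = 1) {
  stopifnot(inherits(profile, "accel_profile"))
  fs <- profile$sampling_rate
  n <- round(profile$duration * fs)
  t <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    acc <- matrix(0, n, 3)
    acc[, 3] <- 1000
    for (k in seq_len(nrow(profile$segments))) {
      seg <- profile$segments[k, ]
      idx <- which(t >= seg$start & t < seg$end)
      if (!length(idx)) next
      if (seg$type == "nonwear") {
        acc[idx, ] <- acc[idx, ] +
          matrix(stats::rnorm(3 * length(idx), 0, profile$nonwear_noise_sd),
                 ncol = 3)
      } else {
        for (ax in 1:3) {
          period <- stats::runif(1, 30, 120)
          phase <- stats::runif(1, 0, 2 * pi)
          acc[idx, ax] <- acc[idx, ax] +
            profile$drift_amp[ax] * sin(2 * pi * t[idx] / period + phase) +
            stats::rnorm(length(idx), 0, profile$noise_sd)
        }
        if (seg$type == "activity") {
          for (ax in 1:3) {
            f <- stats::runif(1, 1, 3.5)
            amp <- stats::runif(1, 100, 300)
            acc[idx, ax] <- acc[idx, ax] +
              amp * sin(2 * pi * f * t[idx] + stats::runif(1, 0, 2 * pi)) +
              stats::rnorm(length(idx), 0, 3 * profile$noise_sd)
          }
        }
      }
    }
    structure(data.frame(time = t, x_mg = acc[, 1], y_mg = acc[, 2],
                         z_mg = acc[, 3]),
              sampling_rate = fs, profile = profile,
              class = c("raw_accel", "data.frame"))
  })
}

#' Write / read raw accelerometer CSV with a JSON sidecar
#'
#' The CSV holds `time, x_mg, y_mg, z_mg`; `<path>.json` records the
#' sampling rate so the signal can be reconstructed exactly.
#'
#' @param signal a `raw_accel`.
#' @param path CSV file path.
#' @export
write_accel_csv <- function(signal, path) {
  utils::write.csv(as.data.frame(signal)[c("time", "x_mg", "y_mg", "z_mg")],
                   path, row.names = FALSE)
  jsonlite::write_json(list(sampling_rate = attr(signal, "sampling_rate")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_accel_csv
#' @export
read_accel_csv <- function(path) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  fs <- if (file.exists(side)) jsonlite::read_json(side)$sampling_rate
        else 1 / stats::median(diff(df$time))
  structure(df, sampling_rate = fs, class = c("raw_accel", "data.frame"))
}
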