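#' Configure an EMA sampling design
#'
#' Encodes the sampling scheme of the emulated study: 7 consecutive days with
#' 8 prompts per day, each randomized within a 105-minute block between 08:00
#' and 22:00, and an average prompt missingness of 17.5%.
#'
#' @param n_subjects_per_group subjects simulated per group.
#' @param n_days days of sampling per subject.
#' @param beeps_per_day prompts per day.
#' @param block_minutes length of the randomization block per prompt.
#' @param day_start,day_end clock bounds of the sampling window ("HH:MM").
#' @param missing_rate probability that a prompt is missed (MCAR), in `[0, 0.5]`.
#' @param marginal_maps `"ema"` for the observed-scale maps (logistic to
#'   0-100 for visual-analog items, 7-bin quantile discretization for the
#'   Likert item, exponential for physical activity), `"identity"` to emit
#'   the latent gaussian values directly, or a named list of per-variable
#'   specs `list(type = , ...)`.
#' @param group_labels labels used for the simulated groups.
#' @param start_date calendar date of day 1 (timestamps are informative only).
#' @param seed integer RNG seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects_per_group = 130, n_days = 7,
                              beeps_per_day = 8, block_minutes = 105,
                              day_start = "08:00", day_end = "22:00",
                              missing_rate = 0.175, marginal_maps = "ema",
                              group_labels = NULL,
                              start_date = "2021-01-04", seed = 1) {
  if (missing_rate < 0 || missing_rate > 0.5)
    stop_("missing_rate must lie in [0, 0.5], got %g", missing_rate)
  mins <- function(hm) sum(as.numeric(strsplit(hm, ":")[[1]]) * c(60, 1))
  window <- mins(day_end) - mins(day_start)
  if (beeps_per_day * block_minutes > window)
    stop_("%d beeps x %d-minute blocks do not fit in the %s-%s window",
          beeps_per_day, block_minutes, day_start, day_end)
  structure(list(n_subjects_per_group = n_subjects_per_group, n_days = n_days,
                 beeps_per_day = beeps_per_day, block_minutes = block_minutes,
                 day_start_min = mins(day_start), day_window_min = window,
                 missing_rate = missing_rate, marginal_maps = marginal_maps,
                 group_labels = group_labels, start_date = start_date,
                 seed = seed),
            class = "simulation_config")
}

# Observed-scale marginal maps. Each is strictly monotone in the latent value
# (the Likert map is monotone with ties by construction), so ranks -- and
# hence the nonparanormal recovery of the latent copula -- are preserved.
default_marginal_maps <- function(node_labels) {
  lapply(node_labels, function(v) {
    if (grepl("social", v)) list(type = "likert7", latent_sd = 1.2)
    else if (grepl("physical|activity|enmo", v)) list(type = "lognormal", mu = log(35), sigma = 0.35)
    else list(type = "vas", scale = 1)
  }) |> stats::setNames(node_labels)
}

apply_marginal <- function(x, map) {
  switch(map$type,
         identity  = x,
         vas       = 100 * stats::plogis(x / (map$scale %||% 1)),
         likert7   = {
           u <- stats::pnorm(x, sd = map$latent_sd %||% 1.2)
           as.numeric(cut(u, breaks = seq(0, 1, length.out = 8),
                          labels = FALSE, include.lowest = TRUE))
         },
         lognormal = exp((map$mu %||% log(35)) + (map$sigma %||% 0.35) * x),
         stop_("unknown marginal map type '%s'", map$type))
}

resolve_marginal_maps <- function(config, node_labels) {
  mm <- config$marginal_maps
  if (identical(mm, "ema")) return(default_marginal_maps(node_labels))
  if (identical(mm, "identity"))
    return(stats::setNames(rep(list(list(type = "identity")), length(node_labels)),
                           node_labels))
  if (!is.list(mm) || !all(node_labels %in% names(mm)))
    stop_("marginal_maps must be 'ema', 'identity', or a named list covering all nodes")
  mm[node_labels]
}

# Subject matrix: population matrix plus entry-wise normal random effects,
# redrawn until the subject process is stationary.
draw_subject_matrix <- function(B, re_sd, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    Bi <- B + matrix(stats::rnorm(length(B), 0, re_sd), nrow(B), ncol(B))
    if (spectral_radius(Bi) < 1) return(Bi)
  }
  stop_("no stationary subject matrix found in %d draws", max_tries)
}

#' Simulate a multilevel VAR(1) EMA dataset
#'
#' For every subject a coefficient matrix is drawn around the group matrix
#' (entry-wise independent normal random effects, resampled until the subject
#' process is stationary), a latent gaussian VAR(1) series is simulated over
#' the beep schedule (20 burn-in steps), latent values are pushed through the
#' configured marginal maps onto the observed scales, and prompts are deleted
#' completely at random at the configured rate. Device-measured variables
#' (the `lognormal` physical-activity map) are retained when a prompt is
#' missed; self-report items are blanked. The same seed reproduces the
#' dataset bit for bit.
#'
#' @param spec a [true_network_spec()].
#' @param config a [simulation_config()].
#' @return A `data.frame` of class `ema_dataset` with columns `subject_id`,
#'   `group`, `day`, `beep`, `timestamp` and one column per node; attributes
#'   `node_labels`, `true_spec`, `provenance`.
#' @export
generate_dataset <- function(spec, config) {
  stopifnot(inherits(spec, "true_network_spec"),
            inherits(config, "simulation_config"))
  labels <- spec$node_labels
  p <- length(labels)
  maps <- resolve_marginal_maps(config, labels)
  n_groups <- length(spec$B)
  glab <- config$group_labels %||% paste0("group", seq_len(n_groups))
  if (length(glab) != n_groups) stop_("group_labels must have length %d", n_groups)
  L <- t(chol(spec$innovation_cov))
  nT <- config$n_days * config$beeps_per_day
  burn <- 20L
  day0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  device <- vapply(maps, function(m) m$type == "lognormal", TRUE)

  with_seed(config$seed, {
    rows <- vector("list", n_groups * config$n_subjects_per_group)
    k <- 0L
    for (g in seq_len(n_groups)) {
      for (s in seq_len(config$n_subjects_per_group)) {
        Bi <- draw_subject_matrix(spec$B[[g]], spec$random_effect_sd)
        x <- numeric(p)
        lat <- matrix(NA_real_, nT, p)
        for (t in seq_len(burn + nT)) {
          x <- drop(Bi %*% x) + drop(L %*% stats::rnorm(p))
          if (t > burn) lat[t - burn, ] <- x
        }
        obs <- vapply(seq_len(p), function(j) apply_marginal(lat[, j], maps[[j]]),
                      numeric(nT))
        # beep schedule: uniform within consecutive disjoint blocks
        off <- stats::runif(nT, 0, config$block_minutes * 60)
        day <- rep(seq_len(config$n_days), each = config$beeps_per_day)
        beep <- rep(seq_len(config$beeps_per_day), config$n_days)
        ts <- day0 + (day - 1) * 86400 + config$day_start_min * 60 +
          (beep - 1) * config$block_minutes * 60 + off
        # MCAR missed prompts; per-subject realized rate capped at 0.5
        repeat {
          miss <- stats::runif(nT) < config$missing_rate
          if (mean(miss) <= 0.5) break
        }
        obs[miss, !device] <- NA_real_
        k <- k + 1L
        rows[[k]] <- data.frame(
          subject_id = sprintf("%s_s%03d", glab[g], s), group = glab[g],
          day = day, beep = beep, timestamp = ts, obs)
      }
    }
    out <- do.call(rbind, rows)
    names(out)[6:(5 + p)] <- labels
    rownames(out) <- NULL
    structure(out, node_labels = labels, true_spec = spec,
              provenance = "synthetic", class = c("ema_dataset", "data.frame"))
  })
}

#' Write / read an EMA dataset as long-format CSV
#'
#' Columns: `subject_id, group, day, beep, timestamp` (ISO-8601, UTC) and one
#' column per variable; empty cells encode missing values.
#'
#' @param dataset an `ema_dataset` (or compatible data.frame).
#' @param path file path.
#' @return `read_ema_csv` returns an `ema_dataset` with
#'   `provenance = "file"`.
#' @export
write_ema_csv <- function(dataset, path) {
  out <- as.data.frame(dataset)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ema_csv
#' @export
read_ema_csv <- function(path) {
  if (!file.exists(path)) stop_("EMA CSV not found: %s", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "day", "beep", "timestamp")
  if (!all(need %in% names(out)))
    stop_("EMA CSV %s lacks required columns: %s", path,
          paste(setdiff(need, names(out)), collapse = ", "))
  out$timestamp <- as.POSIXct(out$timestamp, format = "%Y-%m-%dT%H:%M:%OS",
                              tz = "UTC")
  labels <- setdiff(names(out), need)
  key <- paste(out$subject_id, out$day, out$beep)
  if (anyDuplicated(key)) stop_("duplicate (subject, day, beep) keys in %s", path)
  structure(out, node_labels = labels, provenance = "file",
            class = c("ema_dataset", "data.frame"))
}
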