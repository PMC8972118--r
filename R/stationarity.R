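#' KPSS level-stationarity test
#'
#' Tests the null hypothesis that a series is stationary around a constant
#' level. The statistic is the scaled sum of squared partial sums of the
#' demeaned series, with a Bartlett-window long-run variance estimate; the
#' p-value is interpolated from the published critical values (0.347, 0.463,
#' 0.574, 0.739 for 10%, 5%, 2.5%, 1%) and reported as an interval endpoint
#' when the statistic falls outside the table.
#'
#' @param x numeric series (missing values removed).
#' @param lags number of autocovariance lags in the long-run variance;
#'   `"auto"` uses `trunc(4 * (n/100)^0.25)`.
#' @return list with `statistic`, `p_value`, `lags`, `n`.
#' @export
kpss_test <- function(x, lags = "auto") {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 10) stop_("KPSS test needs at least 10 observations, got %d", n)
  if (identical(lags, "auto")) lags <- trunc(4 * (n / 100)^0.25)
  e <- x - mean(x)
  s_cum <- cumsum(e)
  lrv <- sum(e^2) / n
  if (lags > 0) {
    for (l in seq_len(lags)) {
      w <- 1 - l / (lags + 1)
      lrv <- lrv + 2 * w * sum(e[(l + 1):n] * e[1:(n - l)]) / n
    }
  }
  stat <- sum(s_cum^2) / (n^2 * lrv)
  cv <- c(0.347, 0.463, 0.574, 0.739)
  pv <- c(0.10, 0.05, 0.025, 0.01)
  p <- if (stat <= cv[1]) 0.10
       else if (stat >= cv[4]) 0.01
       else stats::approx(cv, pv, xout = stat)$y
  list(statistic = stat, p_value = p, lags = lags, n = n)
}

# Within-subject, within-day lag-1 pairs of a single variable.
lag_pairs_one <- function(tab, v) {
  o <- order(tab$subject_id, tab$day, tab$beep)
  s <- tab$subject_id[o]; d <- tab$day[o]; b <- tab$beep[o]
  y <- tab[[v]][o]
  i <- seq_len(length(y) - 1)
  ok <- s[i] == s[i + 1] & d[i] == d[i + 1] & b[i + 1] - b[i] == 1 &
    !is.na(y[i]) & !is.na(y[i + 1])
  data.frame(subject = s[i][ok], y = y[i + 1][ok], ylag = y[i][ok])
}

#' Moment-to-moment inertia diagnostic
#'
#' Fits, per group and variable, a two-level autoregressive model in which
#' each score is regressed on the immediately preceding score of the same
#' variable (consecutive beeps within a day), with a random intercept per
#' subject. The fixed-effect slope is the moment-to-moment inertia; values
#' of 1 or more indicate a nonstationary process and are flagged.
#'
#' @param table an `analysis_table`.
#' @param warn_band inertia at or above this value is flagged.
#' @return A `data.frame` of class `stationarity_report` with columns
#'   `group`, `variable`, `inertia`, `se`, `n_pairs`, `nonstationary`.
#' @export
inertia_diagnostic <- function(table, warn_band = 1) {
  labels <- attr(table, "node_labels")
  out <- list()
  for (g in unique(table$group)) {
    sub <- table[table$group == g, , drop = FALSE]
    if (length(unique(sub$subject_id)) < 2)
      stop_("inertia diagnostic needs >= 2 subjects in group '%s'", g)
    for (v in labels) {
      d <- lag_pairs_one(sub, v)
      if (nrow(d) < 3) stop_("too few lag-1 pairs for '%s' in group '%s'", v, g)
      fit <- suppressMessages(
        lme4::lmer(y ~ ylag + (1 | subject), data = d, REML = TRUE))
      est <- lme4::fixef(fit)[["ylag"]]
      se <- sqrt(diag(as.matrix(stats::vcov(fit))))[2]
      out[[length(out) + 1]] <- data.frame(
        group = g, variable = v, inertia = est, se = se, n_pairs = nrow(d),
        nonstationary = est >= warn_band)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(res$nonstationary))
    warning(sprintf("inertia >= %g for: %s", warn_band,
                    paste(res$variable[res$nonstationary], collapse = ", ")),
            call. = FALSE)
  structure(res, class = c("stationarity_report", "data.frame"))
}

#' Per-subject, per-variable KPSS battery
#'
#' Runs the KPSS level-stationarity test separately for every subject and
#' variable (observations in time order, missing values dropped) and reports
#' the per-series decision at `alpha` together with the overall proportion
#' of series for which stationarity is not rejected. Series shorter than
#' `min_length` non-missing points or constant are skipped and counted.
#'
#' @param table an `analysis_table`.
#' @param alpha rejection level for the stationarity null.
#' @param min_length minimum non-missing series length.
#' @return list of class `kpss_report`: `series` (data.frame with one row
#'   per tested series), `proportion_stationary`, `n_tested`, `n_skipped`.
#' @export
kpss_stationarity <- function(table, alpha = 0.05, min_length = 10) {
  labels <- attr(table, "node_labels")
  tab <- table[order(table$subject_id, table$day, table$beep), , drop = FALSE]
  rows <- list(); skipped <- 0L
  for (s in unique(tab$subject_id)) {
    sub <- tab[tab$subject_id == s, , drop = FALSE]
    for (v in labels) {
      x <- sub[[v]][!is.na(sub[[v]])]
      if (length(x) < min_length || length(unique(x)) < 2) {
        skipped <- skipped + 1L
        next
      }
      k <- kpss_test(x)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = s, group = sub$group[1], variable = v,
        statistic = k$statistic, p_value = k$p_value, n = k$n,
        stationary = k$p_value > alpha)
    }
  }
  if (!length(rows)) stop_("no testable series (all skipped)")
  series <- do.call(rbind, rows)
  rownames(series) <- NULL
  structure(list(series = series,
                 proportion_stationary = mean(series$stationary),
                 n_tested = nrow(series), n_skipped = skipped, alpha = alpha),
            class = "kpss_report")
}

#' @export
print.kpss_report <- function(x, ...) {
  cat(sprintf("KPSS battery: %d series tested, %d skipped; %.1f%% stationary at alpha = %.2f\n",
              x$n_tested, x$n_skipped, 100 * x$proportion_stationary, x$alpha))
  invisible(x)
}
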