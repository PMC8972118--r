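#' Assemble the per-beep analysis table
#'
#' Joins the EMA items with per-beep actigraphy summaries on
#' `(subject_id, timestamp)`. Rows missing either source are retained with
#' missing values; subjects who missed more than `max_missing` of their
#' prompts (a prompt counts as missed when every self-report item is
#' missing) are excluded, mirroring the recruitment property that no
#' retained participant missed more than 50% of the sent questionnaires.
#'
#' @param ema an `ema_dataset`.
#' @param activity optional data.frame (`subject_id`, `beep_time` or
#'   `timestamp`, `mean_enmo`); when supplied it fills the
#'   `physical_activity` column.
#' @param max_missing exclusion threshold on per-subject prompt missingness.
#' @param activity_var name of the activity column in the output.
#' @return A `data.frame` of class `analysis_table` with attributes
#'   `node_labels`, `groups`, `excluded_subjects`.
#' @export
assemble_analysis_table <- function(ema, activity = NULL, max_missing = 0.5,
                                    activity_var = "physical_activity") {
  tab <- as.data.frame(ema)
  labels <- attr(ema, "node_labels") %||%
    setdiff(names(tab), c("subject_id", "group", "day", "beep", "timestamp"))
  key <- paste(tab$subject_id, tab$day, tab$beep)
  if (anyDuplicated(key)) stop_("duplicate (subject, day, beep) beep keys")
  if (!is.null(activity)) {
    tname <- if ("timestamp" %in% names(activity)) "timestamp" else "beep_time"
    if (is.character(activity[[tname]]))
      activity[[tname]] <- as.POSIXct(activity[[tname]],
                                      format = "%Y-%m-%dT%H:%M:%OS",
                                      tz = "UTC")
    if (!length(intersect(tab$subject_id, activity$subject_id)))
      stop_("EMA and activity tables share no subjects")
    idx <- match(paste(tab$subject_id, as.numeric(tab$timestamp)),
                 paste(activity$subject_id, as.numeric(activity[[tname]])))
    if (activity_var %in% names(tab)) {
      # partial actigraphy coverage: device summaries override the existing
      # column only where a pre-beep window was computed
      sel <- !is.na(idx)
      tab[[activity_var]][sel] <- activity$mean_enmo[idx[sel]]
    } else {
      tab[[activity_var]] <- activity$mean_enmo[idx]
    }
    if (!activity_var %in% labels) labels <- c(labels, activity_var)
  }
  items <- setdiff(labels, activity_var)
  miss_by_subj <- tapply(
    rowSums(!is.na(tab[, items, drop = FALSE])) == 0, tab$subject_id, mean)
  drop <- names(miss_by_subj)[miss_by_subj > max_missing]
  if (length(drop)) {
    message(sprintf("excluding %d subject(s) with > %.0f%% missed prompts: %s",
                    length(drop), 100 * max_missing,
                    paste(drop, collapse = ", ")))
    tab <- tab[!tab$subject_id %in% drop, , drop = FALSE]
  }
  tab <- tab[order(tab$subject_id, tab$day, tab$beep), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, node_labels = labels, groups = unique(tab$group),
            excluded_subjects = drop, transform = NULL,
            class = c("analysis_table", "data.frame"))
}

# Truncated-ECDF gaussianization of one vector (missing values pass through).
# delta = 1 / (4 n^(1/4) sqrt(pi log n)) is the usual truncation level.
npn_column <- function(x) {
  ok <- !is.na(x)
  v <- x[ok]
  n <- length(v)
  if (length(unique(v)) < 2) return(NULL)
  delta <- 1 / (4 * n^(1 / 4) * sqrt(pi * log(n)))
  f <- rank(v, ties.method = "average") / n
  x[ok] <- stats::qnorm(pmin(pmax(f, delta), 1 - delta))
  x
}

#' Nonparanormal (rank-based gaussian) transformation
#'
#' Maps each variable through its truncated empirical CDF to standard-normal
#' quantiles, within the chosen pooling unit (default: all observations of a
#' group). The transform depends on the data only through ranks, so any
#' strictly monotone pre-distortion of a column leaves the output unchanged,
#' and ties map to equal outputs. Missing values pass through untouched.
#'
#' @param table an `analysis_table`.
#' @param pool `"group"` (default), `"all"`, or `"subject"`: the set of
#'   observations over which each variable's empirical CDF is estimated.
#' @return The transformed `analysis_table`; attribute `transform` records
#'   the pooling unit.
#' @export
nonparanormal_transform <- function(table, pool = c("group", "all", "subject")) {
  pool <- match.arg(pool)
  labels <- attr(table, "node_labels")
  unit <- switch(pool, all = rep("all", nrow(table)),
                 group = table$group, subject = table$subject_id)
  for (v in labels) {
    for (u in unique(unit)) {
      sel <- unit == u
      z <- npn_column(table[[v]][sel])
      if (is.null(z))
        stop_("variable '%s' is constant within %s '%s'; cannot gaussianize",
              v, pool, u)
      table[[v]][sel] <- z
    }
  }
  attr(table, "transform") <- list(method = "nonparanormal", pool = pool)
  table
}
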