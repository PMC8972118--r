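#' Per-person means on the raw scales
#'
#' Averages every variable over all of a subject's non-missing beeps, on the
#' untransformed scales. Subjects with no data for a variable get a missing
#' mean (reported via a message).
#'
#' @param table an `analysis_table` (untransformed).
#' @return A `data.frame` of class `person_means`: `subject_id`, `group`,
#'   one column per variable.
#' @export
person_means <- function(table) {
  labels <- attr(table, "node_labels")
  ids <- unique(table$subject_id)
  out <- data.frame(subject_id = ids,
                    group = table$group[match(ids, table$subject_id)])
  for (v in labels)
    out[[v]] <- as.vector(tapply(table[[v]], table$subject_id, mean,
                                 na.rm = TRUE)[ids])
  for (v in labels) out[[v]][is.nan(out[[v]])] <- NA_real_
  n_na <- sum(is.na(out[, labels]))
  if (n_na) message(sprintf("%d all-missing person means set to NA", n_na))
  structure(out, node_labels = labels,
            class = c("person_means", "data.frame"))
}

#' Welch two-sample t-test
#'
#' Unequal variances are assumed and the Welch-Satterthwaite approximation
#' is applied to the degrees of freedom; the p-value is two-sided.
#'
#' @param a,b numeric vectors (at least 2 finite values each; `NA` dropped).
#' @return list: `t`, `df`, `p`, `mean_a`, `mean_b`, `sd_a`, `sd_b`.
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop_("each group needs at least 2 finite values")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b),
       sd_a = stats::sd(a), sd_b = stats::sd(b))
}

#' Group comparison of person means
#'
#' Welch t-test per variable between the two groups of a [person_means()]
#' table, reporting each group's mean and SD of the person means.
#'
#' @param pm a `person_means` with exactly two groups.
#' @return data.frame: `variable`, `mean_1`, `sd_1`, `mean_2`, `sd_2`, `t`,
#'   `df`, `p`.
#' @export
group_comparison_table <- function(pm) {
  groups <- unique(pm$group)
  if (length(groups) != 2) stop_("person_means must contain exactly 2 groups")
  labels <- attr(pm, "node_labels")
  rows <- lapply(labels, function(v) {
    w <- welch_t(pm[[v]][pm$group == groups[1]],
                 pm[[v]][pm$group == groups[2]])
    data.frame(variable = v, mean_1 = w$mean_a, sd_1 = w$sd_a,
               mean_2 = w$mean_b, sd_2 = w$sd_b, t = w$t, df = w$df, p = w$p)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- groups
  out
}
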