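#' Build the lag-1 design for multilevel VAR estimation
#'
#' Pairs each beep with the immediately preceding beep of the same subject
#' and day (no overnight pairs, so the roughly equal spacing of prompts is
#' preserved). Pairs with a missing value in any variable at either endpoint
#' are dropped. Predictors are within-person centered on each subject's own
#' mean (over all of that subject's non-missing observations in the table),
#' so lagged effects reflect within-subject fluctuation.
#'
#' @param table an `analysis_table`.
#' @return An object of class `lagged_design`: outcome matrix `y` (pairs x
#'   nodes), centered predictor matrix `x`, `subject` factor, `node_labels`,
#'   `n_dropped`.
#' @export
build_lagged_design <- function(table) {
  labels <- attr(table, "node_labels")
  tab <- table[order(table$subject_id, table$day, table$beep), , drop = FALSE]
  m <- as.matrix(tab[, labels, drop = FALSE])
  i <- seq_len(nrow(tab) - 1)
  consec <- tab$subject_id[i] == tab$subject_id[i + 1] &
    tab$day[i] == tab$day[i + 1] & tab$beep[i + 1] - tab$beep[i] == 1
  complete <- stats::complete.cases(m[i, , drop = FALSE]) &
    stats::complete.cases(m[i + 1, , drop = FALSE])
  keep <- which(consec & complete)
  if (!length(keep)) stop_("no valid lag-1 pairs")
  y <- m[keep + 1, , drop = FALSE]
  x <- m[keep, , drop = FALSE]
  subject <- tab$subject_id[keep]
  # within-person centering on the subject's full observed mean
  for (j in seq_along(labels)) {
    mu <- tapply(m[, j], tab$subject_id, mean, na.rm = TRUE)
    x[, j] <- x[, j] - mu[subject]
  }
  structure(list(y = y, x = x, subject = factor(subject),
                 node_labels = labels,
                 n_dropped = sum(consec) - length(keep)),
            class = "lagged_design")
}

# Fast fixed-effect estimator: within-subject demeaning of outcome and
# predictors absorbs subject intercepts; pooled least squares then yields
# the slopes. Returns coefficients only (se = NULL) when se = FALSE.
fit_ols_engine <- function(y, x, subject, se = TRUE) {
  gm_y <- rowsum(y, subject) / as.vector(table(subject)[levels(subject)])
  gm_x <- rowsum(x, subject) / as.vector(table(subject)[levels(subject)])
  idx <- as.integer(subject)
  yd <- y - gm_y[idx, , drop = FALSE]
  xd <- x - gm_x[idx, , drop = FALSE]
  xtx <- crossprod(xd)
  bt <- solve(xtx, crossprod(xd, yd))   # p x p, column j = slopes for outcome j
  B <- t(bt)
  if (!se) return(list(B = B))
  n <- nrow(y); p <- ncol(x)
  dfree <- n - p - nlevels(subject)
  resid <- yd - xd %*% bt
  sig2 <- colSums(resid^2) / max(dfree, 1)
  xtx_inv <- solve(xtx)
  SE <- t(sqrt(outer(diag(xtx_inv), sig2)))
  P <- 2 * stats::pt(-abs(B / SE), df = max(dfree, 1))
  list(B = B, SE = SE, p = P)
}

fit_lmm_engine <- function(y, x, subject, labels, random_slopes = FALSE) {
  p <- length(labels)
  d <- data.frame(x, subject = subject)
  names(d)[1:p] <- paste0("L_", seq_len(p))
  preds <- paste(names(d)[1:p], collapse = " + ")
  B <- SE <- P <- matrix(NA_real_, p, p)
  for (j in seq_len(p)) {
    d$.y <- y[, j]
    form <- if (random_slopes)
      stats::as.formula(paste0(".y ~ ", preds, " + (1 + ", preds, " || subject)"))
    else stats::as.formula(paste0(".y ~ ", preds, " + (1 | subject)"))
    fit <- tryCatch(
      suppressMessages(lme4::lmer(form, data = d, REML = TRUE)),
      error = function(e) NULL)
    if (random_slopes && (is.null(fit) || lme4::isSingular(fit))) {
      warning(sprintf("singular random-slope fit for '%s'; refitting with random intercept only",
                      labels[j]), call. = FALSE)
      form <- stats::as.formula(paste0(".y ~ ", preds, " + (1 | subject)"))
      fit <- suppressMessages(lme4::lmer(form, data = d, REML = TRUE))
    }
    if (is.null(fit)) stop_("mixed-model fit failed for outcome '%s'", labels[j])
    fe <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    B[j, ] <- fe[-1]
    SE[j, ] <- se[-1]
  }
  P <- 2 * stats::pnorm(-abs(B / SE))
  list(B = B, SE = SE, p = P)
}

#' Fit the group-level lag-1 temporal network
#'
#' Estimates the directed lag-1 network nodewise: each variable at beep t is
#' regressed on all within-person-centered variables (including itself) at
#' beep t-1. The default engine is a mixed-effects regression with a random
#' intercept per subject (optionally uncorrelated random slopes); the
#' `"ols"` engine absorbs subject intercepts by within-subject demeaning and
#' fits pooled least squares, which agrees with the mixed model when
#' between-subject heterogeneity is small and is fast enough for permutation
#' refits. Variables are z-scaled over the design (per group) by default so
#' edge weights are comparable across the network; p-values are two-sided
#' Wald tests.
#'
#' @param design a `lagged_design` from [build_lagged_design()].
#' @param engine `"lmm"` (mixed model, default) or `"ols"`.
#' @param random_slopes add uncorrelated per-subject random slopes
#'   (`"lmm"` engine only); singular fits fall back to intercept-only with a
#'   warning.
#' @param standardize z-scale each variable over the design rows before
#'   fitting.
#' @return An object of class `temporal_network`: `node_labels`, matrices
#'   `B` (rows = outcome, columns = predictor), `SE`, `p`, plus
#'   `n_subjects`, `n_pairs`, `engine`.
#' @export
fit_temporal_network <- function(design, engine = c("lmm", "ols"),
                                 random_slopes = FALSE, standardize = TRUE) {
  engine <- match.arg(engine)
  if (nlevels(design$subject) < 2)
    stop_("multilevel estimation requires at least 2 subjects")
  y <- design$y; x <- design$x
  labels <- design$node_labels
  if (standardize) {
    s <- apply(y, 2, stats::sd)
    if (any(s == 0)) stop_("constant variable(s): %s",
                           paste(labels[s == 0], collapse = ", "))
    y <- sweep(y, 2, s, "/")
    x <- sweep(x, 2, s, "/")
  }
  fit <- if (engine == "ols") fit_ols_engine(y, x, design$subject)
         else fit_lmm_engine(y, x, design$subject, labels, random_slopes)
  dimnames(fit$B) <- dimnames(fit$SE) <- dimnames(fit$p) <-
    list(labels, labels)
  structure(list(node_labels = labels, B = fit$B, SE = fit$SE, p = fit$p,
                 n_subjects = nlevels(design$subject), n_pairs = nrow(y),
                 engine = engine, standardized = standardize),
            class = "temporal_network")
}

#' Extract significant directed edges
#'
#' @param network a `temporal_network`.
#' @param alpha significance level in `(0, 1]`; edges with `p < alpha` are
#'   kept (self-loops included).
#' @return data.frame `predictor, outcome, weight, se, p`, ordered by
#'   decreasing `|weight|` with ties broken by predictor then outcome label.
#' @export
significant_edges <- function(network, alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 1)
  edges <- edge_list(network)
  edges <- edges[edges$p < alpha, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

# All p^2 directed edges (B is outcome x predictor, so column-major
# enumeration walks predictors in the outer loop), ordered by |weight|.
edge_list <- function(network) {
  edges <- expand.grid(outcome = network$node_labels,
                       predictor = network$node_labels,
                       stringsAsFactors = FALSE)[, c("predictor", "outcome")]
  edges$weight <- as.vector(network$B)
  edges$se <- as.vector(network$SE)
  edges$p <- as.vector(network$p)
  edges[order(-abs(edges$weight), edges$predictor, edges$outcome), ]
}

#' @export
print.temporal_network <- function(x, ...) {
  cat(sprintf("Lag-1 temporal network (%s engine): %d nodes, %d subjects, %d pairs\n",
              x$engine, length(x$node_labels), x$n_subjects, x$n_pairs))
  sig <- significant_edges(x, 0.05)
  cat(sprintf("  %d edges with p < .05 (of %d)\n", nrow(sig),
              length(x$node_labels)^2))
  invisible(x)
}

#' Serialize / restore a temporal network as JSON
#'
#' @param network a `temporal_network`.
#' @param path file path.
#' @export
network_to_json <- function(network, path) {
  jsonlite::write_json(
    list(node_labels = network$node_labels, B = network$B, SE = network$SE,
         p = network$p, n_subjects = network$n_subjects,
         n_pairs = network$n_pairs, engine = network$engine),
    path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname network_to_json
#' @export
network_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("B", "SE", "p"))
    dimnames(obj[[f]]) <- list(obj$node_labels, obj$node_labels)
  structure(obj, class = "temporal_network")
}

#' Write the full edge list as CSV
#'
#' @param network a `temporal_network`.
#' @param path file path.
#' @export
write_edges_csv <- function(network, path) {
  e <- edge_list(network)
  utils::write.csv(e, path, row.names = FALSE)
  invisible(path)
}
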