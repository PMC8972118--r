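#' Two-sided permutation p-value with add-one correction
#'
#' `p = (1 + #\{|permuted| >= |observed|\}) / (1 + n)`. The add-one rule
#' counts the observed assignment among the permutations, guaranteeing
#' `p > 0` and validity at finite replication counts.
#'
#' @param observed observed statistic.
#' @param permuted vector of permutation statistics.
#' @return p-value in `(0, 1]`.
#' @export
pvalue_two_sided <- function(observed, permuted) {
  if (!length(permuted)) stop_("empty permutation distribution")
  if (!is.finite(observed) || any(!is.finite(permuted)))
    stop_("non-finite inputs to pvalue_two_sided")
  (1 + sum(abs(permuted) >= abs(observed))) / (1 + length(permuted))
}

# Named vector of group-difference statistics (group1 - group2).
diff_stats <- function(B1, B2, labels, statistics, signed_strength,
                       self_strength, self_connectivity) {
  out <- numeric(0)
  if ("edges" %in% statistics) {
    D <- B1 - B2
    nm <- as.vector(outer(labels, labels,
                          function(o, p) paste0("edge:", p, "->", o)))
    out <- c(out, stats::setNames(as.vector(D), nm))
  }
  if ("strength" %in% statistics) {
    c1 <- strength_centrality(B1, signed = signed_strength,
                              include_self = self_strength)
    c2 <- strength_centrality(B2, signed = signed_strength,
                              include_self = self_strength)
    out <- c(out,
             stats::setNames(c1$in_strength - c2$in_strength,
                             paste0("in_strength:", labels)),
             stats::setNames(c1$out_strength - c2$out_strength,
                             paste0("out_strength:", labels)))
  }
  if ("connectivity" %in% statistics) {
    out <- c(out, connectivity =
               global_connectivity(B1, include_self = self_connectivity) -
               global_connectivity(B2, include_self = self_connectivity))
  }
  out
}

#' Permutation comparison of two groups' temporal networks
#'
#' Fits the lag-1 temporal network of each observed group, then repeatedly
#' reassigns whole subjects to groups (preserving group sizes), refits both
#' networks with the same estimator options, and compares each selected
#' statistic's observed group difference (group 1 minus group 2) with its
#' permutation distribution. The subject is the exchangeable unit: a
#' subject's time series is never split across groups, which preserves
#' within-person dependence under the null. With `exhaustive = TRUE` all
#' distinct subject splits are enumerated and the p-value is the exact
#' proportion of splits (including the observed one) whose absolute
#' statistic reaches the observed value.
#'
#' @param tableA,tableB `analysis_table`s for the two groups (same node set).
#' @param n_permutations Monte-Carlo permutations (ignored when exhaustive).
#' @param seed integer RNG seed.
#' @param statistics any of `"edges"` (all directed-edge differences),
#'   `"strength"` (in-/out-strength per node), `"connectivity"`.
#' @param engine,random_slopes,standardize estimator options, applied
#'   identically to the observed and every permuted fit (see
#'   [fit_temporal_network()]); `"ols"` is recommended for large
#'   permutation counts.
#' @param exhaustive enumerate all subject splits instead of sampling.
#' @param signed_strength,self_strength,self_connectivity flags passed to
#'   the centrality/connectivity statistics.
#' @param max_fail_rate abort if more than this fraction of permutation
#'   refits fail (failed permutations are redrawn and counted).
#' @param keep_splits retain the permutation assignment matrix (testing).
#' @return An object of class `permutation_result`: `table` (one row per
#'   statistic: `statistic`, `type`, `observed`, `p`, permutation summary),
#'   observed `networks`, `n_permutations`, `seed`, `n_redrawn`,
#'   `exhaustive`.
#' @export
permutation_compare <- function(tableA, tableB, n_permutations = 2000,
                                seed = 1,
                                statistics = c("edges", "strength",
                                               "connectivity"),
                                engine = c("lmm", "ols"),
                                random_slopes = FALSE, standardize = TRUE,
                                exhaustive = FALSE, signed_strength = FALSE,
                                self_strength = FALSE,
                                self_connectivity = TRUE,
                                max_fail_rate = 0.05, keep_splits = FALSE) {
  engine <- match.arg(engine)
  statistics <- match.arg(statistics, several.ok = TRUE)
  labels <- attr(tableA, "node_labels")
  if (!identical(sort(labels), sort(attr(tableB, "node_labels"))))
    stop_("the two tables do not share a node set")
  dA <- build_lagged_design(tableA)
  dB <- build_lagged_design(tableB)
  nA <- nlevels(dA$subject); nB <- nlevels(dB$subject)
  if (nA < 2 || nB < 2) stop_("need at least 2 subjects per group")

  Y <- rbind(dA$y, dB$y)
  X <- rbind(dA$x, dB$x)
  subject <- factor(c(paste0("A:", as.character(dA$subject)),
                      paste0("B:", as.character(dB$subject))))
  subj_levels <- levels(subject)
  subj_idx <- as.integer(subject)
  obs_group1 <- paste0("A:", levels(dA$subject))

  if (engine == "ols") {
    # per-subject demeaning is group-independent: precompute once
    cnt <- as.vector(table(subject))
    Yd <- Y - (rowsum(Y, subject) / cnt)[subj_idx, , drop = FALSE]
    Xd <- X - (rowsum(X, subject) / cnt)[subj_idx, , drop = FALSE]
    group_B <- function(g1_levels) {
      rows <- subj_idx %in% match(g1_levels, subj_levels)
      yr <- Yd[rows, , drop = FALSE]; xr <- Xd[rows, , drop = FALSE]
      B <- t(solve(crossprod(xr), crossprod(xr, yr)))
      if (standardize) {
        s <- apply(Y[rows, , drop = FALSE], 2, stats::sd)
        if (any(s == 0)) stop_("constant variable in permuted group")
        B <- B * outer(1 / s, s)
      }
      dimnames(B) <- list(labels, labels)
      B
    }
  } else {
    group_B <- function(g1_levels) {
      rows <- subj_idx %in% match(g1_levels, subj_levels)
      d <- structure(list(y = Y[rows, , drop = FALSE],
                          x = X[rows, , drop = FALSE],
                          subject = droplevels(subject[rows]),
                          node_labels = labels, n_dropped = 0L),
                     class = "lagged_design")
      fit_temporal_network(d, engine = "lmm", random_slopes = random_slopes,
                           standardize = standardize)$B
    }
  }

  both_B <- function(g1_levels) {
    g2 <- setdiff(subj_levels, g1_levels)
    list(B1 = group_B(g1_levels), B2 = group_B(g2))
  }
  obs <- both_B(obs_group1)
  observed <- diff_stats(obs$B1, obs$B2, labels, statistics, signed_strength,
                         self_strength, self_connectivity)

  # observed networks with full inference, for reporting
  netA <- fit_temporal_network(dA, engine = engine,
                               random_slopes = random_slopes,
                               standardize = standardize)
  netB <- fit_temporal_network(dB, engine = engine,
                               random_slopes = random_slopes,
                               standardize = standardize)

  n_redrawn <- 0L
  if (exhaustive) {
    n_splits <- choose(nA + nB, nA)
    if (n_splits > 20000)
      stop_("%d exhaustive splits is too many; use Monte-Carlo sampling",
            n_splits)
    splits <- utils::combn(subj_levels, nA)
    perm <- apply(splits, 2, function(g1) {
      b <- both_B(g1)
      diff_stats(b$B1, b$B2, labels, statistics, signed_strength,
                 self_strength, self_connectivity)
    })
    perm <- matrix(perm, nrow = length(observed),
                   dimnames = list(names(observed), NULL))
    pvals <- vapply(seq_along(observed), function(k)
      mean(abs(perm[k, ]) >= abs(observed[k]) - 1e-12), 0)
    n_eff <- ncol(perm)
    kept_splits <- if (keep_splits) splits else NULL
  } else {
    perm <- matrix(NA_real_, length(observed), n_permutations,
                   dimnames = list(names(observed), NULL))
    kept_splits <- if (keep_splits)
      matrix(NA_character_, nA, n_permutations) else NULL
    with_seed(seed, {
      i <- 1L
      while (i <= n_permutations) {
        g1 <- sample(subj_levels, nA)
        res <- tryCatch({
          b <- both_B(g1)
          diff_stats(b$B1, b$B2, labels, statistics, signed_strength,
                     self_strength, self_connectivity)
        }, error = function(e) NULL)
        if (is.null(res)) {
          n_redrawn <- n_redrawn + 1L
          if (n_redrawn > max_fail_rate * n_permutations)
            stop_("permutation refit failure rate exceeded %.0f%%",
                  100 * max_fail_rate)
          next
        }
        perm[, i] <- res
        if (keep_splits) kept_splits[, i] <- g1
        i <- i + 1L
      }
    })
    pvals <- vapply(seq_along(observed), function(k)
      pvalue_two_sided(observed[k], perm[k, ]), 0)
    n_eff <- n_permutations
  }

  type <- sub(":.*$", "", names(observed))
  tab <- data.frame(statistic = names(observed), type = type,
                    observed = unname(observed), p = pvals,
                    perm_mean = rowMeans(perm),
                    perm_sd = apply(perm, 1, stats::sd),
                    perm_q025 = apply(perm, 1, stats::quantile, 0.025),
                    perm_q975 = apply(perm, 1, stats::quantile, 0.975))
  rownames(tab) <- NULL
  structure(list(table = tab, networks = list(group1 = netA, group2 = netB),
                 n_permutations = n_eff, seed = seed, n_redrawn = n_redrawn,
                 exhaustive = exhaustive, statistics = statistics,
                 splits = kept_splits, node_labels = labels),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation comparison: %s%d permutations, seed %d, %d redrawn\n",
              if (x$exhaustive) "exhaustive, " else "", x$n_permutations,
              x$seed, x$n_redrawn))
  sig <- x$table[x$table$p < 0.05, , drop = FALSE]
  cat(sprintf("  %d of %d statistics with p < .05\n", nrow(sig), nrow(x$table)))
  if (nrow(sig)) print(sig[, c("statistic", "observed", "p")], row.names = FALSE)
  invisible(x)
}

#' Write a permutation result as CSV / JSON
#'
#' @param result a `permutation_result`.
#' @param path file path (`.csv` flat table or `.json` full object).
#' @export
write_permutation_csv <- function(result, path) {
  utils::write.csv(result$table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_permutation_csv
#' @export
write_permutation_json <- function(result, path) {
  jsonlite::write_json(
    list(table = result$table, n_permutations = result$n_permutations,
         seed = result$seed, n_redrawn = result$n_redrawn,
         exhaustive = result$exhaustive, statistics = result$statistics),
    path, digits = NA, dataframe = "columns")
  invisible(path)
}
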