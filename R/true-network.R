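#' Construct a generating lag-1 network specification
#'
#' Defines the population from which multilevel VAR(1) datasets are drawn:
#' one lag-1 coefficient matrix per group (rows index the outcome at time t,
#' columns the predictor at t-1), the between-subject SD of each coefficient,
#' and the innovation covariance of the latent process.
#'
#' @param node_labels character vector of variable names (no duplicates).
#' @param B a coefficient matrix, or a list of one matrix per group.
#' @param random_effect_sd scalar or matrix of between-subject coefficient SDs.
#' @param innovation_cov positive-definite innovation covariance matrix;
#'   defaults to unit variances with correlation `innovation_cor`.
#' @param innovation_cor off-diagonal innovation correlation used when
#'   `innovation_cov` is not supplied.
#' @param spectral_cap upper bound (exclusive of 1) imposed on the spectral
#'   radius of every group matrix.
#' @return An object of class `true_network_spec`.
#' @export
true_network_spec <- function(node_labels, B, random_effect_sd = 0.05,
                              innovation_cov = NULL, innovation_cor = 0.2,
                              spectral_cap = 0.9) {
  if (anyDuplicated(node_labels)) stop_("node_labels contains duplicates")
  p <- length(node_labels)
  if (is.matrix(B)) B <- list(B)
  for (g in seq_along(B)) {
    if (!all(dim(B[[g]]) == c(p, p)))
      stop_("B for group %d does not conform to %d node labels", g, p)
    dimnames(B[[g]]) <- list(node_labels, node_labels)
    sr <- spectral_radius(B[[g]])
    if (sr > spectral_cap)
      stop_("spectral radius %.3f of group %d exceeds cap %.3f", sr, g, spectral_cap)
  }
  if (length(random_effect_sd) == 1L)
    random_effect_sd <- matrix(random_effect_sd, p, p)
  if (!all(dim(random_effect_sd) == c(p, p)) || any(random_effect_sd < 0))
    stop_("random_effect_sd must be a nonnegative %dx%d matrix", p, p)
  if (is.null(innovation_cov)) {
    innovation_cov <- matrix(innovation_cor, p, p)
    diag(innovation_cov) <- 1
  }
  if (!isSymmetric(unname(innovation_cov)) ||
      min(eigen(innovation_cov, only.values = TRUE)$values) <= 0)
    stop_("innovation_cov must be symmetric positive definite")
  structure(list(node_labels = node_labels, B = B,
                 random_effect_sd = random_effect_sd,
                 innovation_cov = innovation_cov,
                 spectral_cap = spectral_cap),
            class = "true_network_spec")
}

#' Draw a random generating network for one or two groups
#'
#' Off-diagonal lag-1 coefficients are nonzero with probability `sparsity`
#' and drawn uniformly in `edge_range` with a random sign; diagonal
#' (autoregressive) coefficients are drawn from `diag_range`, matching the
#' moment-to-moment inertia magnitudes typical of EMA items. If the spectral
#' radius exceeds `spectral_cap` the matrix is rescaled below the cap. With
#' two groups the matrices are identical except for an optional single-edge
#' difference `group_delta`, so that group comparisons have a known truth.
#'
#' @param n_groups 1 or 2.
#' @param sparsity probability in `[0, 1]` that an off-diagonal entry is nonzero.
#' @param group_delta optional `list(from = , to = , delta = )`: group 2's
#'   coefficient for predictor `from` on outcome `to` differs from group 1's
#'   by exactly `delta`; all other entries are equal.
#' @param seed integer RNG seed.
#' @param node_labels variable names; default [ema_nodes()].
#' @param diag_range,edge_range uniform ranges for diagonal / off-diagonal magnitudes.
#' @param neg_prob probability that a nonzero off-diagonal edge is negative.
#' @param max_tries draws attempted before giving up on the spectral cap.
#' @inheritParams true_network_spec
#' @return A `true_network_spec` with `n_groups` coefficient matrices.
#' @export
generate_true_network <- function(n_groups = 2, sparsity = 0.3,
                                  group_delta = NULL, seed = 1,
                                  node_labels = ema_nodes(),
                                  diag_range = c(0.1, 0.35),
                                  edge_range = c(0.05, 0.15),
                                  neg_prob = 0.3,
                                  random_effect_sd = 0.05,
                                  innovation_cor = 0.2,
                                  innovation_cov = NULL,
                                  spectral_cap = 0.9,
                                  max_tries = 100L) {
  stopifnot(n_groups %in% c(1L, 2L), sparsity >= 0, sparsity <= 1)
  p <- length(node_labels)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      B <- matrix(0, p, p)
      off <- which(row(B) != col(B))
      nz <- off[stats::runif(length(off)) < sparsity]
      B[nz] <- stats::runif(length(nz), edge_range[1], edge_range[2]) *
        ifelse(stats::runif(length(nz)) < neg_prob, -1, 1)
      diag(B) <- stats::runif(p, diag_range[1], diag_range[2])
      sr <- spectral_radius(B)
      if (sr > spectral_cap) B <- B * (0.999 * spectral_cap / sr)
      Bs <- rep(list(B), n_groups)
      if (!is.null(group_delta)) {
        if (n_groups != 2L) stop_("group_delta requires n_groups = 2")
        i <- match(group_delta$to, node_labels)
        j <- match(group_delta$from, node_labels)
        if (is.na(i) || is.na(j)) stop_("group_delta names unknown nodes")
        Bs[[2]][i, j] <- Bs[[2]][i, j] + group_delta$delta
      }
      if (all(vapply(Bs, spectral_radius, 0) <= spectral_cap)) {
        return(true_network_spec(node_labels, Bs,
                                 random_effect_sd = random_effect_sd,
                                 innovation_cov = innovation_cov,
                                 innovation_cor = innovation_cor,
                                 spectral_cap = spectral_cap))
      }
    }
    stop_("could not satisfy spectral cap %.2f in %d draws", spectral_cap, max_tries)
  })
}

#' @export
print.true_network_spec <- function(x, ...) {
  cat(sprintf("Generating lag-1 network: %d nodes, %d group(s)\n",
              length(x$node_labels), length(x$B)))
  cat("  nodes:", paste(x$node_labels, collapse = ", "), "\n")
  for (g in seq_along(x$B))
    cat(sprintf("  group %d: spectral radius %.3f, %d nonzero off-diagonal edges\n",
                g, spectral_radius(x$B[[g]]),
                sum(x$B[[g]][row(x$B[[g]]) != col(x$B[[g]])] != 0)))
  invisible(x)
}
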