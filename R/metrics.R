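#' In-strength and out-strength centrality
#'
#' Out-strength of a node is the sum of the weights of its outgoing edges
#' (its column of the outcome-by-predictor coefficient matrix); in-strength
#' sums the ingoing edges (its row). All edges enter regardless of
#' significance. By default absolute weights are summed — the networks
#' contain negative edges and a signed sum would let them cancel — and
#' autoregressive self-loops are excluded, the usual convention for strength
#' as influence on *other* nodes; both choices are flags. Standardized
#' columns are z-scores across nodes.
#'
#' @param network a `temporal_network`, or a bare coefficient matrix
#'   (rows = outcome, columns = predictor).
#' @param signed sum raw (signed) weights instead of absolute values.
#' @param include_self include the diagonal in the sums.
#' @return A `data.frame` of class `centrality_table`: `node`,
#'   `in_strength`, `out_strength`, `in_strength_z`, `out_strength_z`.
#' @export
strength_centrality <- function(network, signed = FALSE, include_self = FALSE) {
  B <- if (is.matrix(network)) network else network$B
  W <- if (signed) B else abs(B)
  if (!include_self) diag(W) <- 0
  zscore <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  out <- data.frame(node = colnames(B) %||% paste0("V", seq_len(ncol(B))),
                    in_strength = rowSums(W), out_strength = colSums(W))
  out$in_strength_z <- zscore(out$in_strength)
  out$out_strength_z <- zscore(out$out_strength)
  rownames(out) <- NULL
  structure(out, class = c("centrality_table", "data.frame"))
}

#' Overall network connectivity
#'
#' Sum of absolute edge weights over the whole coefficient matrix;
#' autoregressive self-loops are included by default.
#'
#' @inheritParams strength_centrality
#' @return scalar.
#' @export
global_connectivity <- function(network, include_self = TRUE) {
  B <- if (is.matrix(network)) network else network$B
  W <- abs(B)
  if (!include_self) diag(W) <- 0
  sum(W)
}
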