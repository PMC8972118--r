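#' Minimal drawing of a temporal network
#'
#' Nodes on a circle; significant directed edges drawn as arrows with width
#' proportional to |weight|, positive edges in blue and negative edges in
#' red; self-loops are omitted from the drawing (they remain in the edge
#' list).
#'
#' @param x a `temporal_network`.
#' @param alpha significance level for displayed edges.
#' @param main plot title.
#' @param ... ignored.
#' @export
plot.temporal_network <- function(x, alpha = 0.05, main = NULL, ...) {
  p <- length(x$node_labels)
  ang <- pi / 2 - 2 * pi * (seq_len(p) - 1) / p
  xs <- cos(ang); ys <- sin(ang)
  graphics::plot(xs, ys, xlim = c(-1.45, 1.45), ylim = c(-1.45, 1.45),
                 axes = FALSE, xlab = "", ylab = "", pch = 21, cex = 4,
                 bg = "grey90", main = main %||% "temporal network")
  e <- significant_edges(x, alpha)
  e <- e[e$predictor != e$outcome, , drop = FALSE]
  for (k in seq_len(nrow(e))) {
    i <- match(e$predictor[k], x$node_labels)
    j <- match(e$outcome[k], x$node_labels)
    shrink <- 0.12
    dx <- xs[j] - xs[i]; dy <- ys[j] - ys[i]
    len <- sqrt(dx^2 + dy^2)
    graphics::arrows(xs[i] + shrink * dx / len, ys[i] + shrink * dy / len,
                     xs[j] - shrink * dx / len, ys[j] - shrink * dy / len,
                     length = 0.08,
                     lwd = 0.5 + 8 * abs(e$weight[k]),
                     col = if (e$weight[k] >= 0) "#2B6CB0" else "#C53030")
  }
  graphics::text(1.22 * xs, 1.22 * ys, x$node_labels, cex = 0.8)
  invisible(x)
}

#' Dot plot of standardized strength centrality for one or two networks
#'
#' @param cent a `centrality_table`, or named list of two of them.
#' @param main plot title.
#' @export
plot_centrality <- function(cent, main = "standardized strength centrality") {
  if (inherits(cent, "centrality_table")) cent <- list(network = cent)
  nodes <- cent[[1]]$node
  n <- length(nodes)
  graphics::plot(NULL, xlim = c(-2.6, 2.6), ylim = c(0.5, n + 0.5),
                 yaxt = "n", xlab = "z-score", ylab = "", main = main)
  graphics::axis(2, at = seq_len(n), labels = nodes, las = 1, cex.axis = 0.8)
  graphics::abline(v = 0, col = "grey80")
  cols <- c("#2B6CB0", "#C53030")
  for (g in seq_along(cent)) {
    graphics::points(cent[[g]]$out_strength_z, seq_len(n), pch = 19,
                     col = cols[g])
    graphics::points(cent[[g]]$in_strength_z, seq_len(n), pch = 1,
                     col = cols[g])
  }
  graphics::legend("topright", bty = "n", cex = 0.7,
                   legend = c(paste(names(cent), "out-strength"),
                              paste(names(cent), "in-strength")),
                   pch = rep(c(19, 1), each = length(cent)),
                   col = rep(cols[seq_along(cent)], 2))
  invisible(cent)
}
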