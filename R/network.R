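#' Summarise a kinetic model as a state network
#'
#' Emits the conformational Markov network: one node per state with its
#' stationary population (in percent) and one directed edge per nonzero
#' rate with its standard error and a weight proportional to the rate
#' magnitude (used as arrow thickness when plotted).
#'
#' @param fit A `dtc` fit, or a rate matrix `K` (then `p0`/`se` may be
#'   given explicitly).
#' @param p0 Stationary populations (computed from `K` when missing).
#' @param se Optional matrix of rate standard errors.
#' @return A list of class `"kinetic_network"`: `nodes` (data frame
#'   `state`, `population_pct`) and `edges` (data frame `from`, `to`,
#'   `rate`, `se`, `weight`).
#' @export
kinetic_network_report <- function(fit, p0 = NULL, se = NULL) {
  if (inherits(fit, "dtc")) {
    K <- fit$K
    if (is.null(p0)) p0 <- fit$p0
    if (is.null(se)) se <- fit$se
  } else K <- fit
  n <- nrow(K)
  if (is.null(p0)) p0 <- stationary_distribution(K)
  nodes <- data.frame(state = seq_len(n), population_pct = 100 * p0)
  idx <- which(row(K) != col(K) & K > 0, arr.ind = TRUE)
  edges <- data.frame(from = integer(0), to = integer(0),
                      rate = numeric(0), se = numeric(0),
                      weight = numeric(0))
  if (nrow(idx)) {
    rate <- K[idx]
    edges <- data.frame(from = idx[, 2], to = idx[, 1], rate = rate,
                        se = if (!is.null(se)) se[idx] else NA_real_,
                        weight = rate / max(rate))
    edges <- edges[order(edges$from, edges$to), ]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "kinetic_network")
}

#' @export
print.kinetic_network <- function(x, ...) {
  cat(sprintf("Kinetic network: %d state(s), %d directed edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  for (i in seq_len(nrow(x$nodes)))
    cat(sprintf("  S%d: %.1f%%\n", x$nodes$state[i],
                x$nodes$population_pct[i]))
  for (i in seq_len(nrow(x$edges)))
    cat(sprintf("  S%d -> S%d: %.5g +/- %.2g 1/ps\n",
                x$edges$from[i], x$edges$to[i], x$edges$rate[i],
                x$edges$se[i]))
  invisible(x)
}

#' @export
plot.dtc <- function(x, ...) {
  net <- kinetic_network_report(x)
  n <- nrow(net$nodes)
  th <- pi / 2 + 2 * pi * (seq_len(n) - 1) / max(n, 1)
  px <- cos(th); py <- sin(th)
  plot(NA, xlim = c(-1.6, 1.6), ylim = c(-1.6, 1.6), axes = FALSE,
       xlab = "", ylab = "", asp = 1, ...)
  if (nrow(net$edges)) for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$from[i]; b <- net$edges$to[i]
    dx <- px[b] - px[a]; dy <- py[b] - py[a]
    len <- sqrt(dx^2 + dy^2)
    ux <- dx / len; uy <- dy / len
    # offset the two directions of each pair sideways
    ox <- -uy * 0.06; oy <- ux * 0.06
    arrows(px[a] + ux * 0.28 + ox, py[a] + uy * 0.28 + oy,
           px[b] - ux * 0.28 + ox, py[b] - uy * 0.28 + oy,
           lwd = 0.5 + 4 * net$edges$weight[i], length = 0.1,
           col = "steelblue")
  }
  graphics::symbols(px, py, circles = rep(0.22, n), inches = FALSE,
                    add = TRUE, bg = "grey92")
  text(px, py, sprintf("S%d\n%.0f%%", net$nodes$state,
                       net$nodes$population_pct), cex = 0.8)
  invisible(x)
}
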