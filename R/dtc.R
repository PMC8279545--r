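#' Count committed state transitions and dwell times
#'
#' Direct transition counting over one or more state sequences: a
#' transition m -> n is counted when consecutive frames carry different
#' labels \emph{within the same segment} (transition-based assignment has
#' already absorbed buffer excursions into the labels); nothing is counted
#' across segment boundaries. The dwell time of state m is the total time
#' spent labelled m.
#'
#' @param state_sequences A `state_seq` (integer vector with a `segments`
#'   attribute) or a list of them.
#' @param dt Frame interval (ps).
#' @param n_states Number of states; default the maximum label seen.
#' @param respect_segments If `FALSE`, segment boundaries are ignored.
#' @return List with `counts` (matrix, `counts[n, m]` = number of m -> n
#'   transitions), `dwell` (ps per state), `n_states`, `dt`, `n_frames`.
#' @export
count_transitions <- function(state_sequences, dt = 1, n_states = NULL,
                              respect_segments = TRUE) {
  seqs <- if (is.list(state_sequences)) state_sequences
          else list(state_sequences)
  if (length(seqs) == 0 || all(lengths(seqs) == 0))
    stop("no state sequences supplied")
  if (is.null(n_states))
    n_states <- max(unlist(lapply(seqs, max, na.rm = TRUE)))
  C <- matrix(0, n_states, n_states)
  dwell <- numeric(n_states)
  n_frames <- 0L
  for (s in seqs) {
    lab <- as.integer(s)
    n <- length(lab)
    n_frames <- n_frames + n
    seg <- attr(s, "segments")
    if (is.null(seg) || !respect_segments) seg <- rep(1L, n)
    ok <- !is.na(lab)
    dwell <- dwell + tabulate(lab[ok], n_states) * dt
    if (n < 2) next
    i <- seq_len(n - 1L)
    tr <- ok[i] & ok[i + 1L] & lab[i] != lab[i + 1L] & seg[i] == seg[i + 1L]
    if (any(tr)) {
      tb <- table(factor(lab[i + 1L][tr], levels = seq_len(n_states)),
                  factor(lab[i][tr], levels = seq_len(n_states)))
      C <- C + unclass(tb)
    }
  }
  dimnames(C) <- NULL
  list(counts = C, dwell = dwell, n_states = n_states, dt = dt,
       n_frames = n_frames)
}

#' Estimate a master-equation rate matrix by direct transition counting
#'
#' The DTC estimator: `k_nm = N(m -> n) / tau_m`, the number of committed
#' m -> n transitions divided by the total dwell time in m; the diagonal is
#' set so every column sums to zero, as required by the master equation
#' `dp/dt = K p`.
#'
#' @param counts Transition-count matrix (`counts[n, m]` = m -> n).
#' @param dwells Per-state dwell times (ps).
#' @return Rate matrix K (1/ps). Columns of states never visited are `NA`
#'   and flagged with a warning rather than silently zero; an all-zero
#'   count matrix yields `K = 0` with a warning.
#' @export
estimate_rates <- function(counts, dwells) {
  n <- length(dwells)
  stopifnot(is.matrix(counts), all(dim(counts) == n))
  K <- matrix(0, n, n)
  unvisited <- dwells <= 0
  if (any(unvisited & colSums(counts) > 0))
    stop("states with outgoing transitions but zero dwell time")
  for (m in seq_len(n)) {
    if (unvisited[m]) { K[, m] <- NA_real_; next }
    K[, m] <- counts[, m] / dwells[m]
    K[m, m] <- 0
    K[m, m] <- -sum(K[, m])
  }
  if (any(unvisited))
    warning("state(s) never visited: ",
            paste(which(unvisited), collapse = ", "),
            "; their rate columns are undetermined (NA)")
  if (n > 1 && !any(unvisited) && all(counts == 0))
    warning("no transitions observed: K = 0")
  K
}

.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which((adj[v, ] | adj[, v]) & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Stationary populations from the rate matrix
#'
#' The equilibrium population vector p0 satisfies `K p0 = 0`: it is the
#' right eigenvector of K for the eigenvalue 0 (the largest eigenvalue of a
#' valid rate matrix), normalised to sum to one, with strictly positive
#' entries for a connected chain.
#'
#' @param K Rate matrix (`K[n, m]` = m -> n rate, zero column sums).
#' @param tol Relative tolerance for validation.
#' @return Numeric population vector summing to 1.
#' @export
stationary_distribution <- function(K, tol = 1e-8) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  n <- nrow(K)
  if (n == 1) return(1)
  if (anyNA(K)) stop("rate matrix has undetermined (NA) columns")
  off <- K; diag(off) <- 0
  scale <- max(abs(K))
  if (any(off < -tol * max(scale, 1)))
    stop("rate matrix has negative off-diagonal entries")
  if (any(abs(colSums(K)) > tol * max(scale, 1) * n))
    stop("rate matrix columns must sum to zero")
  adj <- off > 0
  comp <- .components(adj)
  if (max(comp) > 1) {
    grp <- split(seq_len(n), comp)
    stop("disconnected chain: zero eigenvalue is degenerate; components: ",
         paste(vapply(grp, function(g)
           paste0("{", paste(g, collapse = ","), "}"), ""), collapse = " "))
  }
  ev <- eigen(K)
  i0 <- which.min(abs(ev$values))
  p <- Re(ev$vectors[, i0])
  p <- p / sum(p)
  if (any(p < -1e-8))
    stop("stationary eigenvector has negative entries; invalid rate matrix")
  p[p < 0] <- 0
  p <- p / sum(p)
  if (max(abs(K %*% p)) > tol * max(scale, 1) * n * 10)
    stop("stationary vector does not satisfy K p = 0 within tolerance")
  as.numeric(p)
}

#' Master-equation propagator
#'
#' The lag-Delta conditional transition-probability matrix
#' `P(Delta) = exp(K Delta)`: `P[n, m]` is the probability of being in
#' state n after a lag Delta given state m. Columns sum to one and the
#' family satisfies the semigroup property
#' `P(d1 + d2) = P(d1) P(d2)`.
#'
#' @param K Rate matrix.
#' @param lag Lag time (ps), >= 0.
#' @return N x N propagator matrix.
#' @export
propagator <- function(K, lag) {
  if (lag < 0) stop("lag must be >= 0")
  if (anyNA(K)) stop("rate matrix has undetermined (NA) columns")
  as.matrix(Matrix::expm(K * lag))
}

#' Empirical propagator from state sequences
#'
#' Counts ordered pairs (state at t = m, state at t + lag = n), excluding
#' pairs that span a segment boundary, and normalises per origin state.
#'
#' @param state_sequences A `state_seq` or list of them.
#' @param lag Lag time (must be a multiple of `dt`).
#' @param dt Frame interval (ps).
#' @param n_states Number of states; default the maximum label.
#' @return N x N matrix of conditional probabilities (columns = origin,
#'   summing to 1); origin states with no valid pairs give `NA` columns
#'   with a warning.
#' @export
empirical_propagator <- function(state_sequences, lag, dt = 1,
                                 n_states = NULL) {
  seqs <- if (is.list(state_sequences)) state_sequences
          else list(state_sequences)
  L <- round(lag / dt)
  if (L < 1 || abs(L - lag / dt) > 1e-9)
    stop("lag must be a positive multiple of the frame interval")
  if (is.null(n_states))
    n_states <- max(unlist(lapply(seqs, max, na.rm = TRUE)))
  C <- matrix(0, n_states, n_states)
  for (s in seqs) {
    lab <- as.integer(s)
    n <- length(lab)
    if (n <= L) next
    seg <- attr(s, "segments")
    if (is.null(seg)) seg <- rep(1L, n)
    i <- seq_len(n - L)
    ok <- !is.na(lab[i]) & !is.na(lab[i + L]) & seg[i] == seg[i + L]
    if (any(ok)) {
      tb <- table(factor(lab[i + L][ok], levels = seq_len(n_states)),
                  factor(lab[i][ok], levels = seq_len(n_states)))
      C <- C + unclass(tb)
    }
  }
  dimnames(C) <- NULL
  tot <- colSums(C)
  if (all(tot == 0)) stop("no valid state pairs at this lag")
  P <- sweep(C, 2, ifelse(tot > 0, tot, 1), "/")
  if (any(tot == 0)) {
    P[, tot == 0] <- NA_real_
    warning("origin state(s) with no valid pairs: ",
            paste(which(tot == 0), collapse = ", "))
  }
  P
}

#' Check the geometric-mean relation between R- and T-propagators
#'
#' Propagators for transitions along the continuous replica trajectories
#' are, to a good approximation, the weighted geometric means of the
#' propagators of the corresponding transitions in the per-temperature
#' trajectories, with weights the fractions of time spent at each
#' temperature. This compares the replica propagator against
#' `normalise( prod_t P_t^(w_t) )` elementwise.
#'
#' @param per_temperature_propagators List of N x N propagators, one per
#'   rung.
#' @param temperature_weights Non-negative weights summing to 1 (fractions
#'   of time at each temperature).
#' @param replica_propagator N x N propagator estimated from the replica
#'   trajectories.
#' @return A list of class `"propagator_check"`: `deviation` (max absolute
#'   elementwise difference over comparable entries), `table` (per-entry
#'   comparison), `skipped` (entries whose geometric mean is ill-defined
#'   because some per-temperature entry is zero or missing).
#' @export
check_geometric_mean_relation <- function(per_temperature_propagators,
                                          temperature_weights,
                                          replica_propagator) {
  w <- temperature_weights
  if (any(w < 0)) stop("weights must be >= 0")
  if (abs(sum(w) - 1) > 1e-8) stop("weights must sum to 1")
  if (length(w) != length(per_temperature_propagators))
    stop("one weight per temperature propagator required")
  n <- nrow(replica_propagator)
  lg <- matrix(0, n, n)
  bad <- matrix(FALSE, n, n)
  for (t in seq_along(w)) {
    if (w[t] == 0) next
    P <- per_temperature_propagators[[t]]
    b <- !is.finite(P) | P <= 0
    bad <- bad | b
    Pl <- P
    Pl[b] <- 1            # masked below
    lg <- lg + w[t] * log(Pl)
  }
  G <- exp(lg)
  G[bad] <- NA_real_
  cs <- colSums(G, na.rm = TRUE)
  G <- sweep(G, 2, ifelse(cs > 0, cs, 1), "/")
  dev <- abs(G - replica_propagator)
  tab <- data.frame(from = rep(seq_len(n), each = n),
                    to = rep(seq_len(n), n),
                    geometric_mean = as.vector(G),
                    replica = as.vector(replica_propagator),
                    deviation = as.vector(dev))
  skipped <- tab[is.na(tab$geometric_mean), c("from", "to")]
  structure(list(deviation = max(dev, na.rm = TRUE), table = tab,
                 skipped = skipped), class = "propagator_check")
}

#' @export
print.propagator_check <- function(x, ...) {
  cat(sprintf("R/T propagator geometric-mean check: max deviation %.4f (%d entr%s skipped)\n",
              x$deviation, nrow(x$skipped),
              if (nrow(x$skipped) == 1) "y" else "ies"))
  invisible(x)
}

#' Block-averaged statistical errors of DTC rates
#'
#' Splits each state sequence into `B` contiguous blocks, estimates the
#' rate matrix per block (pooling sequences), and reports per-rate means
#' and standard errors of the block means (`SEM = sd / sqrt(B)`), the
#' standard convergence assessment for quantities extracted from REMD
#' data. Blocks in which a state is never visited are excluded for that
#' state's outgoing rates, with a warning.
#'
#' @param state_sequences A `state_seq` or list of them.
#' @param B Number of blocks (>= 2).
#' @param dt Frame interval (ps).
#' @param n_states Number of states; default the maximum label.
#' @return A list of class `"block_error_report"`: `mean` and `se`
#'   (N x N matrices), `B`, `used` (blocks used per column), `per_block`
#'   (N x N x B array of block rate matrices).
#' @export
block_errors <- function(state_sequences, B, dt = 1, n_states = NULL) {
  if (B < 2) stop("need at least 2 blocks")
  seqs <- if (is.list(state_sequences)) state_sequences
          else list(state_sequences)
  if (is.null(n_states))
    n_states <- max(unlist(lapply(seqs, max, na.rm = TRUE)))
  if (min(lengths(seqs)) < B)
    stop("sequences too short to form ", B, " blocks")
  per_block <- array(NA_real_, c(n_states, n_states, B))
  dwell_b <- matrix(0, B, n_states)
  for (b in seq_len(B)) {
    chunk <- lapply(seqs, function(s) {
      n <- length(s)
      cut <- floor(n * c(b - 1, b) / B)
      idx <- (cut[1] + 1L):cut[2]
      seg <- attr(s, "segments")
      structure(as.integer(s)[idx],
                segments = if (is.null(seg)) NULL else seg[idx],
                class = "state_seq")
    })
    ct <- count_transitions(chunk, dt = dt, n_states = n_states)
    dwell_b[b, ] <- ct$dwell
    Kb <- suppressWarnings(estimate_rates(ct$counts, ct$dwell))
    per_block[, , b] <- Kb
  }
  mean_m <- matrix(NA_real_, n_states, n_states)
  se_m <- matrix(NA_real_, n_states, n_states)
  used <- integer(n_states)
  excluded <- FALSE
  for (m in seq_len(n_states)) {
    ok <- dwell_b[, m] > 0
    used[m] <- sum(ok)
    if (sum(ok) < B) excluded <- TRUE
    if (sum(ok) == 0) next
    for (n2 in seq_len(n_states)) {
      v <- per_block[n2, m, ok]
      mean_m[n2, m] <- mean(v)
      se_m[n2, m] <- if (sum(ok) > 1) sd(v) / sqrt(sum(ok)) else NA_real_
    }
  }
  if (excluded)
    warning("some blocks never visit state(s) ",
            paste(which(used < B), collapse = ", "),
            "; those blocks are excluded for the affected rates")
  structure(list(mean = mean_m, se = se_m, B = B, used = used,
                 per_block = per_block), class = "block_error_report")
}

#' @export
print.block_error_report <- function(x, ...) {
  cat(sprintf("Block error analysis (B = %d)\n", x$B))
  n <- nrow(x$mean)
  for (m in seq_len(n)) for (n2 in seq_len(n)) if (m != n2)
    cat(sprintf("  k[%d<-%d] = %.5g +/- %.2g 1/ps (%d blocks)\n",
                n2, m, x$mean[n2, m], x$se[n2, m], x$used[m]))
  invisible(x)
}

#' Fit a Markov kinetic model by direct transition counting
#'
#' The main fitting function of the package. Given TBA-labelled state
#' sequences (typically all replica trajectories of an REMD run,
#' cumulated), it counts committed transitions and dwell times, estimates
#' the master-equation rate matrix `k_nm = N(m->n)/tau_m`, computes the
#' stationary populations from the zero-eigenvalue eigenvector of K, and
#' attaches block-averaged standard errors.
#'
#' @param state_sequences A `state_seq` or a list of them.
#' @param dt Frame interval (ps).
#' @param n_states Number of states; default the maximum label.
#' @param blocks Number of blocks for the error analysis (default 5; set to
#'   0 to skip).
#' @return An object of class `"dtc"` with components `K`, `counts`,
#'   `dwell`, `p0` (stationary populations, `NULL` when the chain is
#'   disconnected), `se`, `blocks`, `dt`, `n_states`, `n_frames`.
#'   Standard methods are available: [print()], [summary()], [coef()],
#'   [vcov()], [predict()] (propagator / population evolution),
#'   [simulate()] and [plot()].
#' @examples
#' s <- structure(rep(c(1L, 2L), each = 500), class = "state_seq")
#' fit <- dtc(s, dt = 1, blocks = 2)
#' coef(fit)
#' @export
dtc <- function(state_sequences, dt = 1, n_states = NULL, blocks = 5) {
  ct <- count_transitions(state_sequences, dt = dt, n_states = n_states)
  K <- estimate_rates(ct$counts, ct$dwell)
  p0 <- tryCatch(stationary_distribution(K), error = function(e) NULL)
  se <- NULL
  if (blocks >= 2)
    se <- tryCatch(block_errors(state_sequences, B = blocks, dt = dt,
                                n_states = ct$n_states),
                   error = function(e) NULL)
  structure(list(K = K, counts = ct$counts, dwell = ct$dwell, p0 = p0,
                 se = if (is.null(se)) NULL else se$se,
                 block_report = se, blocks = blocks, dt = dt,
                 n_states = ct$n_states, n_frames = ct$n_frames,
                 call = match.call()),
            class = "dtc")
}

#' @export
print.dtc <- function(x, digits = 4, ...) {
  cat(sprintf("Direct-transition-counting kinetic model: %d state(s), %d frames\n",
              x$n_states, x$n_frames))
  cat("Rate matrix K (1/ps; K[n,m] = rate m -> n):\n")
  print(signif(x$K, digits))
  if (!is.null(x$p0))
    cat("Stationary populations:",
        paste(sprintf("%.1f%%", 100 * x$p0), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.dtc <- function(object, ...) {
  n <- object$n_states
  idx <- which(row(object$K) != col(object$K))
  k <- object$K[idx]
  names(k) <- paste0("k[", row(object$K)[idx], "<-", col(object$K)[idx], "]")
  k
}

#' @export
vcov.dtc <- function(object, ...) {
  k <- coef(object)
  v <- matrix(0, length(k), length(k), dimnames = list(names(k), names(k)))
  if (!is.null(object$se)) {
    idx <- which(row(object$K) != col(object$K))
    diag(v) <- object$se[idx]^2
  } else diag(v) <- NA_real_
  v
}

#' @export
summary.dtc <- function(object, ...) {
  n <- object$n_states
  idx <- which(row(object$K) != col(object$K), arr.ind = TRUE)
  rates <- data.frame(from = idx[, 2], to = idx[, 1],
                      counts = object$counts[idx],
                      rate = object$K[idx],
                      se = if (!is.null(object$se)) object$se[idx]
                           else NA_real_)
  rates <- rates[order(rates$from, rates$to), ]
  structure(list(rates = rates,
                 populations_pct = if (!is.null(object$p0)) 100 * object$p0
                                   else NULL,
                 dwell = object$dwell, n_frames = object$n_frames,
                 n_states = n, blocks = object$blocks),
            class = "summary.dtc")
}

#' @export
print.summary.dtc <- function(x, ...) {
  cat(sprintf("DTC kinetic model: %d state(s), %d frames, %d error blocks\n",
              x$n_states, x$n_frames, x$blocks))
  cat("Transition rates (1/ps):\n")
  print(transform(x$rates, rate = signif(rate, 4), se = signif(se, 2)),
        row.names = FALSE)
  if (!is.null(x$populations_pct))
    cat("Stationary populations:",
        paste(sprintf("%.1f%%", x$populations_pct), collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.dtc <- function(object, lag = 1,
                        type = c("propagator", "populations"),
                        p = NULL, ...) {
  type <- match.arg(type)
  P <- propagator(object$K, lag)
  if (type == "propagator") return(P)
  if (is.null(p)) p <- rep(1 / object$n_states, object$n_states)
  as.numeric(P %*% p)
}

#' @export
simulate.dtc <- function(object, nsim = 1, seed = NULL, n_frames = 1000,
                         start_state = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  K <- object$K
  if (anyNA(K)) stop("cannot simulate from a model with undetermined columns")
  n <- object$n_states
  off <- K; diag(off) <- 0
  lam <- colSums(off)
  dt <- object$dt
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    s0 <- if (is.null(start_state)) {
      if (!is.null(object$p0)) sample.int(n, 1, prob = object$p0)
      else sample.int(n, 1)
    } else start_state
    total <- n_frames * dt
    jt <- numeric(0); js <- integer(0)
    s <- s0
    t_cur <- 0
    while (lam[s] > 0) {
      t_cur <- t_cur + rexp(1, lam[s])
      if (t_cur > total) break
      s <- sample.int(n, 1, prob = off[, s])
      jt <- c(jt, t_cur); js <- c(js, s)
    }
    frame_t <- seq_len(n_frames) * dt
    out[[r]] <- structure(c(s0, js)[findInterval(frame_t, jt) + 1L],
                          class = "state_seq")
  }
  out
}
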