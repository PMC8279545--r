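# Replay the accepted swaps of an exchange log from the identity permutation.
# Returns occupant snapshots: occ[j, k] = replica at temperature k after the
# first (j-1) accepted swaps. Validates neighbour pairs and, when the log
# records occupant replica ids, their consistency with the replay.
.replay_snapshots <- function(log, n_temps) {
  if (nrow(log) && any(log$temp_hi != log$temp_lo + 1L))
    stop("exchange log: pair (", log$temp_lo[which(log$temp_hi != log$temp_lo + 1L)[1]],
         ",", log$temp_hi[which(log$temp_hi != log$temp_lo + 1L)[1]],
         ") is not a ladder neighbour pair")
  if (nrow(log) && any(log$temp_lo < 1L | log$temp_hi > n_temps))
    stop("exchange log: temperature index outside ladder of size ", n_temps)
  if (nrow(log) && is.unsorted(log$time))
    stop("exchange log: times must be non-decreasing")
  acc <- log[log$accepted, , drop = FALSE]
  occ <- matrix(0L, nrow(acc) + 1L, n_temps)
  occ[1L, ] <- seq_len(n_temps)
  cur <- seq_len(n_temps)
  has_ids <- all(c("replica_lo", "replica_hi") %in% names(log))
  for (j in seq_len(nrow(acc))) {
    k <- acc$temp_lo[j]
    if (has_ids && !is.na(acc$replica_lo[j]) &&
        (cur[k] != acc$replica_lo[j] || cur[k + 1L] != acc$replica_hi[j]))
      stop("exchange log inconsistent with replay at time ", acc$time[j],
           ": temperatures (", k, ",", k + 1L, ") occupied by (",
           cur[k], ",", cur[k + 1L], "), log says (",
           acc$replica_lo[j], ",", acc$replica_hi[j], ")")
    cur[c(k, k + 1L)] <- cur[c(k + 1L, k)]
    occ[j + 1L, ] <- cur
  }
  list(occ = occ, times = acc$time)
}

.log_n_temps <- function(exchange_log, default = NULL) {
  n <- attr(exchange_log, "n_temps")
  if (!is.null(n)) return(n)
  if (!is.null(default)) return(default)
  if (nrow(exchange_log)) max(exchange_log$temp_hi) else
    stop("cannot infer ladder size from an empty exchange log")
}

# Snapshot row applicable to each frame time: a swap accepted at time t
# affects frames strictly later than t.
.snapshot_index <- function(times, acc_times) {
  eps <- if (length(times) > 1) (times[2] - times[1]) * 1e-9 else 1e-9
  findInterval(times - eps, acc_times) + 1L
}

#' Demultiplex replica trajectories into temperature trajectories
#'
#' Replica (R-) trajectories are continuous records of each replica as it
#' wanders across temperatures; temperature (T-) trajectories are stitched
#' from whichever replica occupies a given rung and are discontinuous at
#' accepted exchanges. `demux` replays the exchange log's accepted swaps
#' from the identity permutation and reassembles the per-temperature view;
#' [remux()] is its exact inverse.
#'
#' @param replicas A `remd_run`, or a list of per-replica data frames
#'   sharing one uniform time grid (column `time` plus per-frame series).
#' @param exchange_log An `exchange_log` data frame (ignored when
#'   `replicas` is a run, which carries its own).
#' @return A list of `temp_traj` data frames, one per rung, each with the
#'   replica columns plus `source_replica`, and attributes `temp_index`,
#'   `boundaries` (times of accepted swaps touching the rung) and
#'   `segments` (per-frame segment id between those boundaries).
#' @export
demux <- function(replicas, exchange_log = NULL) {
  if (inherits(replicas, "remd_run")) {
    exchange_log <- replicas$exchange
    replicas <- replicas$replicas
  }
  if (is.null(exchange_log)) stop("an exchange log is required")
  M <- .log_n_temps(exchange_log, default = length(replicas))
  if (M != length(replicas))
    stop("exchange log ladder size (", M, ") does not match the ",
         length(replicas), " replica trajectories")
  times <- replicas[[1]]$time
  for (r in seq_along(replicas))
    if (!isTRUE(all.equal(replicas[[r]]$time, times)))
      stop("replica trajectories do not share a time grid (replica ", r, ")")
  if (nrow(exchange_log) && max(exchange_log$time) > max(times) + 1e-9)
    stop("exchange log inconsistent with time grid: attempt at time ",
         exchange_log$time[which(exchange_log$time > max(times) + 1e-9)[1]],
         " is beyond the last frame")
  rp <- .replay_snapshots(exchange_log, M)
  idx <- .snapshot_index(times, rp$times)
  cols <- setdiff(names(replicas[[1]]), c("time", "temp"))
  mats <- lapply(cols, function(cn)
    vapply(replicas, function(d) as.numeric(d[[cn]]), numeric(length(times))))
  names(mats) <- cols
  n <- length(times)
  out <- vector("list", M)
  for (k in seq_len(M)) {
    src <- rp$occ[cbind(idx, rep(k, n))]
    df <- data.frame(time = times, temp = rep(k, n))
    for (cn in cols) df[[cn]] <- mats[[cn]][cbind(seq_len(n), src)]
    if ("state" %in% cols) df$state <- as.integer(df$state)
    df$source_replica <- src
    acc <- exchange_log[exchange_log$accepted, , drop = FALSE]
    bnd <- acc$time[acc$temp_lo == k | acc$temp_hi == k]
    attr(df, "temp_index") <- k
    attr(df, "boundaries") <- bnd
    eps <- if (n > 1) (times[2] - times[1]) * 1e-9 else 1e-9
    attr(df, "segments") <- findInterval(times - eps, bnd) + 1L
    class(df) <- c("temp_traj", "data.frame")
    out[[k]] <- df
  }
  out
}

#' Recompose replica trajectories from temperature trajectories
#'
#' Exact inverse of [demux()]: `remux(demux(x, log), log)` reproduces `x`
#' field by field.
#'
#' @param temp_trajs List of `temp_traj` data frames from [demux()].
#' @param exchange_log The same exchange log used to demultiplex.
#' @return A list of per-replica data frames.
#' @export
remux <- function(temp_trajs, exchange_log) {
  M <- .log_n_temps(exchange_log, default = length(temp_trajs))
  if (M != length(temp_trajs))
    stop("exchange log ladder size does not match the trajectories")
  times <- temp_trajs[[1]]$time
  rp <- .replay_snapshots(exchange_log, M)
  idx <- .snapshot_index(times, rp$times)
  # temp_of[j, r]: temperature of replica r in snapshot j
  tof <- matrix(0L, nrow(rp$occ), M)
  for (j in seq_len(nrow(rp$occ))) tof[j, rp$occ[j, ]] <- seq_len(M)
  cols <- setdiff(names(temp_trajs[[1]]), c("time", "temp", "source_replica"))
  mats <- lapply(cols, function(cn)
    vapply(temp_trajs, function(d) as.numeric(d[[cn]]), numeric(length(times))))
  names(mats) <- cols
  n <- length(times)
  out <- vector("list", M)
  for (r in seq_len(M)) {
    tmp <- tof[cbind(idx, rep(r, n))]
    df <- data.frame(time = times, temp = tmp)
    for (cn in cols) df[[cn]] <- mats[[cn]][cbind(seq_len(n), tmp)]
    if ("state" %in% cols) df$state <- as.integer(df$state)
    attr(df, "replica_id") <- r
    class(df) <- c("replica_traj", "data.frame")
    out[[r]] <- df
  }
  out
}

#' Exchange acceptance rate
#'
#' Fraction of accepted exchange attempts, overall and per neighbour pair.
#'
#' @param exchange_log An `exchange_log` data frame.
#' @param pair Optional rung index `k` selecting the pair `(k, k+1)`; the
#'   returned `overall` is then that pair's rate.
#' @return A list of class `"acceptance_report"` with `overall` (fraction in
#'   `[0, 1]`) and `by_pair` (data frame with `temp_lo`, `temp_hi`,
#'   `attempts`, `accepted`, `rate`; pairs never attempted have `NA` rate).
#' @export
acceptance_rate <- function(exchange_log, pair = NULL) {
  M <- .log_n_temps(exchange_log)
  if (nrow(exchange_log) == 0)
    stop("acceptance rate undefined: no exchange attempts")
  lo <- seq_len(M - 1L)
  att <- vapply(lo, function(k) sum(exchange_log$temp_lo == k), 0L)
  acc <- vapply(lo, function(k)
    sum(exchange_log$accepted[exchange_log$temp_lo == k]), 0L)
  by_pair <- data.frame(temp_lo = lo, temp_hi = lo + 1L,
                        attempts = att, accepted = acc,
                        rate = ifelse(att > 0, acc / att, NA_real_))
  if (!is.null(pair)) {
    if (att[pair] == 0)
      stop("acceptance rate undefined for pair (", pair, ",", pair + 1L,
           "): no attempts")
    overall <- by_pair$rate[pair]
  } else {
    overall <- mean(exchange_log$accepted)
  }
  structure(list(overall = overall, by_pair = by_pair),
            class = "acceptance_report")
}

#' @export
print.acceptance_report <- function(x, ...) {
  cat(sprintf("Exchange acceptance: %.3f overall\n", x$overall))
  print(x$by_pair, row.names = FALSE)
  invisible(x)
}

#' Equal-occupancy diagnostic
#'
#' In a converged REMD run each replica spends approximately equal time at
#' every temperature. This computes the replica-by-temperature occupancy
#' matrix and the deviation statistic `max |omega_rt - 1/M|`; the run
#' passes when the statistic is below `threshold` (default `0.5/M`).
#'
#' @param x A `remd_run`, a list of replica trajectories (per-frame `temp`
#'   column), or an `exchange_log` (occupancy then weighted per attempt
#'   round).
#' @param ladder_size Ladder size `M`; inferred when possible.
#' @param threshold Pass threshold on the deviation statistic.
#' @return An `"occupancy_report"`: list with `occupancy` (rows = replicas,
#'   summing to 1), `deviation`, `threshold`, `pass`.
#' @export
occupancy <- function(x, ladder_size = NULL, threshold = NULL) {
  if (inherits(x, "remd_run")) x <- x$replicas
  if (inherits(x, "exchange_log")) {
    M <- .log_n_temps(x, default = ladder_size)
    rp <- .replay_snapshots(x, M)
    occ <- rp$occ
    if (nrow(occ) < 2) stop("occupancy: log replays to zero duration")
    # weight each snapshot by its persistence in rounds (last one by 1)
    w <- diff(c(rp$times, max(x$time)))
    w <- c(w, attr(x, "exchange_interval") %||% 1)
    om <- matrix(0, M, M)
    for (j in seq_len(nrow(occ)))
      om[cbind(occ[j, ], seq_len(M))] <- om[cbind(occ[j, ], seq_len(M))] + w[j]
    om <- om / rowSums(om)
  } else {
    M <- if (is.null(ladder_size)) length(x) else ladder_size
    n <- nrow(x[[1]])
    if (n == 0) stop("occupancy: zero-duration trajectories")
    om <- t(vapply(x, function(d) tabulate(d$temp, M) / n, numeric(M)))
  }
  if (is.null(threshold)) threshold <- 0.5 / ncol(om)
  dev <- max(abs(om - 1 / ncol(om)))
  structure(list(occupancy = om, deviation = dev, threshold = threshold,
                 pass = dev < threshold), class = "occupancy_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.occupancy_report <- function(x, ...) {
  cat(sprintf("Equal-occupancy check: max |omega - 1/M| = %.4f (threshold %.4f) -> %s\n",
              x$deviation, x$threshold, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
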