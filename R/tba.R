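# Topographic prominence of local maxima of a binned density: height above
# the higher of the two key saddles (the minimum on the path to the nearest
# higher peak, or to the boundary when no higher peak exists on that side).
.peak_prominence <- function(d, peaks) {
  n <- length(d)
  vapply(peaks, function(p) {
    h <- d[p]
    left <- which(d[seq_len(p - 1)] > h)
    saddle_l <- if (length(left)) min(d[max(left):p]) else min(d[1:p])
    right <- which(d[seq(p + 1, n)] > h) + p
    saddle_r <- if (length(right)) min(d[p:min(right)]) else min(d[p:n])
    h - max(saddle_l, saddle_r)
  }, numeric(1))
}

#' Detect conformational core intervals on the d_ee axis
#'
#' Builds a binned density of the reaction coordinate, lightly smooths it
#' (moving average), finds local maxima whose topographic prominence
#' exceeds `prominence` times the maximum density, and defines each state's
#' core as the interval around its peak where the density stays at or above
#' `core_fraction` of the peak height, truncated at the density minimum
#' between adjacent peaks so the cores are pairwise disjoint. Everything
#' outside the cores is buffer.
#'
#' @param x Numeric d_ee series (Angstrom), length >= 1000.
#' @param bin_width Histogram bin width (default 0.1 A).
#' @param prominence Minimum peak prominence as a fraction of the maximum
#'   density (default 0.05).
#' @param core_fraction Density fraction of the peak height delimiting the
#'   core (default 0.6, leaving a clear buffer between cores).
#' @param smooth Odd moving-average window in bins (default 3).
#' @return A data frame of class `"core_def"`, one row per state (sorted by
#'   lower bound): `state`, `lower`, `upper`, `peak`, `height`.
#' @export
detect_cores <- function(x, bin_width = 0.1, prominence = 0.05,
                         core_fraction = 0.6, smooth = 3) {
  x <- as.numeric(x)
  if (length(x) < 1000)
    stop("core detection needs at least 1000 frames (got ", length(x), ")")
  h <- obs_histogram(x, bin_width = bin_width)
  d <- h$density
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    d <- as.numeric(stats::filter(d, k, sides = 2))
    d[is.na(d)] <- h$density[is.na(d)]
  }
  n <- length(d)
  if (n < 3) stop("too few bins for peak detection; decrease bin_width")
  cand <- which(d[-c(1, n)] > d[-c(n - 1, n)] &
                  d[-c(1, n)] >= d[-c(1, 2)]) + 1L
  if (length(cand) == 0)
    stop("no density peak found; lower `prominence` or adjust `bin_width`")
  prom <- .peak_prominence(d, cand)
  keep <- cand[prom >= prominence * max(d)]
  if (length(keep) == 0)
    stop("no peak above the prominence threshold (", prominence,
         " x max density); lower `prominence` or adjust `bin_width`")
  keep <- sort(keep)
  # valley bin between consecutive kept peaks bounds the cores
  valleys <- if (length(keep) > 1)
    vapply(seq_len(length(keep) - 1), function(i) {
      rng <- keep[i]:keep[i + 1]
      rng[which.min(d[rng])]
    }, integer(1)) else integer(0)
  cores <- lapply(seq_along(keep), function(i) {
    p <- keep[i]
    thr <- core_fraction * d[p]
    lo_lim <- if (i > 1) valleys[i - 1] + 1L else 1L
    hi_lim <- if (i < length(keep)) valleys[i] - 1L else n
    l <- p
    while (l > lo_lim && d[l - 1L] >= thr) l <- l - 1L
    r <- p
    while (r < hi_lim && d[r + 1L] >= thr) r <- r + 1L
    c(h$breaks[l], h$breaks[r + 1L], h$mids[p], d[p])
  })
  m <- do.call(rbind, cores)
  out <- data.frame(state = seq_along(keep), lower = m[, 1], upper = m[, 2],
                    peak = m[, 3], height = m[, 4])
  class(out) <- c("core_def", "data.frame")
  validate_cores(out)
  out
}

#' Validate a core definition
#' @param cores A `core_def` data frame (`state`, `lower`, `upper`).
#' @return `cores`, invisibly.
#' @export
validate_cores <- function(cores) {
  stopifnot(is.data.frame(cores),
            all(c("state", "lower", "upper") %in% names(cores)))
  if (any(cores$upper <= cores$lower))
    stop("cores: each interval must be nonempty")
  o <- order(cores$lower)
  if (any(cores$upper[o][-nrow(cores)] > cores$lower[o][-1]))
    stop("cores: intervals must be pairwise disjoint")
  invisible(cores)
}

#' Transition-based state assignment (TBA)
#'
#' Frames inside a core receive that core's label. Buffer frames inherit
#' the label of the most recently visited core within the current segment,
#' so excursions into the buffer that return to the same core are not
#' transitions; a transition is committed only when a different core is
#' entered. Leading buffer frames of a segment inherit the first core
#' subsequently visited in that segment (default), or are dropped as `NA`
#' with `leading = "drop"`. Inheritance never crosses a segment boundary
#' (the discontinuities of temperature trajectories at accepted exchanges).
#'
#' @param x Numeric d_ee series.
#' @param cores A `core_def` (see [detect_cores()]).
#' @param segments Optional non-decreasing integer segment id per frame
#'   (default one continuous segment, as for replica trajectories).
#' @param leading `"inherit"` (default) or `"drop"` for leading buffer
#'   frames.
#' @return Integer state labels (class `"state_seq"`) with the `segments`
#'   attribute attached. A segment that never touches any core is an error
#'   listing the offending segment ids.
#' @export
assign_tba <- function(x, cores, segments = NULL,
                       leading = c("inherit", "drop")) {
  leading <- match.arg(leading)
  validate_cores(cores)
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0) stop("empty series")
  if (is.null(segments)) segments <- rep(1L, n)
  if (length(segments) != n)
    stop("segments must have one id per frame")
  lab <- integer(n)
  for (s in seq_len(nrow(cores)))
    lab[x >= cores$lower[s] & x <= cores$upper[s]] <- cores$state[s]

  new_seg <- c(TRUE, segments[-1] != segments[-n])
  seg_id <- cumsum(new_seg)
  seg_first <- which(new_seg)[seg_id]
  last_of_seg <- c(which(new_seg)[-1] - 1L, n)[seg_id]

  nz <- lab != 0L
  pos <- which(nz)
  last_pos <- c(0L, pos)[cumsum(nz) + 1L]
  nzr <- rev(nz)
  posr <- which(nzr)
  last_r <- c(0L, posr)[cumsum(nzr) + 1L]
  next_pos <- rev(ifelse(last_r == 0L, 0L, n + 1L - last_r))

  out <- lab
  buf <- !nz
  inherit_ok <- buf & last_pos >= seg_first
  out[inherit_ok] <- lab[last_pos[inherit_ok]]
  lead <- buf & !inherit_ok
  lead_ok <- lead & next_pos > 0L & next_pos <= last_of_seg
  if (leading == "inherit") {
    out[lead_ok] <- lab[next_pos[lead_ok]]
    dead <- lead & !lead_ok
  } else {
    out[lead_ok] <- NA_integer_
    dead <- lead & !lead_ok
  }
  if (any(dead)) {
    bad <- unique(segments[dead])
    stop("segment(s) never touch any core: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  }
  structure(out, segments = as.integer(segments), class = "state_seq")
}

#' Carry replica-trajectory state assignments to temperature trajectories
#'
#' State assignment is performed on the continuous replica trajectories and
#' then carried through the exchange permutation, so the per-temperature
#' state sequences equal the demultiplexed replica sequences frame by
#' frame, with segment boundaries at the accepted exchanges touching each
#' rung.
#'
#' @param assignments List of per-replica `state_seq` (or integer) vectors.
#' @param exchange_log The run's `exchange_log`.
#' @param times Frame times shared by all replicas.
#' @return A list of per-temperature `state_seq` vectors with `segments`
#'   and `temp_index` attributes.
#' @export
project_replica_assignments <- function(assignments, exchange_log, times) {
  M <- .log_n_temps(exchange_log, default = length(assignments))
  if (M != length(assignments))
    stop("exchange log ladder size does not match the assignments")
  n <- length(times)
  mat <- vapply(assignments, function(a) as.integer(a), integer(n))
  rp <- .replay_snapshots(exchange_log, M)
  idx <- .snapshot_index(times, rp$times)
  acc <- exchange_log[exchange_log$accepted, , drop = FALSE]
  eps <- if (n > 1) (times[2] - times[1]) * 1e-9 else 1e-9
  lapply(seq_len(M), function(k) {
    src <- rp$occ[cbind(idx, rep(k, n))]
    bnd <- acc$time[acc$temp_lo == k | acc$temp_hi == k]
    structure(mat[cbind(seq_len(n), src)],
              segments = findInterval(times - eps, bnd) + 1L,
              temp_index = k, class = "state_seq")
  })
}
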