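#' Derive a deterministic sub-seed
#'
#' One root seed drives the whole simulation; independent streams (the
#' exchange process and each replica's conformational path) use sub-seeds
#' derived by fixed offsets, so changing the replica count never reshuffles
#' the other replicas.
#' @keywords internal
.mix_seed <- function(seed, replica, stage) {
  ((seed %% 1000003) * 2017 + replica * 7919 + stage * 104729) %% 2147483629
}

#' Metropolis acceptance probability for a replica exchange
#'
#' The standard parallel-tempering criterion
#' `min(1, exp((beta_i - beta_j) (U_i - U_j)))` with `beta = 1/(R T)`,
#' `R = 0.0019872` kcal/(mol K). It preserves detailed balance between the
#' canonical ensembles at the two temperatures and is symmetric under a
#' simultaneous swap of (i, j).
#'
#' @param u_i,u_j Potential energies of the two replicas (kcal/mol).
#' @param t_i,t_j Temperatures of the two rungs (K), > 0.
#' @return Acceptance probability in `[0, 1]`. Vectorised.
#' @examples
#' metropolis_acceptance(-11000, -10990, 310, 372)
#' @export
metropolis_acceptance <- function(u_i, u_j, t_i, t_j) {
  if (any(t_i <= 0) || any(t_j <= 0))
    stop("metropolis_acceptance: temperatures must be positive")
  pmin(1, exp((1 / (.R_KCAL * t_i) - 1 / (.R_KCAL * t_j)) * (u_i - u_j)))
}

# Continuous-time Markov jump path over a piecewise-constant temperature
# schedule. Exact exponential dwell-time (Gillespie) sampling with a single
# Exp(1) hazard budget carried across temperature segments, then snapped to
# the frame grid; avoids the time-discretisation bias of k*dt schemes.
.sim_ctmc_path <- function(scenario, temp_runs_val, temp_runs_len, dt,
                           start_state) {
  n <- scenario$n_states
  M <- length(scenario$ladder)
  Ks <- lapply(seq_len(M), function(k) {
    K <- arrhenius_rate(scenario$base_rates, scenario$activation_energies,
                        scenario$ladder[k], scenario$ref_temp)
    diag(K) <- 0
    K
  })
  lams <- lapply(Ks, colSums)

  n_frames <- sum(temp_runs_len)
  jump_t <- numeric(64); jump_s <- integer(64); nj <- 0L
  s <- start_state
  t_cur <- 0
  E <- rexp(1)
  seg_end <- cumsum(temp_runs_len) * dt
  seg_start <- c(0, seg_end[-length(seg_end)])
  for (j in seq_along(temp_runs_val)) {
    Tk <- temp_runs_val[j]
    lam <- lams[[Tk]]
    tend <- seg_end[j]
    repeat {
      ls <- lam[s]
      if (ls <= 0) break
      t_need <- E / ls
      if (t_cur + t_need > tend) {
        E <- E - ls * (tend - t_cur)
        break
      }
      t_cur <- t_cur + t_need
      s_new <- sample.int(n, 1L, prob = Ks[[Tk]][, s])
      nj <- nj + 1L
      if (nj > length(jump_t)) {
        length(jump_t) <- 2L * length(jump_t)
        length(jump_s) <- 2L * length(jump_s)
      }
      jump_t[nj] <- t_cur
      jump_s[nj] <- s_new
      s <- s_new
      E <- rexp(1)
    }
    t_cur <- tend
  }
  jump_t <- jump_t[seq_len(nj)]
  jump_s <- jump_s[seq_len(nj)]
  frame_t <- seq_len(n_frames) * dt
  state <- c(start_state, jump_s)[findInterval(frame_t, jump_t) + 1L]
  list(state = as.integer(state), jump_times = jump_t, jump_states = jump_s)
}

#' Simulate a Markov jump state path with observable emissions
#'
#' Propagates the scenario's N-state continuous-time Markov jump process
#' along a prescribed per-frame temperature schedule (rates are
#' Arrhenius-scaled to the current rung), using exact exponential dwell-time
#' sampling, and emits a noisy d_ee value per frame from the occupied
#' state's Gaussian emission model.
#'
#' @param scenario A `remd_scenario`.
#' @param temperature_schedule Integer vector of ladder indices, one per
#'   frame.
#' @param n_frames Number of frames; must equal the schedule length.
#' @param seed Optional integer seed (set only when non-NULL, so callers
#'   managing their own streams can pass `NULL`).
#' @param start_state Initial state index; default samples the generator's
#'   stationary distribution at the reference temperature.
#' @return A list with `state` (integer per frame), `dee` (numeric per
#'   frame, Angstrom), `jump_times`, `jump_states`, `start_state`.
#' @export
simulate_state_path <- function(scenario, temperature_schedule, n_frames,
                                seed = NULL, start_state = NULL) {
  stopifnot(inherits(scenario, "remd_scenario"))
  if (length(temperature_schedule) != n_frames)
    stop("temperature_schedule length must equal n_frames")
  temperature_schedule <- as.integer(temperature_schedule)
  M <- length(scenario$ladder)
  if (anyNA(temperature_schedule) ||
      any(temperature_schedule < 1L | temperature_schedule > M))
    stop("temperature_schedule: index outside the ladder (1..", M, ")")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start_state)) {
    p0 <- tryCatch(stationary_distribution(scenario_rate_matrix(scenario)),
                   error = function(e) rep(1 / scenario$n_states,
                                           scenario$n_states))
    start_state <- sample.int(scenario$n_states, 1L, prob = p0)
  }
  if (start_state < 1 || start_state > scenario$n_states)
    stop("start_state: unknown state index ", start_state)
  runs <- rle(temperature_schedule)
  path <- .sim_ctmc_path(scenario, runs$values, runs$lengths,
                         scenario$frame_interval, as.integer(start_state))
  path$dee <- rnorm(n_frames, scenario$emission_mean[path$state],
                    scenario$emission_sd[path$state])
  path$start_state <- as.integer(start_state)
  path
}

# Per-round "low-energy ensemble" indicator used by the energy model.
# corrected field run: all replicas low; zero field: none; artifact mode:
# affected replicas toggle between the unperturbed and the field-stabilised
# ensemble (slow two-state chain, stationary low-occupancy = artifact_mix).
.initial_low <- function(scenario) {
  M <- length(scenario$ladder)
  if (scenario$field > 0 && !scenario$artifact_mode) return(rep(TRUE, M))
  low <- rep(FALSE, M)
  if (scenario$artifact_mode) low[scenario$affected_replicas] <- TRUE
  low
}

#' Simulate a full synthetic REMD run
#'
#' Runs `length(ladder)` replicas in parallel. Between exchange attempts each
#' replica evolves the conformational jump process at its current rung;
#' every `exchange_interval` ps, neighbouring rungs attempt a Metropolis
#' swap of temperatures (alternating even/odd pairings), with the potential
#' energies drawn from the per-temperature Gaussian energy model. Swaps
#' exchange temperature indices only, so replica (R-) trajectories stay
#' continuous. Every attempt is recorded in the exchange log.
#'
#' In artifact mode the affected replicas carry the field-stabilised
#' low-energy ensemble (offset `energy$artifact_offset` below the
#' unperturbed mean) part of the time, which both distorts the energy
#' marginals and traps those replicas at the bottom of the ladder — the
#' uncorrected-initialisation artifact. See [corrected_restart()].
#'
#' @param scenario A `remd_scenario`.
#' @param n_frames Frames per replica (>= 1) at `frame_interval` spacing.
#' @param seed Integer root seed; the run is bit-reproducible given
#'   (scenario, n_frames, seed).
#' @return An object of class `"remd_run"`: list with `scenario`,
#'   `replicas` (list of per-replica data frames with columns
#'   `time`, `temp`, `energy`, `dee`, `state`), `exchange` (an
#'   `exchange_log` data frame), `n_frames`, `seed`.
#' @export
simulate_remd <- function(scenario, n_frames, seed = 1) {
  stopifnot(inherits(scenario, "remd_scenario"))
  if (n_frames < 1) stop("n_frames must be >= 1")
  n_frames <- as.integer(n_frames)
  M <- length(scenario$ladder)
  Tl <- scenario$ladder
  dt <- scenario$frame_interval
  dx <- scenario$exchange_interval
  total <- n_frames * dt
  ta <- dx * seq_len(floor(total / dx + 1e-9))
  n_rounds <- length(ta)
  en <- scenario$energy
  offset <- if (scenario$field > 0) en$artifact_offset else 0

  # --- exchange / temperature process ---------------------------------
  set.seed(.mix_seed(seed, 0L, 1L))
  temp_of <- seq_len(M)              # replica -> temperature index
  rep_at <- seq_len(M)               # temperature index -> replica
  tom <- matrix(0L, n_rounds + 1L, M)  # temp_of after 0..n_rounds rounds
  tom[1L, ] <- temp_of
  low <- .initial_low(scenario)
  lowm <- matrix(FALSE, max(n_rounds, 1L), M)
  toggling <- scenario$artifact_mode
  if (toggling) {
    aff <- scenario$affected_replicas
    k_lh <- (1 - en$artifact_mix) / en$artifact_tau   # low -> high
    k_hl <- en$artifact_mix / en$artifact_tau         # high -> low
    p_lh <- 1 - exp(-k_lh * dx)
    p_hl <- 1 - exp(-k_hl * dx)
  }
  max_att <- if (n_rounds > 0) n_rounds * ((M - 1) %/% 2 + 1L) else 0L
  log_m <- matrix(0, max_att, 6L)
  natt <- 0L
  for (j in seq_len(n_rounds)) {
    if (toggling) {
      u <- runif(length(aff))
      flip <- ifelse(low[aff], u < p_lh, u < p_hl)
      low[aff] <- xor(low[aff], flip)
    }
    lowm[j, ] <- low
    U <- en$u0 + en$slope * (Tl[temp_of] - Tl[1L]) - offset * low +
      en$sigma * rnorm(M)
    lo <- if (j %% 2L == 1L) {
      if (M >= 2L) seq(1L, M - 1L, by = 2L) else integer(0)
    } else {
      if (M >= 3L) seq(2L, M - 1L, by = 2L) else integer(0)
    }
    if (length(lo)) {
      hi <- lo + 1L
      ri <- rep_at[lo]; rj <- rep_at[hi]
      pr <- metropolis_acceptance(U[ri], U[rj], Tl[lo], Tl[hi])
      acc <- runif(length(lo)) < pr
      idx <- natt + seq_along(lo)
      log_m[idx, 1L] <- ta[j]
      log_m[idx, 2L] <- lo
      log_m[idx, 3L] <- hi
      log_m[idx, 4L] <- ri
      log_m[idx, 5L] <- rj
      log_m[idx, 6L] <- acc
      natt <- natt + length(lo)
      if (any(acc)) {
        la <- lo[acc]; ha <- hi[acc]
        ria <- ri[acc]; rja <- rj[acc]
        rep_at[la] <- rja; rep_at[ha] <- ria
        temp_of[ria] <- ha; temp_of[rja] <- la
      }
    }
    tom[j + 1L, ] <- temp_of
  }
  log_m <- log_m[seq_len(natt), , drop = FALSE]
  exchange <- data.frame(time = log_m[, 1L],
                         temp_lo = as.integer(log_m[, 2L]),
                         temp_hi = as.integer(log_m[, 3L]),
                         replica_lo = as.integer(log_m[, 4L]),
                         replica_hi = as.integer(log_m[, 5L]),
                         accepted = as.logical(log_m[, 6L]))
  class(exchange) <- c("exchange_log", "data.frame")
  attr(exchange, "n_temps") <- M
  attr(exchange, "exchange_interval") <- dx

  # --- per-frame temperature / ensemble indicator ---------------------
  frame_t <- seq_len(n_frames) * dt
  before <- findInterval(frame_t - dt * 1e-9, ta)   # attempts strictly before
  round_of <- pmin(pmax(before + 1L, 1L), max(n_rounds, 1L))
  init_low <- .initial_low(scenario)

  # --- per-replica conformational paths and emissions ------------------
  replicas <- vector("list", M)
  p0 <- tryCatch(stationary_distribution(scenario_rate_matrix(scenario)),
                 error = function(e) rep(1 / scenario$n_states,
                                         scenario$n_states))
  for (r in seq_len(M)) {
    set.seed(.mix_seed(seed, r, 2L))
    temp_fr <- tom[cbind(before + 1L, rep(r, n_frames))]
    start <- if (scenario$field > 0 || (scenario$artifact_mode &&
                                        r %in% scenario$affected_replicas)) {
      if (is.na(scenario$field_state))
        sample.int(scenario$n_states, 1L, prob = p0)
      else scenario$field_state
    } else sample.int(scenario$n_states, 1L, prob = p0)
    runs <- rle(temp_fr)
    path <- .sim_ctmc_path(scenario, runs$values, runs$lengths, dt,
                           as.integer(start))
    dee <- rnorm(n_frames, scenario$emission_mean[path$state],
                 scenario$emission_sd[path$state])
    low_fr <- if (n_rounds > 0) lowm[cbind(round_of, rep(r, n_frames))]
              else rep(init_low[r], n_frames)
    energy <- en$u0 + en$slope * (Tl[temp_fr] - Tl[1L]) -
      offset * low_fr + en$sigma * rnorm(n_frames)
    df <- data.frame(time = frame_t, temp = as.integer(temp_fr),
                     energy = energy, dee = dee, state = path$state)
    attr(df, "replica_id") <- r
    class(df) <- c("replica_traj", "data.frame")
    replicas[[r]] <- df
  }
  structure(list(scenario = scenario, replicas = replicas,
                 exchange = exchange, n_frames = n_frames, seed = seed),
            class = "remd_run")
}

#' @export
print.remd_run <- function(x, ...) {
  cat(sprintf("Synthetic REMD run: scenario '%s', %d replicas x %d frames (%g ps)\n",
              x$scenario$name, length(x$replicas), x$n_frames,
              x$n_frames * x$scenario$frame_interval))
  n_att <- nrow(x$exchange)
  if (n_att > 0)
    cat(sprintf("  exchange attempts: %d, accepted: %d (%.1f%%)\n",
                n_att, sum(x$exchange$accepted),
                100 * mean(x$exchange$accepted)))
  else cat("  no exchange attempts\n")
  invisible(x)
}
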