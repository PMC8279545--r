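#' Arrhenius temperature scaling of a transition rate
#'
#' Scales a reference rate to temperature `temperature` using an Arrhenius
#' barrier: `k(T) = k0 * exp(-Ea/R * (1/T - 1/T_ref))` with
#' `R = 0.0019872` kcal/(mol K). A zero barrier gives a
#' temperature-independent rate.
#'
#' @param base_rate Reference rate at `reference_temperature` (1/ps), >= 0.
#' @param activation_energy Arrhenius barrier Ea (kcal/mol).
#' @param temperature Target temperature (K), > 0.
#' @param reference_temperature Reference temperature (K), > 0.
#' @return Rate at `temperature` (1/ps). Vectorised over all arguments.
#' @examples
#' arrhenius_rate(0.01, 2.0, 373.45, 310.00)
#' @export
arrhenius_rate <- function(base_rate, activation_energy, temperature,
                           reference_temperature) {
  if (any(temperature <= 0) || any(reference_temperature <= 0))
    stop("arrhenius_rate: temperatures must be positive")
  if (any(base_rate < 0))
    stop("arrhenius_rate: base_rate must be non-negative")
  base_rate * exp(-activation_energy / .R_KCAL *
                    (1 / temperature - 1 / reference_temperature))
}

#' Expected Metropolis acceptance for Gaussian energy distributions
#'
#' Closed-form expectation of `min(1, exp(db * D))` where
#' `D = U_i - U_j` is Gaussian with mean `m` and standard deviation `s`,
#' and `db = beta_i - beta_j`. Used to calibrate the synthetic energy model
#' to a target average exchange acceptance.
#'
#' @keywords internal
.analytic_pair_acceptance <- function(m, s, db) {
  # E[min(1, e^{a D})], D ~ N(m, s^2), a = db > 0
  a <- db
  pnorm(m / s) +
    exp(a * m + a^2 * s^2 / 2 + pnorm(-m / s - a * s, log.p = TRUE))
}

#' Calibrate the energy-mean slope to a target exchange acceptance
#'
#' The synthetic potential-energy model is Gaussian at each temperature with
#' mean `u0 + slope * (T - T_1)` and common standard deviation `sigma`.
#' This solves for the slope such that the analytic expected Metropolis
#' acceptance, averaged over all neighbour pairs of the ladder, equals
#' `target` (all pairs are attempted equally often under alternating
#' even/odd pairing).
#'
#' @param ladder A `temperature_ladder`.
#' @param sigma Common energy standard deviation (kcal/mol), > 0.
#' @param target Target mean neighbour acceptance in (0, 1).
#' @return Slope in kcal/(mol K).
#' @export
calibrate_energy_slope <- function(ladder, sigma, target = 0.20) {
  ladder <- temperature_ladder(ladder)
  if (length(ladder) < 2)
    stop("acceptance calibration needs at least 2 rungs")
  if (sigma <= 0) stop("energy_sds: sigma must be > 0")
  if (target <= 0 || target >= 1) stop("target acceptance must be in (0,1)")
  ti <- ladder[-length(ladder)]
  tj <- ladder[-1]
  db <- (1 / ti - 1 / tj) / .R_KCAL
  s <- sqrt(2) * sigma
  mean_acc <- function(slope) {
    mean(.analytic_pair_acceptance(-slope * (tj - ti), s, db))
  }
  if (mean_acc(0) < target)
    stop("target acceptance unreachable: even a flat energy profile gives less")
  uniroot(function(c) mean_acc(c) - target, c(0, 1e4), tol = 1e-12)$root
}

.scenario_fields <- c("name", "field", "ladder", "ref_temp", "n_states",
                      "base_rates", "activation_energies",
                      "emission_mean", "emission_sd", "energy",
                      "field_state", "artifact_mode", "affected_replicas",
                      "exchange_interval", "frame_interval", "production_ns")

#' Validate a synthetic REMD scenario
#' @param x A `remd_scenario`.
#' @return `x`, invisibly, after validation; errors name the offending field.
#' @keywords internal
validate_scenario <- function(x) {
  missing <- setdiff(.scenario_fields, names(x))
  if (length(missing))
    stop("scenario: missing field(s): ", paste(missing, collapse = ", "))
  temperature_ladder(x$ladder)
  n <- x$n_states
  if (!is.numeric(n) || n < 1 || n != round(n))
    stop("scenario field 'n_states': must be a positive integer")
  for (f in c("base_rates", "activation_energies")) {
    m <- x[[f]]
    if (!is.matrix(m) || !all(dim(m) == c(n, n)))
      stop("scenario field '", f, "': must be an ", n, "x", n, " matrix")
  }
  if (any(x$base_rates < 0))
    stop("scenario field 'base_rates': rates must be >= 0")
  if (length(x$emission_mean) != n)
    stop("scenario field 'emission_mean': length must equal n_states")
  if (length(x$emission_sd) != n || any(x$emission_sd <= 0))
    stop("scenario field 'emission_sd': need ", n, " values, all > 0")
  en <- x$energy
  for (f in c("u0", "slope", "sigma"))
    if (!is.numeric(en[[f]]) || length(en[[f]]) != 1)
      stop("scenario field 'energy$", f, "': must be a single number")
  if (en$sigma <= 0) stop("scenario field 'energy$sigma': must be > 0")
  if (!is.na(x$field_state) &&
      (x$field_state < 1 || x$field_state > n))
    stop("scenario field 'field_state': state index out of range")
  if (x$exchange_interval <= 0)
    stop("scenario field 'exchange_interval': must be > 0")
  if (x$frame_interval <= 0)
    stop("scenario field 'frame_interval': must be > 0")
  if (x$production_ns <= 0)
    stop("scenario field 'production_ns': must be > 0")
  if (isTRUE(x$artifact_mode)) {
    if (is.na(x$field_state))
      stop("scenario field 'artifact_mode': requires a field_state")
    if (length(x$affected_replicas) < 1 ||
        any(x$affected_replicas < 1 | x$affected_replicas > length(x$ladder)))
      stop("scenario field 'affected_replicas': replica index out of range")
  }
  invisible(x)
}

#' Build a synthetic REMD scenario
#'
#' A scenario bundles everything the generator needs: the temperature ladder,
#' the N-state Markov jump network with per-transition Arrhenius barriers,
#' Gaussian emission parameters for the side-chain end-to-end distance
#' `d_ee`, the Gaussian per-temperature potential-energy model, the
#' electric-field label, the exchange/frame intervals, and the
#' uncorrected-initialisation ("artifact") switch.
#'
#' Three scenarios ship with the package and resolve by name without a file:
#' \describe{
#'   \item{`"zero_field"`}{3 metastable states (compact / intermediate /
#'     extended at mean d_ee 5.0 / 8.9 / 11.0 A), stationary populations
#'     0.38 / 0.42 / 0.20, 12-replica ladder 310.00-373.45 K, 126 ns
#'     nominal production per replica.}
#'   \item{`"field_30"`}{E = 30 kcal/(mol A e): a single dominant extended
#'     state (stationary probability 0.995) with emission mean 8.9 A.}
#'   \item{`"field_45"`}{E = 45 kcal/(mol A e): as above with emission mean
#'     10.0 A.}
#' }
#'
#' If the energy-model slope is left `NULL` in the file it is calibrated
#' analytically (see [calibrate_energy_slope()]) so the mean neighbour
#' exchange acceptance equals `energy$target_acceptance` (default 20%).
#'
#' @param config A packaged scenario name (`"zero_field"`, `"field_30"`,
#'   `"field_45"`), a path to a YAML scenario file, or a list with the same
#'   structure as the YAML schema.
#' @param ... Named scenario fields overriding the file values, e.g.
#'   `artifact_mode = TRUE`.
#' @return A validated object of class `"remd_scenario"`.
#' @examples
#' sc <- build_scenario("zero_field")
#' sc$ladder
#' @export
build_scenario <- function(config, ...) {
  if (is.character(config) && length(config) == 1 && !file.exists(config)) {
    path <- system.file("extdata", "scenarios", paste0(config, ".yaml"),
                        package = "remdkin")
    if (!nzchar(path))
      stop("unknown scenario '", config, "' (not a packaged name or a file)")
    config <- path
  }
  raw <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(raw)) stop("scenario config must parse to a list")
  over <- list(...)
  raw[names(over)] <- over

  n <- length(raw$states$emission_mean)
  if (is.null(n) || n < 1)
    stop("scenario field 'states$emission_mean': at least one state required")
  K0 <- matrix(0, n, n)
  Ea <- matrix(0, n, n)
  for (r in raw$rates) {
    if (is.null(r$from) || is.null(r$to) || is.null(r$rate))
      stop("scenario field 'rates': each entry needs from, to, rate")
    if (r$from < 1 || r$from > n || r$to < 1 || r$to > n || r$from == r$to)
      stop("scenario field 'rates': bad state pair (", r$from, ",", r$to, ")")
    K0[r$to, r$from] <- r$rate            # k_nm: column m -> row n
    Ea[r$to, r$from] <- if (is.null(r$ea)) 0 else r$ea
  }
  en <- raw$energy
  defaults <- list(u0 = 0, slope = NULL, sigma = 50,
                   target_acceptance = 0.2, artifact_offset = 300,
                   artifact_mix = 0.35, artifact_tau = 100)
  for (f in names(defaults)) if (is.null(en[[f]])) en[[f]] <- defaults[[f]]

  sc <- structure(list(
    name = if (is.null(raw$name)) "custom" else raw$name,
    field = if (is.null(raw$field)) 0 else raw$field,
    ladder = temperature_ladder(raw$ladder),
    ref_temp = if (is.null(raw$ref_temp)) raw$ladder[[1]] else raw$ref_temp,
    n_states = n,
    base_rates = K0,
    activation_energies = Ea,
    emission_mean = as.numeric(raw$states$emission_mean),
    emission_sd = as.numeric(raw$states$emission_sd),
    energy = en,
    field_state = if (is.null(raw$field_state)) NA_integer_
                  else as.integer(raw$field_state),
    artifact_mode = isTRUE(raw$artifact_mode),
    affected_replicas = if (is.null(raw$affected_replicas)) c(1L, 2L)
                        else as.integer(raw$affected_replicas),
    production_ns = if (is.null(raw$production_ns)) 100 else raw$production_ns,
    exchange_interval = if (is.null(raw$exchange_interval)) 1
                        else raw$exchange_interval,
    frame_interval = if (is.null(raw$frame_interval)) 1
                     else raw$frame_interval
  ), class = "remd_scenario")
  if (is.null(sc$energy$slope))
    sc$energy$slope <- if (length(sc$ladder) < 2) 0 else
      calibrate_energy_slope(sc$ladder, sc$energy$sigma,
                             sc$energy$target_acceptance)
  validate_scenario(sc)
  sc
}

#' Temperature-dependent rate matrix of a scenario
#'
#' @param scenario A `remd_scenario`.
#' @param temperature Temperature (K) at which to evaluate the rates.
#' @return The N x N rate matrix K with `K[n, m]` the m -> n rate (1/ps)
#'   and diagonal set so columns sum to zero.
#' @export
scenario_rate_matrix <- function(scenario, temperature = scenario$ref_temp) {
  K <- arrhenius_rate(scenario$base_rates, scenario$activation_energies,
                      temperature, scenario$ref_temp)
  diag(K) <- 0
  diag(K) <- -colSums(K)
  K
}

#' Mean energy of the scenario's Gaussian potential-energy model
#' @keywords internal
.energy_mean <- function(scenario, temp_index) {
  scenario$energy$u0 +
    scenario$energy$slope * (scenario$ladder[temp_index] - scenario$ladder[1])
}

#' Summarise a scenario
#'
#' Reports the run bookkeeping (replica count, ladder range, nominal
#' per-replica production time and the implied total simulation time) and
#' the state network (emission means and stationary populations of the
#' generator at the reference temperature).
#'
#' @param object A `remd_scenario`.
#' @param ... Unused.
#' @return A list of class `"scenario_summary"` with elements
#'   `name`, `field`, `n_replicas`, `t_min`, `t_max`, `production_ns`,
#'   `total_time_us`, `n_states`, `stationary`.
#' @export
summary.remd_scenario <- function(object, ...) {
  M <- length(object$ladder)
  p0 <- tryCatch(stationary_distribution(scenario_rate_matrix(object)),
                 error = function(e) rep(NA_real_, object$n_states))
  structure(list(
    name = object$name, field = object$field, n_replicas = M,
    t_min = min(object$ladder), t_max = max(object$ladder),
    production_ns = object$production_ns,
    total_time_us = object$production_ns * M / 1000,
    n_states = object$n_states,
    emission_mean = object$emission_mean,
    stationary = as.numeric(p0)
  ), class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf("REMD scenario '%s'  (E = %g kcal/(mol A e))\n", x$name, x$field))
  cat(sprintf("  %d replicas, %.2f-%.2f K\n", x$n_replicas, x$t_min, x$t_max))
  cat(sprintf("  production: %g ns/replica, total %.4g us\n",
              x$production_ns, x$total_time_us))
  cat(sprintf("  %d state(s); d_ee means: %s A\n", x$n_states,
              paste(format(x$emission_mean), collapse = ", ")))
  if (!anyNA(x$stationary))
    cat(sprintf("  stationary populations: %s\n",
                paste(sprintf("%.3f", x$stationary), collapse = ", ")))
  invisible(x)
}

#' @export
print.remd_scenario <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' Restart a scenario with corrected initial conditions
#'
#' In an uncorrected ("artifact-mode") run, only a subset of replicas carries
#' the field-stabilised low-energy conformational ensemble, which distorts
#' the potential-energy distributions. The corrected restart initialises all
#' replicas in the low-energy ensemble, after which every temperature's
#' energy marginal is a single Gaussian again.
#'
#' @param scenario A `remd_scenario` in artifact mode.
#' @param flagged_replicas Optional integer vector of replicas flagged by the
#'   energy diagnostics; recorded on the result. All replicas are corrected
#'   regardless (the correction applies the low-energy ensemble globally).
#' @return The corrected scenario (`artifact_mode = FALSE`). Calling this on
#'   a scenario that is not in artifact mode is a no-op with a warning.
#' @export
corrected_restart <- function(scenario, flagged_replicas = NULL) {
  stopifnot(inherits(scenario, "remd_scenario"))
  if (!isTRUE(scenario$artifact_mode)) {
    warning("scenario is not in artifact mode; nothing to correct")
    return(scenario)
  }
  scenario$artifact_mode <- FALSE
  attr(scenario, "corrected_from_flags") <- flagged_replicas
  scenario
}
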