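#' Gas constant in kcal/(mol K)
#'
#' Used throughout for Boltzmann factors and Arrhenius rates.
#' @keywords internal
.R_KCAL <- 0.0019872

#' Construct and validate a temperature ladder
#'
#' A temperature ladder is the ordered set of absolute temperatures at which
#' REMD replicas run: strictly increasing, positive values. A single-rung
#' ladder is allowed as a degenerate case (plain constant-temperature
#' dynamics, no exchange).
#'
#' @param temperatures Numeric vector of absolute temperatures in Kelvin.
#' @return A numeric vector of class `"temperature_ladder"`.
#' @examples
#' temperature_ladder(c(300, 310, 320.5))
#' @export
temperature_ladder <- function(temperatures) {
  if (!is.numeric(temperatures) || length(temperatures) < 1)
    stop("ladder: need a numeric vector of at least 1 temperature")
  if (anyNA(temperatures) || any(temperatures <= 0))
    stop("ladder: all temperatures must be positive and non-missing")
  if (any(diff(temperatures) <= 0))
    stop("ladder: temperatures must be strictly increasing")
  structure(as.numeric(temperatures), class = "temperature_ladder")
}

#' The 12-replica FF peptide temperature ladder
#'
#' The ladder used by the packaged scenarios: 12 replicas spanning
#' 310.00-373.45 K, spaced according to an optimised exchange protocol
#' for a small solvated dipeptide system.
#'
#' @return A `temperature_ladder` of length 12.
#' @export
ff_ladder <- function() {
  temperature_ladder(c(310.00, 315.38, 320.82, 326.35, 331.96, 337.64,
                       343.41, 349.26, 355.19, 361.20, 367.30, 373.45))
}

#' Geometrically spaced temperature ladder
#'
#' Simple utility producing temperatures in geometric progression between
#' two endpoints, the textbook spacing for constant-heat-capacity systems.
#'
#' @param t_min,t_max Endpoint temperatures (K), `t_min < t_max`.
#' @param n Number of rungs (>= 2).
#' @return A `temperature_ladder` of length `n`.
#' @export
geometric_ladder <- function(t_min, t_max, n) {
  if (n < 2) stop("ladder: need at least 2 rungs")
  if (t_min <= 0 || t_max <= t_min)
    stop("ladder: require 0 < t_min < t_max")
  temperature_ladder(t_min * (t_max / t_min)^((seq_len(n) - 1) / (n - 1)))
}
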