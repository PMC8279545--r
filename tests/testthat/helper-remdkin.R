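# Shared fixtures, built in code. The large zero-field reference run is
# generated once per test session and reused by the state-count, population
# and propagator checks.

.remdkin_cache <- new.env(parent = emptyenv())

big_zero_run <- function() {
  if (is.null(.remdkin_cache$run))
    .remdkin_cache$run <- simulate_remd(build_scenario("zero_field"),
                                        n_frames = 1e5, seed = 1)
  .remdkin_cache$run
}

big_zero_assignments <- function() {
  if (is.null(.remdkin_cache$asg)) {
    run <- big_zero_run()
    dee <- unlist(lapply(run$replicas, `[[`, "dee"))
    cores <- detect_cores(dee)
    .remdkin_cache$cores <- cores
    .remdkin_cache$asg <- lapply(run$replicas,
                                 function(d) assign_tba(d$dee, cores))
  }
  .remdkin_cache$asg
}

big_zero_cores <- function() {
  big_zero_assignments()
  .remdkin_cache$cores
}

big_zero_report <- function() {
  if (is.null(.remdkin_cache$report))
    .remdkin_cache$report <- run_remd_pipeline(big_zero_run())
  .remdkin_cache$report
}

field_run <- function(name) {
  key <- paste0("run_", name)
  if (is.null(.remdkin_cache[[key]]))
    .remdkin_cache[[key]] <- simulate_remd(build_scenario(name),
                                           n_frames = 8400, seed = 1)
  .remdkin_cache[[key]]
}

# single-rung scenario helper for constant-temperature chains
single_rung_scenario <- function(means, sds, rates) {
  build_scenario(list(
    name = "single_rung", ladder = 310,
    states = list(emission_mean = means, emission_sd = sds),
    rates = rates,
    energy = list(u0 = 0, sigma = 10)))
}

make_cores <- function(lower, upper) {
  df <- data.frame(state = seq_along(lower), lower = lower, upper = upper)
  class(df) <- c("core_def", "data.frame")
  df
}

# Brute-force reference implementation of transition-based assignment:
# frame-by-frame search for the nearest preceding (else following) core
# visit within the same segment.
tba_reference <- function(x, cores, segments = rep(1L, length(x))) {
  raw <- integer(length(x))
  for (s in seq_len(nrow(cores)))
    raw[x >= cores$lower[s] & x <= cores$upper[s]] <- cores$state[s]
  out <- integer(length(x))
  for (i in seq_along(x)) {
    if (raw[i] != 0L) { out[i] <- raw[i]; next }
    j <- i - 1L
    while (j >= 1L && segments[j] == segments[i] && raw[j] == 0L) j <- j - 1L
    if (j >= 1L && segments[j] == segments[i]) { out[i] <- raw[j]; next }
    j <- i + 1L
    while (j <= length(x) && segments[j] == segments[i] && raw[j] == 0L)
      j <- j + 1L
    if (j <= length(x) && segments[j] == segments[i]) out[i] <- raw[j]
    else stop("reference: unassignable segment")
  }
  out
}

# minimal diphenylalanine-like PDB text, two C-zeta atoms `dee` apart
write_test_pdb <- function(path, dee_values) {
  lines <- character(0)
  for (m in seq_along(dee_values)) {
    lines <- c(lines, sprintf("MODEL %8d", m),
      "ATOM      1  CZ  PHE A   1       0.000   0.000   0.000  1.00  0.00           C",
      "ATOM      2  CA  PHE A   1       1.000   2.000   2.000  1.00  0.00           C",
      sprintf("ATOM      3  CZ  PHE A   2    %8.3f   0.000   0.000  1.00  0.00           C",
              dee_values[m]),
      "ENDMDL")
  }
  writeLines(lines, path)
  path
}
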