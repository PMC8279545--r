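test_that("demux with an empty log is the identity", {
  run <- simulate_remd(build_scenario("zero_field", exchange_interval = 1e9),
                       200, seed = 1)
  tt <- demux(run)
  for (k in c(1, 7, 12)) {
    expect_equal(tt[[k]]$dee, run$replicas[[k]]$dee)
    expect_equal(unique(tt[[k]]$source_replica), k)
    expect_length(attr(tt[[k]], "boundaries"), 0)
  }
})

test_that("a single accepted swap splices two replicas at the swap time", {
  reps <- lapply(1:2, function(r) {
    df <- data.frame(time = as.numeric(1:10), temp = r,
                     energy = 0, dee = r * 10 + 1:10)
    attr(df, "replica_id") <- r
    df
  })
  log <- data.frame(time = 5, temp_lo = 1L, temp_hi = 2L,
                    replica_lo = 1L, replica_hi = 2L, accepted = TRUE)
  class(log) <- c("exchange_log", "data.frame")
  attr(log, "n_temps") <- 2L
  tt <- demux(reps, log)
  expect_equal(tt[[1]]$dee, c(11:15, 26:30))
  expect_equal(tt[[1]]$source_replica, rep(c(1L, 2L), each = 5))
  expect_equal(attr(tt[[1]], "boundaries"), 5)
  expect_equal(attr(tt[[1]], "segments"), rep(c(1L, 2L), each = 5))
})

test_that("remux is the exact inverse of demux on simulated logs", {
  for (seed in c(21, 22)) {
    run <- simulate_remd(build_scenario("zero_field"), 1000, seed = seed)
    back <- remux(demux(run), run$exchange)
    for (r in c(1, 5, 12)) {
      expect_equal(back[[r]]$dee, run$replicas[[r]]$dee)
      expect_equal(back[[r]]$energy, run$replicas[[r]]$energy)
      expect_identical(back[[r]]$state, run$replicas[[r]]$state)
      expect_identical(back[[r]]$temp, run$replicas[[r]]$temp)
    }
  }
})

test_that("acceptance rates count attempts and flag undefined pairs", {
  log <- data.frame(time = as.numeric(1:50), temp_lo = 1L, temp_hi = 2L,
                    replica_lo = NA_integer_, replica_hi = NA_integer_,
                    accepted = rep(c(TRUE, rep(FALSE, 4)), 10))
  class(log) <- c("exchange_log", "data.frame")
  attr(log, "n_temps") <- 4L
  ar <- acceptance_rate(log)
  expect_equal(ar$overall, 0.20)
  expect_equal(ar$by_pair$rate[1], 0.20)
  expect_true(all(is.na(ar$by_pair$rate[2:3])))
  expect_error(acceptance_rate(log, pair = 2), "no attempts")

  log$accepted <- TRUE
  expect_equal(acceptance_rate(log)$overall, 1.0)
  empty <- log[0, ]
  class(empty) <- c("exchange_log", "data.frame")
  attr(empty, "n_temps") <- 4L
  expect_error(acceptance_rate(empty), "no exchange attempts")
})

test_that("occupancy report covers the perfect and frozen extremes", {
  M <- 12
  cyc <- lapply(1:M, function(r) {
    data.frame(time = as.numeric(1:(12 * 10)),
               temp = rep(((r - 1 + 0:11) %% 12) + 1L, each = 10))
  })
  oc <- occupancy(cyc)
  expect_true(oc$pass)
  expect_equal(oc$deviation, 0)
  expect_true(all(abs(oc$occupancy - 1 / 12) < 1e-12))

  frozen <- lapply(1:M, function(r)
    data.frame(time = as.numeric(1:20), temp = rep(r, 20)))
  of <- occupancy(frozen)
  expect_false(of$pass)
  expect_equal(of$deviation, 1 - 1 / 12)
})

test_that("the Gaussianity check separates single Gaussians from mixtures", {
  set.seed(101)
  chk <- energy_distribution_check(rnorm(10000, -11000, 50))
  expect_false(chk$bimodal)
  mix <- c(rnorm(5000, -11000, 50), rnorm(5000, -11300, 50))
  chk2 <- energy_distribution_check(mix)
  expect_true(chk2$bimodal)
  expect_gt(chk2$separation, 2)
  expect_error(energy_distribution_check(rnorm(10)), "too short")
  expect_error(energy_distribution_check(rep(1, 200)), "degenerate")
})

test_that("the uncorrected field run fails the energy check and its corrected restart passes", {
  sc_art <- build_scenario("field_30", artifact_mode = TRUE)
  run_art <- simulate_remd(sc_art, 6000, seed = 1)
  chk_art <- energy_artifact_report(run_art, by = "temperature")
  expect_false(chk_art$pass)
  # the distortion shows up at the bottom of the ladder, where the
  # affected replicas are trapped
  expect_true(any(chk_art$flagged %in% 1:3))
  expect_false(energy_artifact_report(run_art, by = "replica")$pass)

  sc_fix <- corrected_restart(sc_art, flagged_replicas = chk_art$flagged)
  run_fix <- simulate_remd(sc_fix, 6000, seed = 2)
  chk_fix <- energy_artifact_report(run_fix, by = "temperature")
  expect_true(chk_fix$pass)
  expect_true(energy_artifact_report(run_fix, by = "replica")$pass)
  # healthy zero-field runs pass both views as well
  run0 <- simulate_remd(build_scenario("zero_field"), 6000, seed = 3)
  expect_true(energy_artifact_report(run0, by = "temperature")$pass)
  expect_true(energy_artifact_report(run0, by = "replica")$pass)
})
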