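seq_of <- function(x, segments = NULL) {
  structure(as.integer(x), segments = segments, class = "state_seq")
}

test_that("transition counting respects commitment and segment boundaries", {
  ct <- count_transitions(seq_of(rep(1L, 1000)), dt = 1, n_states = 1)
  expect_equal(sum(ct$counts), 0)
  expect_equal(ct$dwell, 1000)

  ct2 <- count_transitions(seq_of(rep(c(1L, 2L), each = 500)), dt = 1)
  expect_equal(ct2$counts[2, 1], 1)
  expect_equal(ct2$counts[1, 2], 0)
  expect_equal(ct2$dwell, c(500, 500))

  # the A -> B change coincides with a segment boundary: nothing counted
  ct3 <- count_transitions(seq_of(rep(c(1L, 2L), each = 500),
                                  segments = rep(c(1L, 2L), each = 500)))
  expect_equal(sum(ct3$counts), 0)
  expect_error(count_transitions(list()), "no state sequences")
})

test_that("the DTC estimator divides counts by dwell times", {
  C <- matrix(c(0, 10, 0, 0), 2, 2)   # 10 transitions 1 -> 2
  K <- estimate_rates(C, c(1000, 500))
  expect_equal(K[2, 1], 0.01)
  expect_equal(colSums(K), c(0, 0))

  expect_warning(K0 <- estimate_rates(matrix(0, 2, 2), c(10, 10)),
                 "no transitions")
  expect_true(all(K0 == 0))
  expect_warning(Ku <- estimate_rates(matrix(0, 2, 2), c(10, 0)),
                 "never visited")
  expect_true(all(is.na(Ku[, 2])))
})

test_that("stationary populations solve K p = 0", {
  Ksym <- matrix(c(-1, 1, 1, -1), 2, 2)
  expect_equal(stationary_distribution(Ksym), c(0.5, 0.5))
  # k (2->1) = 1, k (1->2) = 2: null space solved by hand -> (1/3, 2/3)
  K <- matrix(c(-2, 2, 1, -1), 2, 2)
  expect_equal(stationary_distribution(K), c(1, 2) / 3, tolerance = 1e-12)
  # packaged generator
  K0 <- scenario_rate_matrix(build_scenario("zero_field"))
  expect_equal(stationary_distribution(K0), c(0.38, 0.42, 0.20),
               tolerance = 1e-10)
  # disconnected chain names its components
  Kd <- matrix(0, 3, 3)
  Kd[2, 1] <- 1; Kd[1, 2] <- 1
  diag(Kd) <- -colSums(Kd)
  expect_error(stationary_distribution(Kd), "disconnected.*\\{1,2\\}.*\\{3\\}")
})

test_that("propagators form a column-stochastic semigroup", {
  K <- scenario_rate_matrix(build_scenario("zero_field"))
  expect_equal(propagator(K, 0), diag(3))
  P1 <- propagator(K, 1)
  expect_equal(colSums(P1), rep(1, 3), tolerance = 1e-12)
  expect_equal(P1 %*% propagator(K, 2), propagator(K, 3),
               tolerance = 1e-10)
  # long-lag limit: every column approaches the stationary vector
  p0 <- stationary_distribution(K)
  expect_equal(propagator(K, 1e4), matrix(p0, 3, 3), tolerance = 1e-8)
  expect_error(propagator(K, -1), ">= 0")
  # eigenvalues of a detailed-balance K have non-positive real parts
  expect_true(all(Re(eigen(K)$values) < 1e-12))
})

test_that("empirical propagators match exp(K lag) on simulated chains", {
  expect_equal(empirical_propagator(seq_of(rep(1L, 100)), lag = 1),
               matrix(1, 1, 1))
  P <- empirical_propagator(seq_of(rep(c(1L, 2L), 50)), lag = 1)
  expect_equal(P[2, 1], 1)
  expect_equal(P[1, 2], 1)

  sc <- single_rung_scenario(c(5, 9), c(0.5, 0.5),
                             list(list(from = 1, to = 2, rate = 0.02),
                                  list(from = 2, to = 1, rate = 0.04)))
  p <- simulate_state_path(sc, rep(1L, 2e5), 2e5, seed = 71)
  Pe <- empirical_propagator(seq_of(p$state), lag = 5)
  Pa <- propagator(scenario_rate_matrix(sc), 5)
  # 3 sigma multinomial error per column
  for (m in 1:2) {
    n_m <- sum(p$state[1:(2e5 - 5)] == m)
    tol <- 3 * sqrt(Pa[1, m] * (1 - Pa[1, m]) / n_m)
    expect_lt(abs(Pe[1, m] - Pa[1, m]), tol + 3e-3)
  }
  expect_error(empirical_propagator(seq_of(1:3), lag = 0.5), "multiple")
})

test_that("block errors vanish for periodic data and shrink with length", {
  per <- seq_of(rep(c(1L, 1L, 2L, 2L), 250))
  be <- block_errors(per, B = 5)
  expect_equal(be$se[2, 1], 0)
  expect_equal(be$se[1, 2], 0)
  expect_error(block_errors(per, B = 1), "at least 2")

  sc <- single_rung_scenario(c(5, 9), c(0.5, 0.5),
                             list(list(from = 1, to = 2, rate = 0.004),
                                  list(from = 2, to = 1, rate = 0.002)))
  ratios <- numeric(0)
  for (seed in c(11, 12, 13)) {
    p <- simulate_state_path(sc, rep(1L, 1e6), 1e6, seed = seed)
    s_full <- seq_of(p$state)
    s_half <- seq_of(p$state[1:5e5])
    b_full <- block_errors(s_full, 5)
    b_half <- block_errors(s_half, 5)
    ratios <- c(ratios, b_full$se[2, 1] / b_half$se[2, 1],
                b_full$se[1, 2] / b_half$se[1, 2])
  }
  # SEM should scale roughly as 1/sqrt(length); with B = 5 the ratio is
  # noisy, so compare the mean over rates and replicates to the band
  expect_gt(mean(ratios), 0.6)
  expect_lt(mean(ratios), 0.85)

  # a block that never visits a state is excluded with a warning
  s <- seq_of(c(rep(1L, 800), rep(c(2L, 1L), 100)))
  expect_warning(bex <- block_errors(s, B = 5), "excluded")
  expect_lt(min(bex$used), 5)
})

test_that("dtc recovers generator rates within 3 block SEMs", {
  sc <- single_rung_scenario(c(5, 9), c(0.5, 0.5),
                             list(list(from = 2, to = 1, rate = 0.002),
                                  list(from = 1, to = 2, rate = 0.004)))
  ps <- lapply(c(11, 12, 13), function(sd)
    seq_of(simulate_state_path(sc, rep(1L, 4e5), 4e5, seed = sd)$state))
  # 10 blocks: with only 5 the SEM estimate itself is too noisy (4 df) to
  # define a dependable 3-sigma band
  fit <- dtc(ps, dt = 1, blocks = 10)
  expect_lt(abs(fit$K[2, 1] - 0.004), 3 * fit$se[2, 1])
  expect_lt(abs(fit$K[1, 2] - 0.002), 3 * fit$se[1, 2])
  # stationary populations agree with empirical occupancy within
  # multinomial-scale error
  occ1 <- mean(unlist(ps) == 1)
  expect_lt(abs(fit$p0[1] - occ1), 0.01)
})

test_that("the geometric-mean check is exact in its degenerate cases", {
  P <- propagator(scenario_rate_matrix(build_scenario("zero_field")), 5)
  chk <- check_geometric_mean_relation(list(P, P, P), rep(1 / 3, 3), P)
  expect_lt(chk$deviation, 1e-12)
  # weights concentrated on one temperature reproduce that propagator
  Q <- propagator(scenario_rate_matrix(build_scenario("zero_field"),
                                       temperature = 373.45), 5)
  chk2 <- check_geometric_mean_relation(list(P, Q), c(0, 1), Q)
  expect_lt(chk2$deviation, 1e-12)
  expect_error(check_geometric_mean_relation(list(P), 2, P), "sum to 1")
})

test_that("the dtc object supports the standard model-methods contract", {
  sc <- single_rung_scenario(c(5, 9), c(0.5, 0.5),
                             list(list(from = 1, to = 2, rate = 0.02),
                                  list(from = 2, to = 1, rate = 0.04)))
  p <- simulate_state_path(sc, rep(1L, 5e4), 5e4, seed = 3)
  fit <- dtc(seq_of(p$state), blocks = 5)
  expect_s3_class(fit, "dtc")
  expect_named(coef(fit), c("k[2<-1]", "k[1<-2]"))
  expect_equal(unname(diag(vcov(fit))), unname(fit$se[c(2, 3)]^2))
  expect_equal(predict(fit, lag = 2), propagator(fit$K, 2))
  pp <- predict(fit, lag = 1e5, type = "populations")
  expect_equal(pp, fit$p0, tolerance = 1e-6)
  sim <- simulate(fit, nsim = 2, seed = 4, n_frames = 500)
  expect_length(sim, 2)
  expect_length(sim[[1]], 500)
  out <- capture.output({ print(fit); print(summary(fit)) })
  expect_true(any(grepl("Stationary populations", out)))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("network reports list populated states and weighted edges", {
  fit_k <- scenario_rate_matrix(build_scenario("zero_field"))
  net <- kinetic_network_report(fit_k)
  expect_equal(nrow(net$nodes), 3)
  expect_lte(nrow(net$edges), 6)
  expect_equal(sum(net$nodes$population_pct), 100, tolerance = 1e-9)
  expect_equal(max(net$edges$weight), 1)

  net1 <- kinetic_network_report(matrix(0, 1, 1), p0 = 1)
  expect_equal(nrow(net1$nodes), 1)
  expect_equal(nrow(net1$edges), 0)
})
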