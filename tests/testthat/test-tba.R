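core_ab <- make_cores(c(0, 10), c(1, 11))

test_that("TBA follows the stated inheritance rules", {
  # all frames inside core A
  expect_equal(as.integer(assign_tba(c(0.5, 0.2, 0.9), core_ab)),
               c(1L, 1L, 1L))
  # A-core, buffer, buffer, B-core, buffer -> A A A B B
  expect_equal(as.integer(assign_tba(c(0.5, 5, 5, 10.5, 5), core_ab)),
               c(1L, 1L, 1L, 2L, 2L))
  # buffer, A-core, buffer, A-core -> all A, zero transitions
  s <- assign_tba(c(5, 0.5, 5, 0.5), core_ab)
  expect_equal(as.integer(s), rep(1L, 4))
  expect_equal(sum(count_transitions(s)$counts), 0)
})

test_that("leading buffer frames follow the configured convention", {
  x <- c(5, 5, 0.5, 5, 10.5)
  expect_equal(as.integer(assign_tba(x, core_ab, leading = "inherit")),
               c(1L, 1L, 1L, 1L, 2L))
  dropped <- assign_tba(x, core_ab, leading = "drop")
  expect_true(all(is.na(dropped[1:2])))
  expect_equal(as.integer(dropped[3:5]), c(1L, 1L, 2L))
})

test_that("inheritance and transitions never cross segment boundaries", {
  x <- c(0.5, 5, 5, 10.5)
  seg <- c(1L, 1L, 2L, 2L)
  s <- assign_tba(x, core_ab, segments = seg)
  # frame 3 opens a new segment: it must inherit forward from B, not
  # backward from A
  expect_equal(as.integer(s), c(1L, 1L, 2L, 2L))
  expect_equal(sum(count_transitions(s)$counts), 0)  # change sits on boundary
  # a segment that never touches a core is an error naming it
  expect_error(assign_tba(c(0.5, 5, 5), core_ab,
                          segments = c(1L, 2L, 2L)),
               "segment.*never touch")
})

test_that("a series entirely inside cores equals nearest-core assignment", {
  set.seed(40)
  x <- c(runif(50, 0, 1), runif(50, 10, 11))[sample(100)]
  s <- assign_tba(x, core_ab)
  expect_equal(as.integer(s), ifelse(x <= 1, 1L, 2L))
})

test_that("vectorised TBA agrees exactly with a brute-force reference", {
  cores <- make_cores(c(0, 4, 8), c(1, 5, 9))
  for (seed in c(51, 52, 53)) {
    set.seed(seed)
    n <- 400
    x <- runif(n, -0.5, 9.5)
    seg <- cumsum(c(1L, as.integer(runif(n - 1) < 0.05)))
    ref <- tryCatch(tba_reference(x, cores, seg), error = function(e) NULL)
    if (is.null(ref)) next
    expect_equal(as.integer(assign_tba(x, cores, segments = seg)), ref)
  }
})

test_that("labels recover generator truth with tight cores", {
  sc <- single_rung_scenario(
    c(5, 8.9, 11), c(0.5, 0.5, 0.5),
    list(list(from = 1, to = 2, rate = 0.012),
         list(from = 2, to = 1, rate = 0.010857142857142857),
         list(from = 2, to = 3, rate = 0.008),
         list(from = 3, to = 2, rate = 0.0168)))
  p <- simulate_state_path(sc, rep(1L, 5e4), 5e4, seed = 7)
  cores <- make_cores(c(4.5, 8.4, 10.6), c(5.5, 9.4, 11.5))
  asg <- assign_tba(p$dee, cores)
  expect_gte(mean(as.integer(asg) == p$state), 0.99)
})

test_that("label agreement degrades monotonically with emission overlap", {
  agree <- vapply(c(0.3, 0.6, 1.2), function(s) {
    sc <- single_rung_scenario(
      c(5, 8.9, 11), rep(s, 3),
      list(list(from = 1, to = 2, rate = 0.012),
           list(from = 2, to = 1, rate = 0.010857142857142857),
           list(from = 2, to = 3, rate = 0.008),
           list(from = 3, to = 2, rate = 0.0168)))
    p <- simulate_state_path(sc, rep(1L, 2e4), 2e4, seed = 13)
    cores <- make_cores(c(5, 8.9, 11) - 0.5, c(5, 8.9, 11) + 0.5)
    mean(as.integer(assign_tba(p$dee, cores)) == p$state)
  }, numeric(1))
  expect_true(all(diff(agree) <= 0))
})

test_that("projected assignments equal the demultiplexed replica labels", {
  run <- simulate_remd(build_scenario("zero_field"), 800, seed = 61)
  cores <- make_cores(c(4.5, 8.4, 10.6), c(5.5, 9.4, 11.5))
  asg <- lapply(run$replicas, function(d) assign_tba(d$dee, cores))
  proj <- project_replica_assignments(asg, run$exchange,
                                      run$replicas[[1]]$time)
  tt <- demux(run)
  for (k in c(1, 6, 12)) {
    src <- tt[[k]]$source_replica
    manual <- vapply(seq_along(src), function(i)
      as.integer(asg[[src[i]]][i]), integer(1))
    expect_equal(as.integer(proj[[k]]), manual)
    expect_equal(attr(proj[[k]], "segments"), attr(tt[[k]], "segments"))
  }
  # empty log: projection is the identity
  run0 <- simulate_remd(build_scenario("zero_field",
                                       exchange_interval = 1e9),
                        100, seed = 62)
  asg0 <- lapply(run0$replicas, function(d) assign_tba(d$dee, cores))
  proj0 <- project_replica_assignments(asg0, run0$exchange,
                                       run0$replicas[[1]]$time)
  for (k in c(2, 9))
    expect_equal(as.integer(proj0[[k]]), as.integer(asg0[[k]]))
})
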