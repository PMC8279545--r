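test_that("end-to-end distance is Euclidean and rigid-motion invariant", {
  f <- molecular_frame(c("CZ", "CA", "CZ"),
                       rbind(c(0, 0, 0), c(0.5, 0.5, 0.5), c(8.9, 0, 0)),
                       resid = c(1, 1, 2))
  expect_equal(end_to_end_distance(f), 8.9)
  g <- molecular_frame(c("CZ", "CZ"), rbind(c(1, 2, 2), c(0, 0, 0)),
                       resid = 1:2)
  expect_equal(end_to_end_distance(g), 3.0)   # sqrt(1 + 4 + 4)
  same <- molecular_frame(c("CZ", "CZ"), rbind(c(1, 1, 1), c(1, 1, 1)),
                          resid = 1:2)
  expect_equal(end_to_end_distance(same), 0)
  # invariance under a global rotation + translation
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  g2 <- molecular_frame(c("CZ", "CZ"), g$xyz %*% R + 3, resid = 1:2)
  expect_equal(end_to_end_distance(g2), 3.0, tolerance = 1e-12)
  bad <- molecular_frame(c("CZ", "CZ", "CZ"), diag(3), resid = 1:3)
  expect_error(end_to_end_distance(bad), "exactly twice")
})

test_that("superposition RMSD removes rigid motion and matches an independent fit", {
  set.seed(5)
  a <- molecular_frame(paste0("C", 1:8), matrix(rnorm(24), 8))
  expect_equal(heavy_atom_rmsd(a, a), 0)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  b <- molecular_frame(paste0("C", 1:8), a$xyz %*% R + 5)
  expect_lt(heavy_atom_rmsd(a, b), 1e-10)
  # derived 2-point case: centred coordinates (-1,1) vs (-2,2)
  p <- molecular_frame(c("C1", "C2"), rbind(c(0, 0, 0), c(2, 0, 0)))
  q <- molecular_frame(c("C1", "C2"), rbind(c(0, 0, 0), c(4, 0, 0)))
  expect_equal(heavy_atom_rmsd(p, q), 1.0)
  # independent oracle: bio3d best-fit RMSD
  for (seed in 1:3) {
    set.seed(seed)
    x <- molecular_frame(paste0("C", 1:10), matrix(rnorm(30), 10))
    y <- molecular_frame(paste0("C", 1:10),
                         x$xyz + matrix(rnorm(30, 0, 0.4), 10))
    expect_equal(heavy_atom_rmsd(x, y),
                 bio3d::rmsd(as.vector(t(x$xyz)), as.vector(t(y$xyz)),
                             fit = TRUE),
                 tolerance = 1e-3)
  }
  expect_error(heavy_atom_rmsd(a, p), "atom count")
})

test_that("RMSD behaves as a pseudometric on random triples", {
  set.seed(8)
  fr <- lapply(1:3, function(i)
    molecular_frame(paste0("C", 1:6), matrix(rnorm(18), 6)))
  d12 <- heavy_atom_rmsd(fr[[1]], fr[[2]])
  d21 <- heavy_atom_rmsd(fr[[2]], fr[[1]])
  d13 <- heavy_atom_rmsd(fr[[1]], fr[[3]])
  d23 <- heavy_atom_rmsd(fr[[2]], fr[[3]])
  expect_equal(d12, d21, tolerance = 1e-10)
  expect_lte(d13, d12 + d23 + 1e-10)
})

test_that("hydrogens are excluded from the default heavy-atom selection", {
  a <- molecular_frame(c("CA", "HA", "1HB", "N"),
                       rbind(c(0, 0, 0), c(9, 9, 9), c(-9, 0, 9), c(1, 0, 0)))
  b <- molecular_frame(c("CA", "HA", "1HB", "N"),
                       rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_lt(heavy_atom_rmsd(a, b), 1e-10)  # differs only in hydrogens
})

test_that("dipole moments convert to Debye and respect neutrality", {
  f <- molecular_frame(c("N", "O"), rbind(c(0, 0, 0), c(1, 0, 0)),
                       charge = c(0.5, -0.5))
  expect_equal(dipole_moment(f), 2.4016, tolerance = 1e-4)
  z <- molecular_frame(c("A", "B"), rbind(c(0, 0, 0), c(1, 1, 1)),
                       charge = c(0, 0))
  expect_equal(dipole_moment(z), 0)
  # mirrored arrangement cancels
  m <- molecular_frame(c("A", "B", "C", "D"),
                       rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)),
                       charge = c(0.3, 0.3, -0.3, -0.3))
  expect_lt(dipole_moment(m), 1e-10)
  # reference independence for a neutral frame: shifting coordinates
  f2 <- molecular_frame(c("N", "O"), f$xyz + 100, charge = c(0.5, -0.5))
  expect_equal(dipole_moment(f), dipole_moment(f2), tolerance = 1e-10)
  nn <- molecular_frame(c("N", "O"), f$xyz, charge = c(0.5, -0.4))
  expect_warning(dipole_moment(nn), "net-neutral")
})

test_that("histograms normalise to unit area and locate modes", {
  h <- obs_histogram(rep(8.9, 50), bin_width = 0.1)
  expect_equal(sum(h$density) * 0.1, 1, tolerance = 1e-6)
  expect_lt(abs(h$mode - 8.9), 0.05 + 1e-12)

  set.seed(30)
  x <- rnorm(1e5, 8.9, 0.5)
  h2 <- obs_histogram(x, bin_width = 0.1)
  expect_equal(sum(h2$density * 0.1), 1, tolerance = 1e-6)
  expect_lt(abs(h2$mode - 8.9), 0.1 + 1e-12)
  expect_error(obs_histogram(numeric(0)), "empty")
})

test_that("core detection resolves the packaged three-state mixture", {
  set.seed(31)
  p0 <- c(0.38, 0.42, 0.20)
  means <- c(5.0, 8.9, 11.0)
  comp <- sample.int(3, 5e4, replace = TRUE, prob = p0)
  x <- rnorm(5e4, means[comp], 0.5)
  cores <- detect_cores(x)
  expect_equal(nrow(cores), 3)
  for (s in 1:3)
    expect_true(cores$lower[s] <= means[s] && means[s] <= cores$upper[s])
  # unimodal series -> a single core containing the mean
  u <- rnorm(5000, 7, 0.4)
  c1 <- detect_cores(u)
  expect_equal(nrow(c1), 1)
  expect_true(c1$lower[1] <= 7 && 7 <= c1$upper[1])
  # uniform noise with a high prominence bar -> error
  expect_error(detect_cores(runif(5000, 0, 20), prominence = 0.9),
               "prominence")
  expect_error(detect_cores(rnorm(100)), "at least 1000")
})
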