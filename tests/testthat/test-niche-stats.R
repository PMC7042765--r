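test_that("overlap metrics reproduce hand-computed two-cell values and limits", {
  # two-cell grids evaluated by hand from the defining formulas
  z1 <- matrix(c(1, 0), 1); z2 <- matrix(c(0.5, 0.5), 1)
  expect_equal(schoener_D(z1, z2), 0.5)
  expect_equal(warren_I(z1, z2), 1 - 0.5 * ((1 - sqrt(0.5))^2 + 0.5))
  expect_equal(warren_I(z1, z2), 0.7071, tolerance = 1e-4)
  # identity and disjoint-support limits
  z <- matrix(runif(100), 10); z <- z / sum(z)
  expect_equal(schoener_D(z, z), 1)
  expect_equal(warren_I(z, z), 1)
  d1 <- matrix(c(1, 0, 0, 0), 2) ; d2 <- matrix(c(0, 0, 0, 1), 2)
  expect_equal(schoener_D(d1, d2), 0)
  expect_equal(warren_I(d1, d2), 0)
  # symmetry and joint cell-permutation invariance
  a <- matrix(runif(64), 8); a <- a / sum(a)
  b <- matrix(runif(64), 8); b <- b / sum(b)
  expect_equal(schoener_D(a, b), schoener_D(b, a))
  expect_equal(warren_I(a, b), warren_I(b, a))
  set.seed(2); pi <- sample(64)
  ap <- matrix(a[pi], 8); bp <- matrix(b[pi], 8)
  expect_equal(schoener_D(a, b), schoener_D(ap, bp))
  expect_equal(warren_I(a, b), warren_I(ap, bp))
  # bounds
  expect_true(schoener_D(a, b) >= 0 && schoener_D(a, b) <= 1)
  # shape mismatch errors; non-normalized input warns
  expect_error(schoener_D(a, matrix(1, 2, 2)), "mismatch")
  expect_warning(schoener_D(a * 2, b), "normalizing")
})

test_that("equivalency test: identity case, separated niches, determinism", {
  set.seed(31)
  bg <- cbind(runif(400, -4, 4), runif(400, -4, 4))
  bounds <- niche_grid_bounds(bg)
  occ <- cbind(rnorm(60, 0, 0.5), rnorm(60, 0, 0.5))
  # identical occurrence sets: observed D = 1, p = 1 (nothing can exceed it)
  eq <- niche_equivalency_test(occ, occ, bg, bg, bounds, R = 40,
                               n_reps = 49, seed = 1)
  expect_equal(eq$observed$D, 1)
  expect_equal(eq$p_D, 1)
  expect_length(eq$null_D, 49)
  expect_true(all(eq$null_D >= 0 & eq$null_D <= 1))
  # widely separated niches: p at the attainable minimum 1/(n_reps + 1)
  occ2 <- cbind(rnorm(60, 3.2, 0.3), rnorm(60, 3.2, 0.3))
  eq2 <- niche_equivalency_test(occ, occ2, bg, bg, bounds, R = 40,
                                n_reps = 99, seed = 2)
  expect_equal(eq2$p_D, 1 / 100)
  expect_true(eq2$reject_D_CI)
  # determinism under seed
  eq3 <- niche_equivalency_test(occ, occ2, bg, bg, bounds, R = 40,
                                n_reps = 19, seed = 7)
  eq4 <- niche_equivalency_test(occ, occ2, bg, bg, bounds, R = 40,
                                n_reps = 19, seed = 7)
  expect_identical(eq3$null_D, eq4$null_D)
  expect_error(niche_equivalency_test(occ, occ2, bg, bg, bounds, n_reps = 0),
               "n_reps")
})

test_that("similarity test: identical concentrated niches, uniform invariance, seeding", {
  set.seed(32)
  bg <- cbind(runif(600, -4, 4), runif(600, -4, 4))
  bounds <- niche_grid_bounds(bg)
  occ <- cbind(rnorm(80, 0, 0.4), rnorm(80, 0, 0.4))
  g <- build_niche_grid(occ, bg, bounds, R = 40)
  # concentrated niche vs itself: random relocation rarely beats observed
  sim <- niche_similarity_test(g, g, n_reps = 99, seed = 3)
  expect_equal(sim$observed$D, 1)
  expect_lt(sim$p_D, 0.05)
  # uniform target under toroidal relocation: translation leaves the
  # surface unchanged, every null value equals the observed, p = 1
  flat_avail <- list(e = matrix(1, 40, 40), bandwidth = c(1, 1), R = 40,
                     bounds = bounds)
  gu <- build_niche_grid(bg, NULL, bounds, R = 40, bandwidth = c(1e9, 1e9),
                         availability = flat_avail)
  simu <- niche_similarity_test(gu, gu, n_reps = 49, seed = 4, edge = "wrap")
  expect_equal(simu$p_D, 1)
  expect_true(all(abs(simu$null_D - simu$observed$D) < 1e-9))
  # determinism: bit-identical null vectors under the same seed
  s1 <- niche_similarity_test(g, gu, n_reps = 29, seed = 11)
  s2 <- niche_similarity_test(g, gu, n_reps = 29, seed = 11)
  expect_identical(s1$null_D, s2$null_D)
  expect_identical(s1$p_D, s2$p_D)
})

test_that("dynamics indices match a set-arithmetic oracle and satisfy E + S = 1", {
  # identity: no expansion, full stability, no unfilling
  set.seed(33)
  bg <- cbind(runif(500, -4, 4), runif(500, -4, 4))
  bounds <- niche_grid_bounds(bg)
  occ <- cbind(rnorm(70, -1, 0.4), rnorm(70, 0, 0.4))
  g <- build_niche_grid(occ, bg, bounds, R = 30)
  d0 <- niche_dynamics(g, g)
  expect_equal(d0$expansion, 0)
  expect_equal(d0$stability, 1)
  expect_equal(d0$unfilling, 0)
  # disjoint supports on plain matrices: complete expansion and unfilling
  m1 <- matrix(0, 10, 10); m1[1:3, 1:3] <- 1 / 9
  m2 <- matrix(0, 10, 10); m2[7:9, 7:9] <- 1 / 9
  dd <- niche_dynamics(m1, m2)
  expect_equal(dd$expansion, 1)
  expect_equal(dd$stability, 0)
  expect_equal(dd$unfilling, 1)
  # random 10x10 grids vs independent cell-by-cell set computation
  for (rep in 1:5) {
    a <- matrix(runif(100), 10); a[a < 0.4] <- 0; a <- a / sum(a)
    b <- matrix(runif(100), 10); b[b < 0.4] <- 0; b <- b / sum(b)
    dyn <- niche_dynamics(a, b)
    occ_a <- a > 0; occ_b <- b > 0   # oracle set arithmetic
    E <- sum(b[occ_b & !occ_a]) / sum(b[occ_b])
    U <- sum(a[occ_a & !occ_b]) / sum(a[occ_a])
    expect_equal(dyn$expansion, E)
    expect_equal(dyn$unfilling, U)
    expect_equal(dyn$expansion + dyn$stability, 1, tolerance = 1e-12)
    expect_true(all(c(dyn$expansion, dyn$stability, dyn$unfilling) >= 0))
    expect_true(all(c(dyn$expansion, dyn$stability, dyn$unfilling) <= 1))
  }
  # empty occupied set errors
  expect_error(niche_dynamics(matrix(0, 5, 5), matrix(1 / 25, 5, 5)),
               "zero total mass|empty occupied set")
  # niche_grid inputs use the data-driven support: shifted niches separate
  occ2 <- cbind(rnorm(70, 2.5, 0.4), rnorm(70, 0, 0.4))
  g2 <- build_niche_grid(occ2, bg, bounds, R = 30)
  dsh <- niche_dynamics(g, g2)
  expect_gt(dsh$expansion, 0.5)
  expect_gt(dsh$unfilling, 0.5)
})

test_that("overlap decreases monotonically with the programmed niche separation", {
  set.seed(34)
  bg <- cbind(runif(500, -5, 5), runif(500, -5, 5))
  bounds <- niche_grid_bounds(bg)
  seps <- c(0, 0.5, 1, 2, 4) * 0.5
  med_D <- vapply(seps, function(d) {
    Ds <- vapply(1:12, function(r) {
      o1 <- cbind(rnorm(60, -1, 0.5), rnorm(60, 0, 0.5))
      o2 <- cbind(rnorm(60, -1 + d, 0.5), rnorm(60, 0, 0.5))
      schoener_D(build_niche_grid(o1, bg, bounds, R = 40),
                 build_niche_grid(o2, bg, bounds, R = 40))
    }, 0)
    median(Ds)
  }, 0)
  expect_true(all(diff(med_D) < 0))
})

test_that("one-row results table carries tests and dynamics in the expected schema", {
  set.seed(35)
  bg <- cbind(runif(300, -4, 4), runif(300, -4, 4))
  bounds <- niche_grid_bounds(bg)
  o1 <- cbind(rnorm(40, 0, .5), rnorm(40, 0, .5))
  o2 <- cbind(rnorm(40, 2, .5), rnorm(40, 0, .5))
  g1 <- build_niche_grid(o1, bg, bounds, R = 30)
  g2 <- build_niche_grid(o2, bg, bounds, R = 30)
  eq <- niche_equivalency_test(o1, o2, bg, bg, bounds, R = 30, n_reps = 9,
                               seed = 1)
  s1 <- niche_similarity_test(g1, g2, n_reps = 9, seed = 2,
                              direction = "native->invasive")
  s2 <- niche_similarity_test(g2, g1, n_reps = 9, seed = 3,
                              direction = "invasive->native")
  dyn <- niche_dynamics(g1, g2)
  f <- tempfile(fileext = ".csv")
  tab <- niche_shift_table(eq, s1, s2, dyn, path = f)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$metric, c("D", "I"))
  expect_true(file.exists(f))
  back <- read.csv(f)
  expect_equal(back$equivalency, tab$equivalency)
  expect_true(all(c("expansion", "stability", "unfilling") %in% names(tab)))
})
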