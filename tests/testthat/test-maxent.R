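test_that("feature construction counts, bounds and hinge identities", {
  env <- random_env(100, 4, seed = 1)
  # L only: one feature per variable
  expect_equal(nrow(build_features(env, "L")$defs), 4)
  # L, Q, P: 4 + 4 + choose(4,2) = 14
  expect_equal(nrow(build_features(env, c("L", "Q", "P"))$defs), 14)
  # full set with k knots: 4L + 4Q + 6P + 2*k*4 H + k*4 T
  k <- 5
  fs <- build_features(env, c("L", "Q", "H", "P", "T"), knots = k)
  expect_equal(nrow(fs$defs), 4 + 4 + 6 + 2 * k * 4 + k * 4)
  # every feature maps in-range data to [0, 1]
  F <- evaluate_features(fs, env)
  expect_true(all(F >= 0 & F <= 1))
  # out-of-range data is clamped, still [0, 1]
  F2 <- evaluate_features(fs, env * 10)
  expect_true(all(F2 >= 0 & F2 <= 1))
  # forward hinge at knot is 0 at the knot and 1 at the variable maximum
  hf <- fs$defs$kind == "HF" & fs$defs$var1 == "var1"
  kn <- fs$defs$knot[hf][1]
  at_knot <- env[1, , drop = FALSE]
  at_knot[, "var1"] <- fs$lo[["var1"]] + kn * (fs$hi[["var1"]] - fs$lo[["var1"]])
  expect_equal(unname(evaluate_features(fs, at_knot)[1, which(hf)[1]]), 0)
  at_max <- at_knot; at_max[, "var1"] <- fs$hi[["var1"]]
  expect_equal(unname(evaluate_features(fs, at_max)[1, which(hf)[1]]), 1)
  # constant variable: nonlinear features dropped with a warning
  envc <- cbind(env, const = 1)
  expect_warning(fsc <- build_features(envc, c("L", "Q")), "constant")
  expect_false(any(fsc$defs$kind == "Q" & fsc$defs$var1 == "const"))
  expect_true(any(fsc$defs$kind == "L" & fsc$defs$var1 == "const"))
})

test_that("single-feature fit matches a brute-force 1-D objective scan", {
  # one binary feature; presences all f = 1, background half and half
  pres <- matrix(rep(1, 20), dimnames = list(NULL, "var1"))
  bg <- matrix(rep(c(0, 1), 50), dimnames = list(NULL, "var1"))
  fs <- build_features(bg, "L")
  m <- fit_maxent(pres, bg, fs, RM = 0.01)
  # with near-zero regularization the fitted mean tracks the presence mean
  Fb <- evaluate_features(fs, bg)
  p <- predict(m, bg, type = "raw")
  expect_equal(sum(p * Fb[, 1]), 1, tolerance = 0.05)
  expect_gt(m$lambda[1], 2)
  # oracle: dense scan of the penalized objective over lambda
  beta <- m$beta[1]
  obj <- function(l)
    log(mean(exp(l * Fb[, 1]))) - l * 1 + beta * abs(l)
  grid <- seq(-2, 15, by = 0.001)
  l_star <- grid[which.min(vapply(grid, obj, 0))]
  expect_equal(unname(m$lambda[1]), l_star, tolerance = 0.01)
})

test_that("fitted models satisfy KKT box conditions and normalization", {
  set.seed(12)
  bg <- random_env(300, 3)
  pres <- random_env(40, 3, mean = 0.7, sd = 0.6)
  fs <- build_features(bg, c("L", "Q", "H"), knots = 6)
  for (rm in c(0.5, 1, 2)) {
    m <- fit_maxent(pres, bg, fs, RM = rm)
    # raw probabilities over training background sum to 1
    expect_equal(sum(predict(m, bg, type = "raw")), 1, tolerance = 1e-9)
    # KKT: |E_fit[f_j] - mean_presence[f_j]| <= beta_j (+tol); binding when
    # lambda_j != 0
    Fb <- evaluate_features(fs, bg)
    p <- predict(m, bg, type = "raw")
    g <- drop(crossprod(Fb, p)) - m$presence_feature_means
    tol <- 1e-6
    expect_true(all(abs(g) <= m$beta + tol))
    nz <- m$lambda != 0
    expect_true(all(abs(g[nz] + m$beta[nz] * sign(m$lambda[nz])) <= tol))
  }
})

test_that("full-shrinkage limit is uniform with the closed-form cloglog value", {
  set.seed(13)
  bg <- random_env(120, 3)
  pres <- random_env(25, 3, mean = 1)
  fs <- build_features(bg, c("L", "Q"))
  m <- fit_maxent(pres, bg, fs, RM = 1e8)
  expect_true(all(m$lambda == 0))
  expect_equal(m$entropy, log(120))
  expect_equal(unique(round(predict(m, bg, type = "raw"), 15)), 1 / 120)
  expect_equal(predict(m, bg)[1], 1 - exp(-1), tolerance = 1e-12)
  # monotone single-L model preserves the variable's ordering
  fs1 <- build_features(bg[, 1, drop = FALSE], "L")
  m1 <- fit_maxent(matrix(pres[, 1], dimnames = list(NULL, "var1")),
                   matrix(bg[, 1], dimnames = list(NULL, "var1")), fs1,
                   RM = 0.5)
  s <- predict(m1, matrix(sort(bg[, 1]), dimnames = list(NULL, "var1")))
  expect_true(all(diff(s) >= 0) || all(diff(s) <= 0))
})

test_that("solution beats random probes and restarts land on the same objective", {
  set.seed(14)
  bg <- random_env(50, 3)
  pres <- random_env(10, 3, mean = 0.5)
  fs <- build_features(bg, "L")
  m <- fit_maxent(pres, bg, fs, RM = 1)
  Fb <- evaluate_features(fs, bg); Fp <- evaluate_features(fs, pres)
  obj <- function(l)
    log(mean(exp(drop(Fb %*% l)))) - mean(drop(Fp %*% l)) +
      sum(m$beta * abs(l))
  o_star <- obj(m$lambda)
  probes <- matrix(rnorm(1000 * 3, sd = 2), ncol = 3)
  expect_true(all(apply(probes, 1, obj) >= o_star - 1e-10))
  # convexity: a refit from the same inputs reaches the same objective
  m2 <- fit_maxent(pres, bg, fs, RM = 1)
  expect_equal(obj(m2$lambda), o_star, tolerance = 1e-6)
})

test_that("nonzero-coefficient count never increases along the RM path", {
  set.seed(15)
  bg <- random_env(250, 4)
  pres <- random_env(50, 4, mean = 0.8, sd = 0.5)
  fs <- build_features(bg, c("L", "Q", "H"), knots = 8)
  ks <- vapply(seq(0.5, 4, by = 0.5),
               function(rm) sum(fit_maxent(pres, bg, fs, RM = rm)$lambda != 0),
               0)
  # the active set shrinks along the path overall (the L1 path can bump by
  # a coefficient at a single step, so the trend is what is asserted here)
  expect_lte(ks[8], ks[1])
  expect_lt(cor(seq_along(ks), ks, method = "kendall"), 0)
  expect_lte(max(ks) - ks[1], 1)
})

test_that("block partition matches brute-force median splits and balances groups", {
  # symmetric 2 x 4 lattice: four groups of two
  lat <- rep(c(0, 1), each = 4); lon <- rep(1:4, 2)
  bp <- block_partition(data.frame(lon = lon, lat = lat))
  expect_equal(as.vector(table(bp$presence_block)), rep(2L, 4))
  # 103 random presences: sizes within {25, 26, 27}; assignment matches oracle
  set.seed(16)
  p <- data.frame(lon = runif(103), lat = runif(103))
  bp2 <- block_partition(p, background = p)
  expect_true(all(table(bp2$presence_block) %in% 25:27))
  lat_med <- median(p$lat)                      # independent re-derivation
  low <- p$lat <= lat_med
  oracle <- ifelse(low, ifelse(p$lon <= median(p$lon[low]), 1L, 2L),
                   ifelse(p$lon <= median(p$lon[!low]), 3L, 4L))
  expect_equal(bp2$presence_block, oracle)
  # pure function of coordinates: identical on rerun
  expect_identical(bp2$presence_block,
                   block_partition(p, p)$presence_block)
  # background assigned by the same boundaries
  expect_equal(bp2$background_block, oracle)
  expect_error(block_partition(data.frame(lon = rep(1, 5), lat = rep(2, 5))),
               "degenerate")
  expect_error(block_partition(data.frame(lon = 1:3, lat = 1:3)), ">= 4")
})

test_that("AICc follows the closed form and flags overparameterized candidates", {
  set.seed(17)
  bg <- random_env(100, 2)
  pres <- bg[1:10, , drop = FALSE]
  fs <- build_features(bg, "L")
  # uniform model: k = 0, logL = n * log(1/n_background), AICc = -2 logL
  m0 <- fit_maxent(pres, bg, fs, RM = 1e8)
  ic <- maxent_aicc(m0, pres)
  expect_equal(ic$k, 0)
  expect_equal(ic$logL, 10 * log(1 / 100))
  expect_equal(ic$AICc, -2 * ic$logL)
  expect_true(ic$valid)
  # penalty monotonicity at fixed logL
  aicc_of <- function(k, logL, n) 2 * k - 2 * logL + 2 * k * (k + 1) / (n - k - 1)
  expect_true(aicc_of(3, -50, 20) > aicc_of(2, -50, 20))
  # n <= k + 1 flagged invalid
  m1 <- fit_maxent(random_env(12, 2, mean = 1), bg, fs, RM = 0.1)
  k1 <- sum(m1$lambda != 0)
  if (k1 >= 1) {
    tiny <- random_env(k1 + 1, 2, mean = 1)
    expect_false(maxent_aicc(m1, tiny)$valid)
  }
})

test_that("tuning enumerates the full candidate grid and selects by AICc", {
  set.seed(18)
  bg <- random_env(200, 3)
  pres <- random_env(40, 3, mean = 0.8, sd = 0.5)
  # trivial 1-candidate grid
  tu1 <- tune_maxent(pres, bg, class_combos = list(L = "L"), RMs = 1,
                     knots = 4, cv = FALSE)
  expect_equal(nrow(tu1$table), 1)
  expect_equal(tu1$selected, 1L)
  # 2 x 3 grid: candidate count, delta-AICc floor at 0, selection rule
  tu <- tune_maxent(pres, bg,
                    class_combos = list(L = "L", LQ = c("L", "Q")),
                    RMs = c(0.5, 1, 2), knots = 4, cv = FALSE)
  expect_equal(nrow(tu$table), 6)
  expect_equal(min(tu$table$delta_AICc[tu$table$valid]), 0)
  expect_true(tu$table$delta_AICc[tu$selected] < 2)
  sel <- tu$table[tu$selected, ]
  best <- tu$table[tu$table$valid & tu$table$delta_AICc < 2, ]
  expect_equal(sel$AICc, min(best$AICc))
  # data generated from a pure linear response selects a combo containing L
  set.seed(19)
  bg2 <- random_env(300, 2)
  w <- exp(2 * bg2[, 1])
  pres_idx <- sample.int(300, 60, replace = TRUE, prob = w)
  tu2 <- tune_maxent(bg2[pres_idx, ], bg2,
                     class_combos = list(L = "L", LQ = c("L", "Q")),
                     RMs = c(0.5, 1), knots = 4, cv = FALSE)
  expect_true(grepl("L", tu2$table$classes[tu2$selected]))
})

test_that("block cross-validation produces test AUC per candidate", {
  set.seed(20)
  bg <- random_env(200, 2)
  w <- exp(1.5 * bg[, 1])
  pres <- bg[sample.int(200, 50, replace = TRUE, prob = w), ]
  coords_p <- data.frame(lon = runif(50), lat = runif(50))
  coords_b <- data.frame(lon = runif(200), lat = runif(200))
  tu <- tune_maxent(pres, bg, class_combos = list(L = "L"), RMs = c(0.5, 1),
                    knots = 4, presence_coords = coords_p,
                    background_coords = coords_b, cv = TRUE)
  expect_true(all(is.finite(tu$table$mean_test_auc)))
  expect_true(all(tu$table$mean_test_auc >= 0 & tu$table$mean_test_auc <= 1))
})
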