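test_that("standard scoring centres, scales, and flags constant columns", {
  X <- cbind(c(1, 2, 3), c(10, 20, 60))
  Z <- standard_score(X)
  expect_equal(colMeans(Z), c(0, 0))
  expect_equal(apply(Z, 2, sd), c(1, 1))
  expect_warning(Zc <- standard_score(cbind(c(5, 5, 5), 1:3)),
                 "zero-variance")
  expect_equal(Zc[, 1], c(0, 0, 0))
  # affine invariance of the scored values
  expect_equal(standard_score(2 * X[, 1] - 3), standard_score(X[, 1]))
})

test_that("KSG estimates match the Gaussian closed form", {
  set.seed(21)
  n <- 2500
  for (rho in c(0.5, 0.9)) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    est <- ksg_mi(x, y, k = 4)
    expect_lt(abs(est$value - gaussian_mi_bits(rho)), 0.1)
    expect_equal(est$n, n)
  }
  x <- rnorm(n)
  expect_lt(abs(ksg_mi(x, rnorm(n))$value), 0.05)
})

test_that("KSG is exactly symmetric and affine invariant", {
  set.seed(3)
  X <- matrix(rnorm(400), ncol = 2)
  Y <- matrix(rnorm(400), ncol = 2)
  expect_identical(ksg_mi(X, Y, 4)$value, ksg_mi(Y, X, 4)$value)
  # dyadic per-column rescaling leaves standard-scored input bit-identical
  X2 <- sweep(sweep(X, 2, c(2, 0.25), "*"), 2, c(-3, 1), "+")
  expect_identical(ksg_mi(X2, Y, 4)$value, ksg_mi(X, Y, 4)$value)
})

test_that("KSG rejects undersized or empty inputs", {
  expect_error(ksg_mi(rnorm(4), rnorm(4), k = 4), "sample-size")
  expect_error(ksg_mi(matrix(numeric(0), 5, 0), rnorm(5)), "zero-dimension")
  expect_error(ksg_mi(rnorm(10), rnorm(9)), "same number of rows")
})

test_that("k-robustness: estimates vary little with k on fixed data", {
  set.seed(13)
  n <- 1000
  x <- rnorm(n)
  y <- 0.7 * x + sqrt(1 - 0.49) * rnorm(n)
  vals <- vapply(2:7, function(k) ksg_mi(x, y, k)$value, numeric(1))
  expect_lt(max(vals) - min(vals), 0.1)
})

test_that("mixed count MI behaves at its analytic anchors", {
  set.seed(5)
  n <- 2500
  Y <- matrix(rnorm(2 * n), ncol = 2)
  # independent labels
  lab <- sample(1:4, n, replace = TRUE)
  expect_lt(abs(mixed_mi_count(lab, Y)$value), 0.05)
  # deterministic balanced binary function of Y: I = H(c) = 1 bit
  cb <- as.integer(Y[, 1] > 0)
  est <- mixed_mi_count(cb, Y)
  expect_lt(abs(est$value - 1), 0.05)
  # capped at the label entropy
  expect_lte(est$value, 1)
  # single class is exactly zero
  expect_identical(mixed_mi_count(rep(1L, n), Y)$value, 0)
  # undersized classes are excluded with a warning
  lab2 <- c(rep(1L, n - 3L), rep(2L, 3L))
  expect_warning(mixed_mi_count(lab2, Y, k = 4), "excluding")
})

test_that("mixed count estimator agrees with KSG on an encoded label", {
  set.seed(8)
  n <- 2000
  Y <- matrix(rnorm(2 * n), ncol = 2)
  # a noisy (non-deterministic) label so both estimators are in-model
  z <- Y[, 1] + rnorm(n)
  cb <- as.integer(z > 0.7) + as.integer(z > -0.7)
  mixed <- mixed_mi_count(cb, Y)$value
  encoded <- ksg_mi(matrix(as.numeric(cb), ncol = 1), Y)$value
  expect_lt(abs(mixed - encoded), 0.05)
})

test_that("count/timing decomposition isolates timing information", {
  # independent times at every count: timing terms near zero (balanced
  # counts so every conditional estimate has a few hundred trials)
  ml0 <- moth_like(n = 2000, count_probs = rep(0.2, 5), timing_rho = 0,
                   seed = 31)
  est0 <- timing_mi_decomposed(ml0$spikes, ml0$motor)
  timing0 <- est0$per_count_terms$mi_bits[est0$per_count_terms$included]
  # each conditional term is estimator noise; their weighted sum averages it
  expect_true(all(abs(timing0) < 0.15))
  expect_lt(abs(est0$timing_term), 0.1)
  # single-spike data: decomposition degenerates to a plain KSG run
  gp <- gaussian_pair(n = 800, rho = 0.8, seed = 32)
  est1 <- timing_mi_decomposed(gp$spikes, gp$motor)
  direct <- ksg_mi(gp$spikes$times, gp$motor$scores)
  expect_identical(est1$value, direct$value)
  expect_identical(est1$count_term, 0)
})

test_that("decomposition equals per-class KSG runs, weighted by count", {
  ml <- moth_like(n = 1500, seed = 33)
  est <- timing_mi_decomposed(ml$spikes, ml$motor)
  terms <- est$per_count_terms
  manual <- est$count_term
  for (i in which(terms$included)) {
    ci <- terms$count[i]
    idx <- which(ml$spikes$counts == ci)
    mi_i <- ksg_mi(ml$spikes$times[idx, seq_len(ci), drop = FALSE],
                   ml$motor$scores[idx, , drop = FALSE])$value
    expect_identical(terms$mi_bits[i], mi_i)
    manual <- manual + terms$weight[i] * mi_i
  }
  expect_equal(est$value, manual)
  expect_lte(sum(terms$weight), 1)
})

test_that("k-NN distance diagnostics respond to added noise", {
  ml <- moth_like(n = 600, seed = 34)
  dg <- knn_distance_diagnostics(ml$spikes, ml$motor,
                                 noise_grid = c(0, 1, 8, 32), seed = 2)
  expect_true(all(dg$median_dist_sd > 0))
  z <- dg[dg$r_c_ms == 0, ]
  expect_true(all(z$delta_ms == 0))
  # medians grow with heavy noise relative to zero noise
  big <- dg[dg$r_c_ms == 32, ]
  expect_true(all(big$delta_ms > 0))
})
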