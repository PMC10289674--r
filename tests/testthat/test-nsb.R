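test_that("NSB matches the plugin entropy when fully sampled", {
  # uniform over 4 words
  r <- nsb_entropy(rep(2500, 4), 4)
  expect_lt(abs(r$mean - 2), 0.02)
  expect_gte(r$std, 0)
  # a skewed but well-sampled distribution
  counts <- c(4000, 2000, 1000, 1000, 500, 500, 500, 500)
  r2 <- nsb_entropy(counts, 8)
  expect_lt(abs(r2$mean - plugin_entropy_bits(counts)), 0.02)
})

test_that("NSB handles the near-deterministic and coincidence regimes", {
  r <- nsb_entropy(1000, 16)
  expect_lt(r$mean, 0.05)
  # all-distinct sample in a huge alphabet: finite mean, large uncertainty
  r2 <- nsb_entropy(rep(1, 10), 1e6)
  expect_true(is.finite(r2$mean))
  expect_gt(r2$std, 1)
  expect_lte(r2$mean, log2(1e6))
})

test_that("NSB agrees with an independent dense-grid quadrature oracle", {
  cases <- list(
    list(counts = c(5, 3, 1, 1), K = 8),
    list(counts = c(10, 1, 1), K = 50),
    list(counts = rep(1, 8), K = 200),
    list(counts = c(40, 30, 20, 10), K = 4)
  )
  for (cs in cases) {
    got <- nsb_entropy(cs$counts, cs$K)$mean
    want <- nsb_oracle_bits(cs$counts, cs$K)
    expect_lt(abs(got - want), 0.02)
  }
})

test_that("NSB validates its inputs", {
  expect_error(nsb_entropy(c(3, 2), 1), "alphabet size")
  expect_error(nsb_entropy(numeric(0), 4), "at least one")
  expect_error(nsb_entropy(c(1.5, 2), 4), "integers")
  expect_identical(nsb_entropy(5, 1)$mean, 0)
})

test_that("spike-word binning obeys the bin-size relation exactly", {
  sm <- spike_matrix(rbind(c(10, 50), c(12.3, 47.9)))
  w <- bin_words(sm, 40)
  expect_identical(w$r_d * w$b_s, w$t_max - w$t_min)
  expect_equal(w$r_d, 1.0)
  # property: exactness across random windows and bin counts
  set.seed(61)
  for (i in 1:20) {
    smr <- suppressWarnings(spike_matrix(matrix(runif(60, -20, 60), ncol = 3)))
    b <- sample(1:70, 1)
    wr <- bin_words(smr, b)
    expect_identical(wr$r_d * wr$b_s, wr$t_max - wr$t_min)
  }
})

test_that("spike words count spikes per bin with a closed last bin", {
  sm <- spike_matrix(rbind(c(10, 50), c(12.3, 47.9)))
  w <- bin_words(sm, 4)
  expect_equal(w$trial_words[2], "1.0.0.1")
  expect_equal(w$trial_words[1], "1.0.0.1") # 10 in first bin, 50 closed at t_max
  # b_s = 1 erases timing: word = spike count
  ml <- moth_like(n = 50, seed = 62)
  w1 <- bin_words(ml$spikes, 1)
  expect_equal(w1$trial_words, as.character(ml$spikes$counts))
  empty <- spike_matrix(matrix(NA_real_, 3, 2))
  expect_error(bin_words(empty, 5), "no spikes")
})

test_that("motor discretisation makes balanced joint quantile states", {
  mo <- motor_scores(matrix(rnorm(200), ncol = 2))
  ms <- discretize_motor(mo, 2)
  expect_equal(sort(unique(ms$states)), 1:4)
  # each PC split 50/50
  expect_equal(sum(ms$states <= 2), 50)
  expect_equal(sum(ms$states %% 2 == 1), 50)
  ms3 <- discretize_motor(mo, 3)
  expect_equal(length(unique(ms3$states)) <= 9, TRUE)
  expect_equal(sum(ms3$probs), 1)
  # partition sizes differ by at most 1, for awkward N too
  for (n in c(97, 100, 101)) {
    mon <- motor_scores(matrix(rnorm(2 * n), ncol = 2))
    for (bm in 2:4) {
      g <- discretize_motor(mon, bm)
      pc1_sizes <- table((g$states - 1) %/% bm)
      expect_lte(max(pc1_sizes) - min(pc1_sizes), 1)
    }
  }
  expect_error(discretize_motor(motor_scores(matrix(rnorm(8), ncol = 2)), 3),
               "too few trials")
})

test_that("quantile ties are broken stably by trial index", {
  sc <- cbind(c(1, 1, 1, 1, 2, 2), c(1, 2, 3, 4, 5, 6))
  ms1 <- discretize_motor(motor_scores(sc), 2)
  ms2 <- discretize_motor(motor_scores(sc), 2)
  expect_identical(ms1$states, ms2$states)
  # the first three tied trials go to the low group
  expect_equal((ms1$states[1:3] - 1) %/% 2, c(0, 0, 0))
})

test_that("discrete MI recovers a deterministic word-state relationship", {
  set.seed(63)
  n <- 2000
  # 4 exactly balanced states (so the quantile split is clean), words a
  # deterministic function of the state
  state <- sample(rep(0:3, n / 4))
  sc <- cbind(ifelse(state %/% 2 == 0, -1, 1) + rnorm(n, sd = 0.05),
              ifelse(state %% 2 == 0, -1, 1) + rnorm(n, sd = 0.05))
  times <- matrix(10 * state + 5, ncol = 1)
  sm <- spike_matrix(times)
  w <- bin_words(sm, 8)
  ms <- discretize_motor(motor_scores(sc), 2)
  r <- mi_discrete(w, ms)
  expect_lt(abs(r$mi - 2), 0.1)
  # b_m = 1: a single state carries no information, exactly
  ms1 <- discretize_motor(motor_scores(sc), 1)
  expect_equal(mi_discrete(w, ms1)$mi, 0)
})

test_that("shuffle correction removes the independence bias", {
  set.seed(64)
  ml <- moth_like(n = 800, seed = 65)
  ms <- discretize_motor(motor_scores(matrix(rnorm(1600), ncol = 2)), 3)
  w <- bin_words(ml$spikes, 30)
  r <- mi_shuffle_corrected(w, ms, n_sh = 10, seed = 66)
  expect_lt(abs(r$I_dsh), 3 * r$I_d_std)
  # raw discrete MI carries positive bias that the correction removes
  expect_gt(r$I_d, r$I_dsh)
  expect_error(mi_shuffle_corrected(w, ms, n_sh = 5), ">= 10")
})

test_that("shuffle-count choice does not move the corrected estimate", {
  gp <- gaussian_pair(n = 600, rho = 0.8, seed = 67)
  w <- bin_words(gp$spikes, 12)
  ms <- discretize_motor(gp$motor, 3)
  r10 <- mi_shuffle_corrected(w, ms, n_sh = 10, seed = 68)
  r50 <- mi_shuffle_corrected(w, ms, n_sh = 50, seed = 68)
  expect_lt(abs(r10$I_dsh - r50$I_dsh), 3 * r10$I_d_std)
  # strong dependence, well sampled: bias correction is a small adjustment
  expect_lt(abs(r10$I_dsh - r10$I_d), 0.1 * abs(r10$I_d))
})

test_that("the discrete precision rule picks the corrected-MI peak", {
  curve <- tibble::tibble(
    b_s = 1:40, r_d_ms = 40 / (1:40),
    I_d = 1 + 0.01 * (1:40),
    I_d_std = 0.02, I_sh = 0,
    I_dsh = c(seq(0.2, 1, length.out = 20), seq(0.98, 0.6, length.out = 20)))
  class(curve) <- c("discrete_curve", class(curve))
  est <- precision_nsb_peak(curve)
  expect_equal(est$value_ms, 40 / 20)
  expect_false(est$diagnostics[[1]]$boundary)
  # monotone rise to the boundary is flagged
  curve2 <- curve
  curve2$I_dsh <- seq(0.1, 1, length.out = 40)
  est2 <- precision_nsb_peak(curve2)
  expect_equal(est2$value_ms, 1)
  expect_true(est2$diagnostics[[1]]$boundary)
  # ties break toward smaller b_s (coarser precision)
  curve3 <- curve
  curve3$I_dsh <- rep(0.5, 40)
  expect_equal(precision_nsb_peak(curve3)$value_ms, 40)
})
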