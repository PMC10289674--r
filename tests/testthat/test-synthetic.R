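test_that("gaussian-pair data reproduce their specification", {
  gp <- gaussian_pair(n = 2500, rho = 0.7, mu = 0, sigma = 2, seed = 71)
  expect_equal(n_trials(gp$spikes), 2500L)
  expect_equal(gp$spikes$max_count, 1L)
  # marginal moments within 3 standard errors
  se_mean <- 2 / sqrt(2500)
  expect_lt(abs(mean(gp$spikes$times) - 0), 3 * se_mean)
  expect_lt(abs(sd(gp$spikes$times) - 2), 3 * 2 / sqrt(2 * 2500))
  expect_lt(abs(mean(gp$motor$scores)), 3 * se_mean)
  # coupling structure: both time-score correlations near rho
  expect_true(all(abs(gp$sample_correlations - 0.7) < 0.05))
  # score-score correlation near rho^2 under the latent-factor coupling
  expect_lt(abs(cor(gp$motor$scores)[1, 2] - 0.49), 0.06)
})

test_that("gaussian-pair generation is deterministic in its seed", {
  a <- gaussian_pair(n = 200, seed = 72)
  b <- gaussian_pair(n = 200, seed = 72)
  c <- gaussian_pair(n = 200, seed = 73)
  expect_identical(a$spikes$times, b$spikes$times)
  expect_identical(a$motor$scores, b$motor$scores)
  expect_false(identical(a$spikes$times, c$spikes$times))
})

test_that("uncorrelated pairs are empirically uncorrelated", {
  gp <- gaussian_pair(n = 2500, rho = 0, seed = 74)
  expect_true(all(abs(gp$sample_correlations) < 0.05))
})

test_that("KSG on gaussian-pair data matches the trivariate closed form", {
  gp <- gaussian_pair(n = 2500, rho = 0.9, seed = 75)
  est <- ksg_mi(gp$spikes$times, gp$motor$scores, k = 4)
  expect_lt(abs(est$value - gaussian_pair_mi_bits(0.9)), 0.1)
  expect_equal(gp$true_mi_bits, gaussian_pair_mi_bits(0.9))
})

test_that("generator specs are validated", {
  expect_error(gaussian_pair(rho = 1), "rho")
  expect_error(gaussian_pair(n = 5), "config error")
  expect_error(gaussian_pair(sigma = 0), "sigma")
  expect_error(moth_like(count_probs = c(0.5, 0.4)), "count_probs")
  expect_error(moth_like(window = c(10, 5)), "window")
  expect_error(moth_like(timing_rho = 1.2), "timing_rho")
})

test_that("moth-like data have the requested count structure and coupling", {
  ml <- moth_like(n = 2000, seed = 76)
  expect_true(all(ml$spikes$counts >= 1 & ml$spikes$counts <= 5))
  emp <- tabulate(ml$spikes$counts, 5) / 2000
  expect_lt(max(abs(emp - ml$count_probs)), 0.05)
  # rows sorted with NA padding
  expect_true(all(apply(ml$spikes$times, 1,
                        function(r) !is.unsorted(r[!is.na(r)]))))
  # degenerate count distribution reduces to single-spike structure
  ml1 <- moth_like(n = 100, count_probs = 1, seed = 77)
  expect_true(all(ml1$spikes$counts == 1))
  # determinism
  expect_identical(moth_like(n = 100, seed = 78)$spikes$times,
                   moth_like(n = 100, seed = 78)$spikes$times)
})

test_that("corruption degrades coupled moth-like MI", {
  ml <- moth_like(n = 1000, timing_rho = 0.9, seed = 79)
  mi0 <- timing_mi_decomposed(ml$spikes, ml$motor)$value
  sp_big <- corrupt_spikes(ml$spikes, 40, seed = 80)
  mi_big <- timing_mi_decomposed(sp_big, ml$motor)$value
  expect_gt(mi0, mi_big + 0.2)
})

test_that("fix_precision rounds to the grid, idempotently", {
  sm <- spike_matrix(rbind(c(12.34, 15.5), c(-3.2, NA)))
  r1 <- fix_precision(sm, 1.0)
  expect_equal(r1$times[1, 1], 12)
  expect_identical(is.na(r1$times), is.na(sm$times))
  # all outputs exact multiples of the resolution
  ml <- moth_like(n = 200, seed = 81)
  r <- fix_precision(ml$spikes, 0.7)
  v <- r$times[!is.na(r$times)]
  expect_true(all(abs(v / 0.7 - round(v / 0.7)) < 1e-12))
  # idempotent
  expect_identical(fix_precision(r, 0.7)$times, r$times)
  # identity on data already on the grid
  on_grid <- spike_matrix(matrix(c(0.1, 0.2, 0.3), ncol = 1))
  expect_equal(fix_precision(on_grid, 0.1)$times, on_grid$times)
  expect_error(fix_precision(sm, 0), "config error")
})

test_that("raw flight signals have the stated geometry and ground truth", {
  sig <- raw_flight_signal(n_cycles = 10, period_ms = 40, noise_sd = 0,
                           seed = 82)
  expect_length(sig$fz, 10 * 40 * 10)
  expect_length(sig$zero_points, 10)
  expect_equal(unique(diff(sig$zero_points)), 400)
  expect_identical(sig$fz, raw_flight_signal(10, 40, 0, seed = 82)$fz)
  expect_warning(raw_flight_signal(10, period_ms = 500, seed = 1),
                 "passband")
})
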