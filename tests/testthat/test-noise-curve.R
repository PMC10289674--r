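test_that("uniform corruption shifts times one-sidedly and keeps structure", {
  sm <- spike_matrix(rbind(c(10, 20), c(5, NA)))
  expect_identical(corrupt_spikes(sm, 0), sm)
  expect_error(corrupt_spikes(sm, -1), "config error")
  set.seed(1)
  out <- corrupt_spikes(sm, 4)
  expect_true(all(out$times[1, ] >= sm$times[1, ] &
                    out$times[1, ] < sm$times[1, ] + 4))
  expect_identical(is.na(out$times), is.na(sm$times))
  # mean shift r_c / 2 over many draws
  big <- spike_matrix(matrix(rep(10, 1e5), ncol = 1))
  shift <- mean(corrupt_spikes(big, 4, seed = 2)$times) - 10
  expect_lt(abs(shift - 2), 0.02)
  # rows re-sorted after corruption
  close_sm <- spike_matrix(matrix(rep(c(10, 10.01), 500), ncol = 2,
                                  byrow = TRUE))
  cc <- corrupt_spikes(close_sm, 5, seed = 3)
  expect_true(all(cc$times[, 2] >= cc$times[, 1]))
})

test_that("corruption with a seed is reproducible and independent draws differ", {
  sm <- gaussian_pair(n = 100, seed = 1)$spikes
  a <- corrupt_spikes(sm, 2, seed = 7)
  b <- corrupt_spikes(sm, 2, seed = 7)
  c <- corrupt_spikes(sm, 2, seed = 8)
  expect_identical(a$times, b$times)
  expect_false(identical(a$times, c$times))
})

test_that("data-fraction uncertainty is non-negative and scales as 1/sqrt(n)", {
  gp1 <- gaussian_pair(n = 600, rho = 0.8, seed = 41)
  gp2 <- gaussian_pair(n = 1200, rho = 0.8, seed = 41)
  r1 <- vapply(1:4, function(s)
    as.numeric(data_fraction_uncertainty(gp1$spikes, gp1$motor, seed = s)),
    numeric(1))
  r2 <- vapply(1:4, function(s)
    as.numeric(data_fraction_uncertainty(gp2$spikes, gp2$motor, seed = s)),
    numeric(1))
  expect_true(all(r1 >= 0) && all(r2 >= 0))
  ratio <- mean(r2) / mean(r1)
  expect_gt(ratio, 1 / sqrt(2) * 0.5)
  expect_lt(ratio, 1 / sqrt(2) * 1.5)
})

test_that("identical trials give (near) zero fraction uncertainty", {
  sm <- suppressWarnings(spike_matrix(matrix(rep(c(3, 7), 50), ncol = 2,
                                             byrow = TRUE)))
  mo <- motor_scores(matrix(rep(c(0.5, -0.5), 50), ncol = 2, byrow = TRUE))
  u <- suppressWarnings(data_fraction_uncertainty(sm, mo, seed = 1))
  # identical trials leave only tie-break jitter noise in tiny subsets
  expect_lt(as.numeric(u), 0.05)
})

test_that("fractioning requires enough trials", {
  gp <- gaussian_pair(n = 30, seed = 1)
  expect_error(data_fraction_uncertainty(gp$spikes, gp$motor), "40")
})

test_that("noise curves are flat for uncoupled data and decay for coupled", {
  cfg <- run_config(n_noise_reps = 8L, noise_grid = noise_grid_default(10),
                    seed = 51L)
  # no timing-motor dependence
  ml0 <- moth_like(n = 500, timing_rho = 0, seed = 52)
  # the smallest count class of this fixture is below k+1 and is excluded
  # from the count term with a warning
  cv0 <- suppressWarnings(noise_curve(ml0$spikes, ml0$motor, cfg))
  expect_true(all(abs(cv0$mi_mean) < 0.15))
  # coupled data: significant decay from zero noise to the last level
  gp <- gaussian_pair(n = 800, rho = 0.9, seed = 53)
  cv <- noise_curve(gp$spikes, gp$motor, cfg)
  expect_equal(cv$mi_mean[1], attr(cv, "zero_noise_mi"))
  expect_gt(cv$mi_mean[1] - cv$mi_mean[nrow(cv)],
            2 * attr(cv, "zero_noise_std"))
  expect_equal(nrow(cv), length(cfg$noise_grid))
  expect_true(all(cv$mi_std >= 0))
})

test_that("the sweep's lean evaluation path matches the full decomposition", {
  ml <- moth_like(n = 400, count_probs = c(0.5, 0.5), seed = 58)
  cfg <- run_config(n_noise_reps = 3L, noise_grid = c(0, 2), seed = 59L)
  cv <- noise_curve(ml$spikes, ml$motor, cfg)
  ct <- timing_mi_decomposed(ml$spikes, ml$motor)$count_term
  manual <- vapply(1:3, function(rep) {
    sp <- corrupt_spikes(ml$spikes, 2,
                         seed = spikeprec:::derive_seed(59L, "noise", 2L, rep))
    timing_mi_decomposed(sp, ml$motor, count_term = ct)$value
  }, numeric(1))
  expect_equal(cv$mi_mean[2], mean(manual))
})

test_that("degenerate single-repetition curves carry a warning and zero std", {
  gp <- gaussian_pair(n = 200, seed = 54)
  cfg <- run_config(n_noise_reps = 1L, noise_grid = c(0, 1, 4), seed = 55L)
  expect_warning(cv <- noise_curve(gp$spikes, gp$motor, cfg), "std")
  expect_true(all(cv$mi_std[-1] == 0))
})

test_that("saturation: heavy noise drives total MI to the count-only term", {
  ml <- moth_like(n = 1000, seed = 56)
  cfg <- run_config(n_noise_reps = 8L,
                    noise_grid = c(0, 1, 400, 800), seed = 57L)
  cv <- noise_curve(ml$spikes, ml$motor, cfg)
  expect_lt(abs(cv$mi_mean[nrow(cv)] - attr(cv, "count_term")), 0.12)
})

test_that("curves are exportable and reconstructible", {
  cv <- sigmoid_curve()
  p <- withr::local_tempfile(fileext = ".csv")
  write_noise_curve(cv, p)
  back <- utils::read.csv(p)
  expect_equal(back$mi_mean_bits, cv$mi_mean)
  g <- glance(cv)
  expect_equal(g$zero_noise_mi, cv$mi_mean[1])
})
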