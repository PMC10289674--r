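# Synthetic data with known ground truth, used for estimator validation.

#' Gaussian-pair synthetic data
#'
#' Generates a single "spike time" per trial coupled to a 2-column matrix
#' of "motor PC scores" through correlated Gaussians: the time T is a
#' common latent factor and each score is `rho * T + sqrt(1 - rho^2) *
#' noise` (all scaled to mean `mu`, standard deviation `sigma`), so the
#' time-score correlation is `rho` for both scores and the score-score
#' correlation is `rho^2`. The joint distribution is trivariate normal, so
#' the true MI is available in closed form:
#' `I(T; M) = 0.5 * log2((1 + rho^2) / (1 - rho^2))`.
#'
#' @param n Number of trials (default 2500).
#' @param rho Time-score correlation, |rho| < 1 (reference range 0.5-0.9).
#' @param mu Mean (default 0).
#' @param sigma Standard deviation (default 2).
#' @param seed RNG seed.
#' @return A list with `spikes` ([spike_matrix()] with one spike per
#'   trial), `motor` ([motor_scores()]), `true_mi_bits`, and
#'   `sample_correlations` (empirical time-score correlations).
#' @export
gaussian_pair <- function(n = 2500L, rho = 0.9, mu = 0, sigma = 2,
                          seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 10L) abort("config error: `n` must be >= 10")
  if (!is.numeric(rho) || abs(rho) >= 1) abort("config error: |rho| must be < 1")
  if (!is.numeric(sigma) || sigma <= 0) abort("config error: `sigma` must be > 0")
  dat <- withr::with_seed(seed, {
    t0 <- rnorm(n)
    m1 <- rho * t0 + sqrt(1 - rho^2) * rnorm(n)
    m2 <- rho * t0 + sqrt(1 - rho^2) * rnorm(n)
    list(t = mu + sigma * t0, m = cbind(mu + sigma * m1, mu + sigma * m2))
  })
  spikes <- spike_matrix(matrix(dat$t, ncol = 1L))
  motor <- motor_scores(dat$m)
  list(spikes = spikes, motor = motor,
       true_mi_bits = 0.5 * log2((1 + rho^2) / (1 - rho^2)),
       sample_correlations = c(stats::cor(dat$t, dat$m[, 1L]),
                               stats::cor(dat$t, dat$m[, 2L])))
}

#' Moth-like multi-spike synthetic data
#'
#' Emulates the structure of a spike-resolved flight motor program: each
#' trial (wing stroke, period ~45 ms) draws a spike count from
#' `count_probs`, standard-normal motor scores, and spike times placed at
#' count-specific baseline phases spread across the trial window with a
#' Gaussian component of spread `sigma_t` that is correlated
#' (`timing_rho`) with a combination of the two motor scores. With
#' `timing_rho = 0` the timing terms of the MI decomposition vanish; with
#' strong coupling the MI degrades as spike times are corrupted.
#'
#' @param n Number of trials.
#' @param count_probs Named or plain probability vector over per-trial
#'   spike counts 1..length(count_probs) (support up to 6).
#' @param timing_rho Coupling of each spike time to the motor scores,
#'   |timing_rho| < 1.
#' @param window Trial window `c(t_min, t_max)` in ms.
#' @param sigma_t Per-spike timing spread in ms.
#' @param seed RNG seed.
#' @return A list with `spikes`, `motor`, and the generating parameters.
#' @export
moth_like <- function(n = 2500L,
                      count_probs = c(0.30, 0.30, 0.20, 0.15, 0.05),
                      timing_rho = 0.9,
                      window = c(0, 45),
                      sigma_t = 3,
                      seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 10L) abort("config error: `n` must be >= 10")
  if (length(count_probs) < 1L || length(count_probs) > 6L ||
      any(count_probs < 0) || abs(sum(count_probs) - 1) > 1e-8)
    abort("config error: `count_probs` must be probabilities over counts 1-6")
  if (abs(timing_rho) >= 1) abort("config error: |timing_rho| must be < 1")
  if (length(window) != 2L || window[2L] <= window[1L])
    abort("config error: `window` bounds must be ordered")
  max_c <- length(count_probs)
  dat <- withr::with_seed(seed, {
    cc <- sample.int(max_c, n, replace = TRUE, prob = count_probs)
    M <- matrix(rnorm(2L * n), ncol = 2L)
    u <- (M[, 1L] + M[, 2L]) / sqrt(2) # standard-normal score combination
    times <- matrix(NA_real_, nrow = n, ncol = max_c)
    span <- window[2L] - window[1L]
    for (i in seq_len(n)) {
      ci <- cc[i]
      base <- window[1L] + (seq_len(ci) - 0.5) / ci * span
      dev <- sigma_t * (timing_rho * u[i] +
                          sqrt(1 - timing_rho^2) * rnorm(ci))
      times[i, seq_len(ci)] <- base + dev
    }
    list(times = sort_spike_rows(times), M = M)
  })
  list(spikes = spike_matrix(dat$times),
       motor = motor_scores(dat$M),
       count_probs = count_probs, timing_rho = timing_rho,
       window = window, sigma_t = sigma_t)
}

#' Fix spike-time precision by rounding
#'
#' Imposes a known ground-truth temporal precision on a data set by
#' rounding every spike time to the nearest multiple of `resolution` ms.
#' Idempotent at a fixed resolution; the missing-spike pattern is
#' unchanged.
#'
#' @param spikes A [spike_matrix()].
#' @param resolution Ground-truth precision in ms (> 0).
#' @return A [spike_matrix()] with rounded times.
#' @export
fix_precision <- function(spikes, resolution) {
  stopifnot(inherits(spikes, "spike_matrix"))
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    abort("config error: `resolution` must be a single positive number")
  tm <- spikes$times
  present <- !is.na(tm)
  tm[present] <- resolution * round(tm[present] / resolution)
  out <- spikes
  out$times <- tm
  out
}

#' Synthetic periodic force/torque recording
#'
#' Builds a raw 10 kHz flight-like recording for exercising the
#' segmentation stage: a vertical-force trace `fz` with one dominant
#' downward peak per cycle (a downward von-Mises-shaped bump at mid-cycle)
#' plus Gaussian noise, and a yaw-torque trace `tau_z` whose per-cycle
#' waveform is a random combination of two latent harmonics (so its
#' cycle-to-cycle variation is exactly two-dimensional before noise).
#' Ground-truth cycle boundaries (the sample of peak downward force in
#' each cycle) are returned.
#'
#' @param n_cycles Number of cycles.
#' @param period_ms Cycle period in ms; a warning is issued outside the
#'   5-35 Hz band (28.6-200 ms) where the segmentation band-pass filter
#'   operates.
#' @param noise_sd Gaussian noise standard deviation added to both traces.
#' @param seed RNG seed.
#' @return A list with `fz`, `tau_z` (numeric traces), `fs_hz` (10000),
#'   `zero_points` (ground-truth boundary sample indices),
#'   `latent_coefs` (n_cycles x 2 matrix) and `period_samples`.
#' @export
raw_flight_signal <- function(n_cycles = 30L, period_ms = 40,
                              noise_sd = 0.02, seed = 1L) {
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 3L) abort("need at least 3 cycles")
  freq <- 1000 / period_ms
  if (freq < 5 || freq > 35)
    warn(sprintf("period %.3g ms (%.3g Hz) is outside the 5-35 Hz passband; segmentation will degrade", period_ms, freq))
  sp <- period_ms * 10 # samples per cycle at 10 kHz
  len <- round(n_cycles * sp)
  t_idx <- seq_len(len) - 1L
  theta <- 2 * pi * t_idx / sp
  # downward force peak at theta = pi (+ 2*pi*k): cycle k's peak at
  # (k+0.5)*period; a dominant fundamental plus a modest second harmonic
  # gives the peaked, asymmetric shape of a real force trace while staying
  # concentrated inside the segmentation passband
  fz_shape <- -0.8 * cos(theta - pi) - 0.2 * cos(2 * (theta - pi))
  zero_points <- round((seq_len(n_cycles) - 0.5) * sp)
  dat <- withr::with_seed(seed, {
    coefs <- matrix(rnorm(2L * n_cycles), ncol = 2L)
    # latent coefficients switch at the downward-force peaks, i.e. at the
    # boundaries the segmentation stage recovers, so each segmented window
    # carries exactly one coefficient pair
    cyc <- pmin(findInterval(t_idx + 1L, zero_points) + 1L, n_cycles)
    s <- (t_idx + 1L) - zero_points[pmax(cyc - 1L, 1L)]
    phase <- 2 * pi * s / sp
    tau <- coefs[cyc, 1L] * sin(phase) + coefs[cyc, 2L] * sin(2 * phase)
    list(fz = fz_shape + rnorm(len, sd = noise_sd),
         tau = tau + rnorm(len, sd = noise_sd),
         coefs = coefs)
  })
  list(fz = dat$fz, tau_z = dat$tau, fs_hz = 10000,
       zero_points = zero_points, latent_coefs = dat$coefs,
       period_samples = sp)
}
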