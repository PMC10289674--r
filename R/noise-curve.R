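#' Corrupt spike times with uniform noise
#'
#' Shifts every spike time by an independent draw from U(0, r_c). The noise
#' is one-sided; the constant mean shift r_c/2 it induces is immaterial to
#' mutual information. The missing-spike pattern is unchanged and rows are
#' re-sorted ascending after corruption.
#'
#' @param spikes A [spike_matrix()].
#' @param r_c Noise width in ms (>= 0); 0 returns the input unchanged.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return A [spike_matrix()] with corrupted times.
#' @export
corrupt_spikes <- function(spikes, r_c, seed = NULL) {
  stopifnot(inherits(spikes, "spike_matrix"))
  if (!is.numeric(r_c) || length(r_c) != 1L || is.na(r_c) || r_c < 0)
    abort("config error: `r_c` must be a single number >= 0")
  if (r_c == 0) return(spikes)
  draw <- function() {
    tm <- spikes$times
    present <- !is.na(tm)
    tm[present] <- tm[present] + runif(sum(present), 0, r_c)
    out <- spikes
    out$times <- sort_spike_rows(tm)
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Zero-noise MI uncertainty by data fractioning
#'
#' Splits the trials into f disjoint random subsets for f = 2, 3, 4, 5,
#' computes the decomposed MI on each subset, and takes the standard
#' deviation across subsets at each f. Fitting the scaling law
#' `std(n) = A / sqrt(n)` to these points by least squares and evaluating
#' the fit at the full sample size gives the uncertainty of the zero-noise
#' MI estimate.
#'
#' @param spikes A [spike_matrix()] (or a [pair_dataset()] handle).
#' @param motor A [motor_scores()]; ignored if `spikes` is a pair.
#' @param k Neighbour count.
#' @param fractions Fraction counts to use (default 2:5).
#' @param seed Seed for the random subset assignment.
#' @param min_class_size Passed to [timing_mi_decomposed()].
#' @return Uncertainty in bits (non-negative scalar) with attribute
#'   `"fit"`: a tibble of (fraction, subset size, std).
#' @export
data_fraction_uncertainty <- function(spikes, motor = NULL, k = 4L,
                                      fractions = 2:5, seed = 1L,
                                      min_class_size = max(k + 2L, 10L)) {
  if (inherits(spikes, "spike_motor_pair")) {
    motor <- spikes$motor
    spikes <- spikes$spikes
  }
  n <- n_trials(spikes)
  if (n < 40L) abort("data fractioning needs at least 40 trials")
  floor_n <- k + 2L
  rows <- withr::with_seed(derive_seed(seed, "fractions"), {
    purrr::map(fractions, function(f) {
      grp <- sample(rep_len(seq_len(f), n))
      sizes <- tabulate(grp, f)
      if (min(sizes) < max(floor_n, min_class_size)) return(NULL)
      mis <- vapply(seq_len(f), function(g) {
        idx <- which(grp == g)
        sub_sp <- spike_matrix(spikes$times[idx, , drop = FALSE],
                               resolution = spikes$resolution)
        sub_mo <- motor_scores(motor$scores[idx, , drop = FALSE])
        tryCatch(
          timing_mi_decomposed(sub_sp, sub_mo, k = k,
                               min_class_size = min_class_size)$value,
          error = function(e) NA_real_)
      }, numeric(1))
      if (anyNA(mis)) return(NULL)
      tibble(f = f, n_sub = mean(sizes), mi_std = sd(mis))
    }) |> dplyr::bind_rows()
  })
  if (nrow(rows) == 0L)
    abort("all fraction counts skipped: subsets below the estimator floor")
  # least squares for std = A / sqrt(n):  A = sum(s*x) / sum(x^2), x = 1/sqrt(n)
  x <- 1 / sqrt(rows$n_sub)
  A <- sum(rows$mi_std * x) / sum(x^2)
  out <- max(A / sqrt(n), 0)
  attr(out, "fit") <- rows
  out
}

#' MI degradation curve under progressive noise corruption
#'
#' The core of the continuous method. For each non-zero noise width r_c in
#' the configured grid, the spike times are independently corrupted
#' `n_noise_reps` times with U(0, r_c) noise and the decomposed MI
#' ([timing_mi_decomposed()]) is estimated for each corruption; the mean
#' and standard deviation over repetitions are recorded. At r_c = 0 a
#' single deterministic estimate is made and its uncertainty is taken from
#' [data_fraction_uncertainty()].
#'
#' @param spikes A [spike_matrix()] (or a [pair_dataset()] handle).
#' @param motor A [motor_scores()]; ignored if `spikes` is a pair.
#' @param config A [run_config()].
#' @return A tibble of class `noise_curve` with columns `r_c_ms`,
#'   `mi_mean`, `mi_std`, `n_reps`, and attributes `zero_noise_mi`,
#'   `zero_noise_std`, `count_term`, `config`.
#' @export
noise_curve <- function(spikes, motor = NULL, config = run_config()) {
  if (inherits(spikes, "spike_motor_pair")) {
    motor <- spikes$motor
    spikes <- spikes$spikes
  }
  stopifnot(inherits(spikes, "spike_matrix"), inherits(motor, "motor_scores"),
            inherits(config, "run_config"))
  grid <- config$noise_grid
  k <- config$k
  n_reps <- config$n_noise_reps
  if (n_reps == 1L) warn("n_noise_reps = 1: per-level std reported as 0")

  zero_est <- timing_mi_decomposed(spikes, motor, k = k)
  zero_std <- data_fraction_uncertainty(spikes, motor, k = k,
                                        seed = config$seed)
  # motor side, class membership and count term are invariant under
  # corruption: prepare once, re-evaluate only the spike-time side per rep
  prep <- prepare_decomposition(spikes, motor, k,
                                min_class_size = max(k + 2L, 10L),
                                jitter_seed = 760813L)

  level <- function(gi) {
    r_c <- grid[gi]
    mis <- vapply(seq_len(n_reps), function(rep) {
      sp <- corrupt_spikes(spikes, r_c,
                           seed = derive_seed(config$seed, "noise", gi, rep))
      tryCatch(
        decomposed_mi_value(sp$times, prep),
        error = function(e) abort(sprintf(
          "estimator failed at r_c = %.4g ms (rep %d): %s",
          r_c, rep, conditionMessage(e))))
    }, numeric(1))
    tibble(r_c_ms = r_c, mi_mean = mean(mis),
           mi_std = if (n_reps > 1L) sd(mis) else 0,
           n_reps = n_reps)
  }
  nz <- purrr::map(seq_along(grid)[-1L], level) |> dplyr::bind_rows()
  out <- dplyr::bind_rows(
    tibble(r_c_ms = 0, mi_mean = zero_est$value, mi_std = as.numeric(zero_std),
           n_reps = 1L),
    nz)
  attr(out, "zero_noise_mi") <- zero_est$value
  attr(out, "zero_noise_std") <- as.numeric(zero_std)
  attr(out, "count_term") <- zero_est$count_term
  attr(out, "config") <- config
  class(out) <- c("noise_curve", class(out))
  out
}

#' Rebuild a noise_curve object from plain columns
#'
#' Used to construct curve fixtures or re-attach metadata after reading an
#' exported CSV.
#'
#' @param r_c_ms,mi_mean,mi_std Equal-length numeric vectors (first level
#'   must be r_c = 0).
#' @param zero_noise_std Uncertainty of the zero-noise estimate (bits).
#' @param n_reps Repetitions per level.
#' @return A `noise_curve` tibble.
#' @export
as_noise_curve <- function(r_c_ms, mi_mean, mi_std = rep(0, length(r_c_ms)),
                           zero_noise_std = 0, n_reps = 1L) {
  stopifnot(length(r_c_ms) == length(mi_mean),
            length(mi_std) == length(mi_mean),
            r_c_ms[1L] == 0, !is.unsorted(r_c_ms, strictly = TRUE),
            all(mi_std >= 0))
  out <- tibble(r_c_ms = r_c_ms, mi_mean = mi_mean, mi_std = mi_std,
                n_reps = n_reps)
  attr(out, "zero_noise_mi") <- mi_mean[1L]
  attr(out, "zero_noise_std") <- zero_noise_std
  class(out) <- c("noise_curve", class(out))
  out
}

#' @export
tidy.noise_curve <- function(x, ...) {
  tibble(r_c_ms = x$r_c_ms, mi_mean = x$mi_mean, mi_std = x$mi_std,
         n_reps = x$n_reps)
}

#' @export
glance.noise_curve <- function(x, ...) {
  tibble(zero_noise_mi = attr(x, "zero_noise_mi"),
         zero_noise_std = attr(x, "zero_noise_std"),
         n_levels = nrow(x) - 1L,
         n_reps = max(x$n_reps),
         mi_floor = x$mi_mean[nrow(x)])
}

#' Export a noise curve as CSV
#' @param curve A `noise_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_noise_curve <- function(curve, path) {
  utils::write.csv(
    data.frame(r_c_ms = curve$r_c_ms, mi_mean_bits = curve$mi_mean,
               mi_std_bits = curve$mi_std),
    path, row.names = FALSE)
  invisible(path)
}
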