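#' Log-spaced noise grid
#'
#' Builds the default corruption grid: 0 followed by `n` log-spaced uniform
#' noise widths between `from` and `to` ms. The lower end defaults to
#' 0.1 ms, the sampling resolution of a 10 kHz recording, which is the hard
#' floor on resolvable precision.
#'
#' @param n Number of non-zero levels (default 60, enough for the two-line
#'   selection rule which fits the first and last 30 levels).
#' @param from,to Grid limits in ms.
#' @return Numeric vector of length `n + 1` starting at 0.
#' @export
noise_grid_default <- function(n = 60, from = 0.1, to = 32) {
  c(0, exp(seq(log(from), log(to), length.out = n)))
}

#' Run configuration
#'
#' Collects the tunable parameters shared by the estimators. Defaults follow
#' the method's reference settings: `k = 4` neighbours, 150 noise
#' repetitions per level, spike-word bin counts 1-70, 3 motor partitions per
#' PC (9 joint states), at least 10 shuffles for the bias correction.
#'
#' @param k Neighbour count for the KSG estimator (integer >= 1).
#' @param n_noise_reps Repetitions per non-zero noise level.
#' @param noise_grid Ascending vector of uniform-noise widths r_c in ms;
#'   must start at 0.
#' @param n_shuffles Number of label shuffles for the discrete bias
#'   correction (>= 10).
#' @param b_s_range Integer vector of spike-word bin counts.
#' @param b_m Motor partitions per PC.
#' @param seed RNG seed; every source of randomness in a run flows from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(k = 4L,
                       n_noise_reps = 150L,
                       noise_grid = noise_grid_default(),
                       n_shuffles = 10L,
                       b_s_range = 1:70,
                       b_m = 3L,
                       seed = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort("`k` must be an integer >= 1")
  n_noise_reps <- as.integer(n_noise_reps)
  if (is.na(n_noise_reps) || n_noise_reps < 1L)
    abort("`n_noise_reps` must be a positive integer")
  if (length(noise_grid) < 1L || noise_grid[1L] != 0 ||
      is.unsorted(noise_grid, strictly = TRUE) || any(noise_grid < 0))
    abort("`noise_grid` must be strictly ascending, start at 0, all >= 0")
  n_shuffles <- as.integer(n_shuffles)
  if (is.na(n_shuffles) || n_shuffles < 10L)
    abort("`n_shuffles` must be >= 10")
  b_s_range <- as.integer(b_s_range)
  if (any(is.na(b_s_range)) || any(b_s_range < 1L))
    abort("`b_s_range` must be integers >= 1")
  b_m <- as.integer(b_m)
  if (is.na(b_m) || b_m < 1L) abort("`b_m` must be an integer >= 1")
  seed <- as.integer(seed)
  if (is.na(seed)) abort("`seed` must be an integer")
  structure(list(k = k, n_noise_reps = n_noise_reps, noise_grid = noise_grid,
                 n_shuffles = n_shuffles, b_s_range = b_s_range, b_m = b_m,
                 seed = seed),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<run_config> k=%d, %d reps/level, %d noise levels (%.3g-%.3g ms),\n",
    "  b_s %d-%d, b_m=%d, %d shuffles, seed=%d\n"),
    x$k, x$n_noise_reps, length(x$noise_grid) - 1L,
    min(x$noise_grid[-1L]), max(x$noise_grid), min(x$b_s_range),
    max(x$b_s_range), x$b_m, x$n_shuffles, x$seed))
  invisible(x)
}

#' Read / write a run configuration as JSON
#' @param path JSON file path.
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[intersect(names(x), names(formals(run_config)))])
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Derive a child seed from a run seed and a stage label, keeping the result
# a valid 32-bit integer. Deterministic, stage-separated RNG streams.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}
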