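# Cycle segmentation of periodic force/torque recordings and per-cycle PCA.

#' Band-pass filter a vertical-force trace
#'
#' Zero-phase application of an 8th-order Butterworth band-pass between 5
#' and 35 Hz, bracketing typical wing-beat frequencies. The filter is
#' applied in the frequency domain with the exact forward-backward
#' Butterworth magnitude response (and reflection padding against
#' wrap-around): a 5-35 Hz band at a 10 kHz rate puts recursive
#' transfer-function realisations on the edge of numerical stability,
#' while the spectral form is exact, stable, and phase-free so cycle zero
#' points are not shifted.
#'
#' @param fz Numeric trace sampled at `fs_hz`.
#' @param fs_hz Sampling rate in Hz (default 10000).
#' @param band Passband in Hz.
#' @param order Band-pass filter order (even; the analog prototype has
#'   order `order/2`).
#' @return Filtered numeric trace of the same length.
#' @export
bandpass_fz <- function(fz, fs_hz = 10000, band = c(5, 35), order = 8L) {
  x <- as.numeric(fz)
  n <- length(x)
  if (n < 100L) abort("trace too short for the band-pass filter warm-up")
  if (order %% 2L != 0L) abort("`order` must be even for a band-pass")
  pad <- min(n - 1L, fs_hz) # up to one second of reflection padding
  xp <- c(2 * x[1L] - rev(x[seq_len(pad) + 1L]), x,
          2 * x[n] - rev(x[seq.int(n - pad, n - 1L)]))
  N <- length(xp)
  f <- (seq_len(N) - 1) / N
  f <- pmin(f, 1 - f) * fs_hz
  # bilinear-prewarped band-pass frequency transformation
  W <- tan(pi * f / fs_hz)
  W1 <- tan(pi * band[1L] / fs_hz)
  W2 <- tan(pi * band[2L] / fs_hz)
  u <- (W^2 - W1 * W2) / (W * (W2 - W1))
  u[!is.finite(u)] <- Inf
  mag2 <- 1 / (1 + u^order) # |H|^2: one forward + one backward pass
  Re(fft(fft(xp) * mag2, inverse = TRUE) / N)[pad + seq_len(n)]
}

# analytic signal via FFT: zero negative frequencies, double positive ones
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Segment a filtered trace into cycles by Hilbert phase
#'
#' Computes the instantaneous phase of the analytic signal and places one
#' zero point per cycle at a fixed reference phase. The reference defaults
#' to the phase at the global minimum of the filtered trace, i.e.
#' approximately the peak downward force.
#'
#' @param filtered_fz Band-passed trace (see [bandpass_fz()]).
#' @param ref_phase Reference phase in radians, or `NULL` to use the
#'   circular mean of the instantaneous phase over the trace's interior
#'   local minima (approximately the peak downward force; robust to filter
#'   edge artifacts).
#' @return An object of class `cycle_segmentation`: list with
#'   `zero_points` (sample indices, strictly increasing), `L` (samples in
#'   the shortest cycle), and `n_cycles`.
#' @export
segment_cycles <- function(filtered_fz, ref_phase = NULL) {
  x <- as.numeric(filtered_fz)
  if (is.na(sd(x)) || sd(x) == 0) abort("constant signal cannot be segmented")
  # odd-reflection padding keeps the analytic-signal edge distortion out of
  # the first and last cycles
  nx <- length(x)
  pad <- min(nx - 1L, 5000L)
  xp <- c(2 * x[1L] - rev(x[seq_len(pad) + 1L]), x,
          2 * x[nx] - rev(x[seq.int(nx - pad, nx - 1L)]))
  phase <- Arg(analytic_signal(xp))[pad + seq_len(nx)]
  if (is.null(ref_phase)) {
    n <- length(x)
    i <- 2:(n - 1L)
    mins <- i[x[i] < x[i - 1L] & x[i] <= x[i + 1L]]
    mins <- mins[mins > 0.05 * n & mins < 0.95 * n] # avoid edge artifacts
    if (!length(mins)) mins <- which.min(x)
    ref_phase <- Arg(mean(exp(1i * phase[mins])))
  }
  # unwrap, then find crossings of ref_phase + 2*pi*k
  dp <- diff(phase)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  unwrapped <- cumsum(c(phase[1L], dp))
  rel <- (unwrapped - ref_phase) / (2 * pi)
  ks <- seq(ceiling(min(rel)), floor(max(rel)))
  zero_points <- vapply(ks, function(k) {
    j <- which(rel[-length(rel)] <= k & rel[-1L] > k)
    if (!length(j)) return(NA_real_)
    j <- j[1L]
    # linear interpolation between samples, rounded to the nearest sample
    round(j + (k - rel[j]) / (rel[j + 1L] - rel[j]))
  }, numeric(1))
  zero_points <- sort(unique(zero_points[!is.na(zero_points)]))
  if (length(zero_points) < 3L)
    abort("fewer than 3 cycles detected")
  L <- min(diff(zero_points))
  structure(list(zero_points = as.integer(zero_points), L = as.integer(L),
                 n_cycles = length(zero_points)),
            class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf("<cycle_segmentation> %d cycles, shortest %d samples\n",
              x$n_cycles, x$L))
  invisible(x)
}

#' Per-cycle torque PCA
#'
#' Stacks the length-L torque window starting at each zero point into an
#' N x L matrix (cycles whose window would run past the end of the trace
#' are dropped), performs centred PCA, and returns the scores on the first
#' two components as a [motor_scores()] object. Loadings are
#' sign-normalised so that each loading's largest-magnitude element is
#' positive.
#'
#' @param tau_z Torque trace aligned with the segmented force trace.
#' @param seg A [segment_cycles()] result.
#' @return A list with `motor` ([motor_scores()]), `loadings` (L x 2),
#'   `explained_variance` (fraction per retained component),
#'   `total_variance`, and `cycles_used`.
#' @export
torque_pca <- function(tau_z, seg) {
  stopifnot(inherits(seg, "cycle_segmentation"))
  tau_z <- as.numeric(tau_z)
  if (seg$L < 2L) abort("shortest cycle has fewer than 2 samples")
  ok <- seg$zero_points + seg$L - 1L <= length(tau_z)
  zp <- seg$zero_points[ok]
  if (length(zp) < 3L) abort("fewer than 3 complete cycles for PCA")
  W <- t(vapply(zp, function(z) tau_z[z:(z + seg$L - 1L)],
                numeric(seg$L)))
  pc <- prcomp(W, center = TRUE, scale. = FALSE)
  load2 <- pc$rotation[, 1:2, drop = FALSE]
  flip <- vapply(1:2, function(j) {
    v <- load2[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  load2 <- sweep(load2, 2L, flip, "*")
  scores <- sweep(pc$x[, 1:2, drop = FALSE], 2L, flip, "*")
  evar <- pc$sdev^2
  list(motor = motor_scores(scores),
       loadings = load2,
       explained_variance = evar[1:2] / sum(evar),
       total_variance = sum(evar),
       cycles_used = which(ok))
}

#' Align raw spike sample indices to segmented cycles
#'
#' Assigns each spike (a sample index into the recording) to the cycle
#' whose window contains it and converts it to a within-cycle time in ms
#' relative to the cycle zero point. Windows run from one zero point to
#' the next; the last zero point's window extends by the median cycle
#' length. Spikes outside all windows are dropped with a message.
#'
#' @param spike_samples Integer sample indices of detected spikes.
#' @param seg A [segment_cycles()] result.
#' @param fs_hz Sampling rate in Hz (default 10000, i.e. 0.1 ms/sample).
#' @return A [spike_matrix()] with one row per cycle.
#' @export
align_spikes <- function(spike_samples, seg, fs_hz = 10000) {
  stopifnot(inherits(seg, "cycle_segmentation"))
  zp <- seg$zero_points
  bounds <- c(zp, zp[length(zp)] + round(median(diff(zp))))
  cyc <- findInterval(spike_samples, bounds)
  inside <- cyc >= 1L & cyc <= length(zp)
  if (any(!inside))
    message(sprintf("%d spike(s) outside all cycle windows dropped",
                    sum(!inside)))
  ms_per_sample <- 1000 / fs_hz
  times_by_cycle <- lapply(seq_along(zp), function(k) {
    s <- spike_samples[inside & cyc == k]
    sort((s - zp[k]) * ms_per_sample)
  })
  jmax <- max(1L, max(lengths(times_by_cycle)))
  tm <- t(vapply(times_by_cycle, function(v)
    c(v, rep(NA_real_, jmax - length(v))), numeric(jmax)))
  if (jmax == 1L) tm <- matrix(tm, ncol = 1L)
  spike_matrix(tm, resolution = ms_per_sample)
}
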