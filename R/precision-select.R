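# Precision-selection rules applied to an MI-vs-noise curve.

new_precision_estimate <- function(method, value, grid_or_bins, diagnostics) {
  out <- tibble(method = method,
                value_ms = value,
                resolved = is.finite(value),
                diagnostics = list(diagnostics))
  attr(out, "grid_or_bins") <- grid_or_bins
  class(out) <- c("precision_estimate", class(out))
  out
}

#' @export
print.precision_estimate <- function(x, ...) {
  v <- if (x$resolved[1L]) sprintf("%.3g ms", x$value_ms[1L]) else "unresolved"
  cat(sprintf("<precision_estimate> %s (%s method)\n", v, x$method[1L]))
  invisible(x)
}

#' @export
glance.precision_estimate <- function(x, ...) {
  tibble(method = x$method, value_ms = x$value_ms, resolved = x$resolved)
}

#' Precision by the zero-noise standard-deviation threshold
#'
#' The reference selection rule: precision is the smallest noise width
#' whose mean MI falls below the lower bound of the zero-noise estimate
#' (zero-noise MI minus its data-fraction uncertainty). Unresolved if the
#' curve never crosses the threshold.
#'
#' @param curve A [noise_curve()].
#' @return A one-row `precision_estimate` tibble (`value_ms` is `NA` when
#'   unresolved).
#' @export
precision_std <- function(curve) {
  stopifnot(inherits(curve, "noise_curve"))
  thr <- attr(curve, "zero_noise_mi") - attr(curve, "zero_noise_std")
  nz <- curve[curve$r_c_ms > 0, ]
  hit <- which(nz$mi_mean < thr)
  value <- if (length(hit)) nz$r_c_ms[min(hit)] else NA_real_
  new_precision_estimate(
    "std_threshold", value, range(curve$r_c_ms),
    list(threshold = thr, crossing_index = if (length(hit)) min(hit) else NA))
}

# Second derivative of noisy samples on a possibly non-uniform grid, by
# local quadratic least squares (Savitzky-Golay style) over a window of
# +/- `half_window` points. With half_window = 1 this is the exact
# three-point finite-difference stencil; wider windows damp the h^-2 noise
# amplification that raw differencing suffers on estimated MI curves.
# Returns values at the interior points 2..(n-1).
second_deriv_local_quad <- function(x, y, half_window = 1L) {
  n <- length(x)
  vapply(2:(n - 1L), function(i) {
    lo <- max(1L, i - half_window)
    hi <- min(n, i + half_window)
    dx <- x[lo:hi] - x[i]
    X <- cbind(1, dx, dx^2)
    cf <- qr.coef(qr(X), y[lo:hi])
    2 * cf[3L]
  }, numeric(1))
}

# peak prominence: height above the higher of the two valley floors on the
# paths toward higher ground (or the series boundary)
peak_prominence <- function(y, idx) {
  left <- y[seq_len(idx - 1L)]
  right <- y[seq.int(idx + 1L, length(y))]
  base_side <- function(v) {
    higher <- which(v > y[idx])
    if (length(higher)) {
      # v is ordered moving away from the peak in callers below
      min(v[seq_len(min(higher))])
    } else if (length(v)) min(v) else y[idx]
  }
  y[idx] - max(base_side(rev(left)), base_side(right))
}

#' Precision by the peak of the second derivative
#'
#' Locates the shoulder of the MI curve: the second derivative of mean MI
#' with respect to log10(r_c) is computed by finite differences over the
#' non-zero noise levels, negated (so that the onset of the MI drop is a
#' peak) and normalised to a maximum of 1. The precision is the noise width
#' at the highest peak satisfying a minimum-amplitude and a prominence
#' requirement; unresolved if no peak qualifies.
#'
#' @param curve A [noise_curve()].
#' @param min_amplitude Minimum normalised peak height (default 0.1).
#' @param min_prominence Minimum normalised prominence (default 0.05).
#' @param half_window Half-width (in grid points) of the local quadratic
#'   fit used to estimate the second derivative; defaults to roughly a
#'   fifteenth of the grid so the smoothing scale tracks the grid density.
#' @return A one-row `precision_estimate`.
#' @export
precision_derivative <- function(curve, min_amplitude = 0.1,
                                 min_prominence = 0.05,
                                 half_window = NULL) {
  stopifnot(inherits(curve, "noise_curve"))
  nz <- curve[curve$r_c_ms > 0, ]
  if (nrow(nz) < 5L) abort("derivative method needs at least 5 grid points")
  if (is.null(half_window)) half_window <- max(1L, nrow(nz) %/% 15L)
  x <- log10(nz$r_c_ms)
  d2 <- -second_deriv_local_quad(x, nz$mi_mean, half_window)
  scale <- max(abs(d2))
  # a curvature indistinguishable from zero at the curve's own scale would
  # only normalise floating-point noise
  if (scale <= 1e-6 * max(diff(range(nz$mi_mean)), .Machine$double.eps))
    return(new_precision_estimate("derivative", NA_real_,
                                  range(curve$r_c_ms), list(reason = "flat")))
  d2n <- d2 / scale
  interior <- seq_along(d2n)
  is_peak <- vapply(interior, function(i) {
    lo <- if (i > 1L) d2n[i - 1L] else -Inf
    hi <- if (i < length(d2n)) d2n[i + 1L] else -Inf
    d2n[i] > lo && d2n[i] >= hi
  }, logical(1))
  cand <- which(is_peak & d2n >= min_amplitude)
  cand <- cand[vapply(cand, function(i)
    peak_prominence(d2n, i) >= min_prominence, logical(1))]
  if (!length(cand))
    return(new_precision_estimate("derivative", NA_real_,
                                  range(curve$r_c_ms),
                                  list(reason = "no qualifying peak")))
  best <- cand[which.max(d2n[cand])]
  # d2 is defined on interior points 2..(n-1) of the non-zero grid
  value <- nz$r_c_ms[best + 1L]
  new_precision_estimate("derivative", value, range(curve$r_c_ms),
                         list(peak_index = best, peak_height = d2n[best]))
}

#' Precision by two-line intersection
#'
#' Treats the MI drop as a phase transition: least-squares lines are fit to
#' the approximately linear low-noise and high-noise ends of the curve (the
#' first and last 30 non-zero levels, in log10(r_c) coordinates, matching
#' the logarithmic noise grids the curves are computed on) and the
#' precision is the noise width at their intersection. Unresolved if the
#' lines are parallel or the intersection falls outside the grid span.
#'
#' @param curve A [noise_curve()].
#' @param n_fit Number of levels in each end fit (default 30).
#' @return A one-row `precision_estimate`.
#' @export
precision_twoline <- function(curve, n_fit = 30L) {
  stopifnot(inherits(curve, "noise_curve"))
  nz <- curve[curve$r_c_ms > 0, ]
  if (nrow(nz) < 2L * n_fit)
    abort(sprintf(
      "config error: two-line method needs >= %d non-zero noise levels, got %d",
      2L * n_fit, nrow(nz)))
  x <- log10(nz$r_c_ms)
  y <- nz$mi_mean
  lo <- seq_len(n_fit)
  hi <- seq.int(nrow(nz) - n_fit + 1L, nrow(nz))
  f1 <- coef(lm(y[lo] ~ x[lo]))
  f2 <- coef(lm(y[hi] ~ x[hi]))
  slopes <- c(f1[2L], f2[2L])
  diag <- list(low_line = unname(f1), high_line = unname(f2))
  if (!all(is.finite(slopes)) || abs(diff(slopes)) < 1e-12)
    return(new_precision_estimate("two_line", NA_real_, range(curve$r_c_ms),
                                  c(diag, reason = "parallel lines")))
  x_star <- (f1[[1L]] - f2[[1L]]) / (f2[[2L]] - f1[[2L]])
  value <- 10^x_star
  if (x_star < min(x) || x_star > max(x))
    return(new_precision_estimate("two_line", NA_real_, range(curve$r_c_ms),
                                  c(diag, reason = "intersection outside grid")))
  new_precision_estimate("two_line", value, range(curve$r_c_ms), diag)
}
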