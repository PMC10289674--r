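#' Spike matrix: per-trial spike times
#'
#' A spike matrix holds the within-trial (e.g. within-wing-stroke) spike
#' times of one motor unit, one row per trial, one column per spike slot.
#' Trials with fewer spikes than the widest trial are padded with `NA`.
#' Times are in milliseconds relative to the trial's zero-phase point;
#' negative times (spikes before the alignment point) are allowed.
#'
#' Rows are normalised so that non-missing times occupy a sorted prefix of
#' each row; a warning is issued if the input required re-sorting.
#'
#' @param x A numeric matrix or data frame, one row per trial, `NA` (or, in
#'   files, an empty cell) marking absent spikes.
#' @param resolution Sampling resolution of the source recording in ms per
#'   sample (default 0.1, i.e. a 10 kHz recording).
#' @return An object of class `spike_matrix`: a list with elements
#'   `times` (N x J_max numeric matrix), `counts` (per-trial spike counts),
#'   `max_count`, and `resolution`.
#' @examples
#' sm <- spike_matrix(rbind(c(10, 25.5), c(12.1, NA)))
#' sm$counts
#' @export
spike_matrix <- function(x, resolution = 0.1) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  if (nrow(x) == 0L) abort("no trials: spike matrix has zero rows")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    abort("`resolution` must be a single positive number (ms per sample)")
  if (any(is.infinite(x))) abort("spike times must be finite or NA")
  # normalise each row: sorted non-NA prefix
  norm <- sort_spike_rows(x)
  if (ncol(x) > 1L) {
    resorted <- any(vapply(seq_len(nrow(x)), function(i) {
      v <- x[i, ]
      is.unsorted(v[!is.na(v)])
    }, logical(1)))
    if (resorted) warn("spike times re-sorted ascending within trials")
  }
  counts <- rowSums(!is.na(norm))
  max_count <- if (all(counts == 0)) 0L else max(counts)
  # drop all-NA trailing columns beyond the widest trial
  if (max_count < ncol(norm)) {
    norm <- norm[, seq_len(max(max_count, 1L)), drop = FALSE]
  }
  dimnames(norm) <- NULL
  structure(
    list(times = norm, counts = as.integer(counts),
         max_count = as.integer(max_count), resolution = resolution),
    class = "spike_matrix"
  )
}

#' @export
print.spike_matrix <- function(x, ...) {
  cat(sprintf(
    "<spike_matrix> %d trials, max %d spikes/trial, resolution %.3g ms\n",
    n_trials(x), x$max_count, x$resolution))
  cat(sprintf("  spike counts: %s\n",
              paste(names(table(x$counts)), table(x$counts),
                    sep = ":", collapse = "  ")))
  invisible(x)
}

# Row-wise ascending sort with NA pushed to the row's tail, vectorised via a
# single order() call (rows are the primary key). Much faster than per-row
# apply() in the corruption loop.
sort_spike_rows <- function(tm) {
  n <- nrow(tm)
  J <- ncol(tm)
  if (J == 1L) return(tm)
  o <- order(rep.int(seq_len(n), J), as.vector(tm), na.last = TRUE)
  matrix(as.vector(tm)[o], nrow = n, ncol = J, byrow = TRUE)
}

#' Motor-output scores
#'
#' Per-trial scores of the motor output on the first two principal
#' components of the within-cycle output waveform (e.g. yaw torque).
#'
#' @param x A numeric matrix or data frame with exactly 2 columns.
#' @return An object of class `motor_scores` wrapping an N x 2 matrix.
#' @export
motor_scores <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) abort("motor scores must be a matrix or data frame")
  storage.mode(x) <- "double"
  if (ncol(x) != 2L)
    abort(sprintf("motor scores must have exactly 2 columns, got %d", ncol(x)))
  if (nrow(x) == 0L) abort("no trials: motor score matrix has zero rows")
  if (any(!is.finite(x))) abort("motor scores must be finite")
  dimnames(x) <- list(NULL, c("pc1", "pc2"))
  structure(list(scores = x, n_trials = nrow(x)), class = "motor_scores")
}

#' @export
print.motor_scores <- function(x, ...) {
  cat(sprintf("<motor_scores> %d trials x 2 PCs\n", x$n_trials))
  invisible(x)
}

#' Number of trials of a spike matrix, motor-score set, or paired data set
#' @param x A `spike_matrix`, `motor_scores` or `spike_motor_pair` object.
#' @return Integer trial count.
#' @export
n_trials <- function(x) {
  if (inherits(x, "spike_matrix")) return(nrow(x$times))
  if (inherits(x, "motor_scores")) return(x$n_trials)
  if (inherits(x, "spike_motor_pair")) return(x$n)
  abort("n_trials() needs a spike_matrix, motor_scores or spike_motor_pair")
}

#' Pair spike data with motor output
#'
#' Validates that a spike matrix and a motor-score set describe the same
#' trials and returns an immutable paired handle used by all estimators.
#'
#' @param spikes A [spike_matrix()].
#' @param motor A [motor_scores()].
#' @return A `spike_motor_pair` object with elements `spikes`, `motor`, `n`.
#' @export
pair_dataset <- function(spikes, motor) {
  stopifnot(inherits(spikes, "spike_matrix"), inherits(motor, "motor_scores"))
  ns <- n_trials(spikes); nm <- n_trials(motor)
  if (ns != nm)
    abort(sprintf("alignment error: %d spike trials vs %d motor trials", ns, nm))
  if (ns == 0L) abort("empty dataset")
  structure(list(spikes = spikes, motor = motor, n = ns),
            class = "spike_motor_pair")
}

#' @export
print.spike_motor_pair <- function(x, ...) {
  cat(sprintf("<spike_motor_pair> %d trials (max %d spikes/trial)\n",
              x$n, x$spikes$max_count))
  invisible(x)
}

#' Convert a spike matrix to a tidy tibble
#'
#' @param x A `spike_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `trial`, `spike` (index within trial), and
#'   `time_ms`; absent spikes are dropped.
#' @export
tidy.spike_matrix <- function(x, ...) {
  J <- ncol(x$times)
  out <- tibble(
    trial = rep(seq_len(nrow(x$times)), J),
    spike = rep(seq_len(J), each = nrow(x$times)),
    time_ms = as.vector(x$times)
  )
  out <- out[!is.na(out$time_ms), ]
  dplyr::arrange(out, .data$trial, .data$spike)
}

#' @export
tidy.motor_scores <- function(x, ...) {
  tibble(trial = seq_len(x$n_trials),
         pc1 = x$scores[, 1], pc2 = x$scores[, 2])
}
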