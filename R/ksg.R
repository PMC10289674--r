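#' Standard-score the columns of a matrix
#'
#' Centres each column to mean 0 and scales to unit sample standard
#' deviation. All distance comparisons in the estimators are made in
#' standard-scored space so that spike times (ms) and motor scores
#' (arbitrary units) are commensurate. A zero-variance column carries no
#' information and is left at 0 with a warning.
#'
#' @param X A numeric matrix (or data frame) n x d.
#' @return A numeric matrix of the same shape with standardized columns.
#' @export
standard_score <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1)
  storage.mode(X) <- "double"
  mu <- colMeans(X)
  sds <- apply(X, 2L, sd)
  zero_var <- sds == 0 | !is.finite(sds)
  if (any(zero_var))
    warn(sprintf("%d zero-variance column(s) left at 0 after standard scoring",
                 sum(zero_var)))
  sds[zero_var] <- 1
  out <- sweep(sweep(X, 2L, mu, "-"), 2L, sds, "/")
  out[, zero_var] <- 0
  out
}

# Deterministic sub-resolution tie-break jitter, applied only inside
# distance computations. The KSG construction assumes continuous data;
# exact ties arise after rounding to the sampling resolution. Amplitude
# 1e-10 in standard-scored units, i.e. ~1e-10 column standard deviations,
# far below the 0.1 ms resolution floor. The jitter seed is derived from the
# matrix contents so that the estimator stays an exact function of its
# inputs and symmetric in (X, Y).
.jitter_amplitude <- 1e-10

tie_break_jitter <- function(Z, seed) {
  sig <- sprintf("%.12e|%.12e|%d|%d", sum(Z), sum(Z * Z), nrow(Z), ncol(Z))
  jseed <- derive_seed(seed, sig)
  withr::with_seed(jseed, {
    Z + matrix((runif(length(Z)) - 0.5) * 2 * .jitter_amplitude,
               nrow = nrow(Z))
  })
}

new_mi_estimate <- function(value, k, n, per_count_terms = NULL) {
  structure(list(value = value, k = k, n = n,
                 per_count_terms = per_count_terms),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("<mi_estimate> %.4f bits (k=%d, n=%d)\n", x$value, x$k, x$n))
  if (!is.null(x$per_count_terms)) {
    cat("decomposition by spike count:\n")
    print(x$per_count_terms)
  }
  invisible(x)
}

#' @export
tidy.mi_estimate <- function(x, ...) {
  if (is.null(x$per_count_terms)) {
    tibble(term = "total", mi_bits = x$value, weight = 1, n = x$n)
  } else {
    x$per_count_terms
  }
}

#' @export
glance.mi_estimate <- function(x, ...) {
  tibble(mi_bits = x$value, k = x$k, n = x$n)
}

#' Kraskov-Stoegbauer-Grassberger mutual information
#'
#' Estimates I(X;Y) in bits with the KSG k-nearest-neighbour estimator
#' (algorithm 1): for each point, the max-norm distance in the joint
#' (X, Y) space to its k-th nearest neighbour defines a ball, and the
#' numbers of marginal neighbours strictly within that ball enter the
#' digamma formula `psi(k) + psi(n) - <psi(nx+1) + psi(ny+1)>` (in nats;
#' converted to bits once at the end). Columns are standard-scored
#' internally, which makes the estimate invariant to per-column affine
#' rescaling. The value may be slightly negative (estimator noise) and is
#' reported unclipped.
#'
#' @param X,Y Numeric matrices (or vectors / data frames) with equal row
#'   counts; rows are samples.
#' @param k Neighbour count (default 4).
#' @param jitter_seed Seed from which the deterministic sub-resolution
#'   tie-break jitter is derived.
#' @return An `mi_estimate` with elements `value` (bits), `k`, `n`.
#' @examples
#' set.seed(1)
#' x <- rnorm(500); y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(500)
#' ksg_mi(x, y)$value  # close to -0.5 * log2(1 - 0.81)
#' @export
ksg_mi <- function(X, Y, k = 4L, jitter_seed = 760813L) {
  X <- standard_score(X)
  Y <- standard_score(Y)
  n <- nrow(X)
  if (nrow(Y) != n) abort("X and Y must have the same number of rows")
  if (ncol(X) == 0L || ncol(Y) == 0L) abort("shape error: zero-dimension input")
  if (n <= k) abort(sprintf("sample-size error: need n > k, got n=%d, k=%d", n, k))
  Xj <- tie_break_jitter(X, jitter_seed)
  Yj <- tie_break_jitter(Y, jitter_seed)
  nats <- ksg_mi_nats_cpp(Xj, Yj, as.integer(k))
  new_mi_estimate(nats / log(2), as.integer(k), n)
}

#' Mutual information between a discrete label and continuous data
#'
#' Nearest-neighbour mixed discrete-continuous estimator (Ross-type): for
#' each point the k-th-neighbour max-norm distance is found among points
#' sharing its label, and neighbours of any label within that distance are
#' counted in the full sample; digamma averages give the MI. Used for the
#' spike-count term of the count/timing decomposition. The estimate is
#' capped at the empirical label entropy, its exact upper bound.
#'
#' Label classes with fewer than `k + 1` members cannot support a
#' neighbour search and are excluded with a warning.
#'
#' @param labels Integer (or factor) vector of discrete labels, length n.
#' @param Y Numeric matrix n x d of continuous data.
#' @param k Neighbour count.
#' @param jitter_seed Tie-break jitter seed, as in [ksg_mi()].
#' @return An `mi_estimate` (bits). Exactly 0 if a single label class
#'   remains.
#' @export
mixed_mi_count <- function(labels, Y, k = 4L, jitter_seed = 760813L) {
  labels <- as.integer(as.factor(labels))
  Y <- standard_score(Y)
  n <- nrow(Y)
  if (length(labels) != n) abort("labels length must match rows of Y")
  tab <- table(labels)
  keep_classes <- as.integer(names(tab)[tab >= k + 1L])
  if (length(keep_classes) < length(tab))
    warn(sprintf("excluding %d label class(es) with < k+1 members from count MI",
                 length(tab) - length(keep_classes)))
  keep <- labels %in% keep_classes
  if (length(keep_classes) <= 1L)
    return(new_mi_estimate(0, as.integer(k), sum(keep)))
  lab <- labels[keep]
  Yk <- tie_break_jitter(Y[keep, , drop = FALSE], jitter_seed)
  nats <- mixed_mi_nats_cpp(lab, Yk, as.integer(k))
  p <- as.vector(table(lab)) / length(lab)
  h_label <- -sum(p * log2(p))
  new_mi_estimate(min(nats / log(2), h_label), as.integer(k), length(lab))
}

#' Count/timing decomposition of spike-train mutual information
#'
#' Total MI between a spike train and the motor output, decomposed into a
#' spike-count term plus count-conditioned timing terms:
#' `I = I(count; M) + sum_i p(count = i) * I(times; M | count = i)`.
#' Conditioning timing on count isolates temporally encoded information
#' from rate (count-per-cycle) information. Each conditional term is a KSG
#' estimate on the n_i x i matrix of spike times of trials with exactly i
#' spikes against the corresponding motor rows.
#'
#' Count classes with fewer than `max(k + 2, 10)` trials are excluded from
#' the timing sum (the neighbour search is unstable there); their
#' probability weight is still reported in the decomposition table.
#'
#' @param spikes A [spike_matrix()] (or [pair_dataset()] handle).
#' @param motor A [motor_scores()]; ignored if `spikes` is a pair.
#' @param k Neighbour count.
#' @param min_class_size Smallest count class entering the timing sum.
#' @param jitter_seed Tie-break jitter seed.
#' @param count_term Optional precomputed count-MI term in bits. The count
#'   term is invariant under spike-time corruption, so the noise sweep
#'   computes it once and passes it here for every repetition.
#' @return An `mi_estimate` whose `per_count_terms` tibble has one row per
#'   observed spike count: `count`, `n_trials`, `weight`, `mi_bits`
#'   (NA when excluded), `included`, plus a `count_term` attribute row.
#' @export
timing_mi_decomposed <- function(spikes, motor = NULL, k = 4L,
                                 min_class_size = max(k + 2L, 10L),
                                 jitter_seed = 760813L,
                                 count_term = NULL) {
  if (inherits(spikes, "spike_motor_pair")) {
    motor <- spikes$motor
    spikes <- spikes$spikes
  }
  stopifnot(inherits(spikes, "spike_matrix"), inherits(motor, "motor_scores"))
  n <- n_trials(spikes)
  if (n != n_trials(motor)) abort("alignment error: trial counts differ")
  counts <- spikes$counts
  M <- motor$scores

  if (is.null(count_term)) {
    count_term <- if (length(unique(counts)) == 1L) {
      0
    } else {
      mixed_mi_count(counts, M, k = k, jitter_seed = jitter_seed)$value
    }
  }

  obs_counts <- sort(unique(counts))
  rows <- purrr::map(obs_counts, function(ci) {
    idx <- which(counts == ci)
    w <- length(idx) / n
    eligible <- ci >= 1L && length(idx) >= min_class_size &&
      length(idx) > k + 1L
    mi <- NA_real_
    if (eligible) {
      Ti <- spikes$times[idx, seq_len(ci), drop = FALSE]
      mi <- ksg_mi(Ti, M[idx, , drop = FALSE], k = k,
                   jitter_seed = jitter_seed)$value
    }
    tibble(count = ci, n_trials = length(idx), weight = w,
           mi_bits = mi, included = eligible)
  })
  terms <- dplyr::bind_rows(rows)
  if (!any(terms$included) && count_term == 0)
    warn("no count class large enough for a timing term; count term only")
  timing_sum <- sum(terms$weight[terms$included] * terms$mi_bits[terms$included])
  est <- new_mi_estimate(count_term + timing_sum, as.integer(k), n,
                         per_count_terms = terms)
  est$count_term <- count_term
  est$timing_term <- timing_sum
  est
}

# Lean evaluation path for the noise sweep: the motor side, count-class
# membership and count term are invariant under spike-time corruption, so
# they are prepared once and only the spike-time side is standardised,
# jittered and searched per repetition. Produces values identical to
# timing_mi_decomposed() (the tie-break jitter is a pure function of the
# data) at a fraction of the overhead.
prepare_decomposition <- function(spikes, motor, k, min_class_size,
                                  jitter_seed) {
  counts <- spikes$counts
  n <- n_trials(spikes)
  obs <- sort(unique(counts))
  obs <- obs[obs >= 1L]
  eligible <- obs[vapply(obs, function(ci) {
    ni <- sum(counts == ci)
    ni >= min_class_size && ni > k + 1L
  }, logical(1))]
  classes <- lapply(eligible, function(ci) {
    idx <- which(counts == ci)
    Y <- standard_score(motor$scores[idx, , drop = FALSE])
    list(count = ci, idx = idx, weight = length(idx) / n,
         Yj = tie_break_jitter(Y, jitter_seed))
  })
  count_term <- if (length(unique(counts)) == 1L) 0
  else mixed_mi_count(counts, motor$scores, k = k,
                      jitter_seed = jitter_seed)$value
  list(classes = classes, count_term = count_term, k = as.integer(k),
       jitter_seed = jitter_seed)
}

decomposed_mi_value <- function(times, prep) {
  total <- prep$count_term
  for (cl in prep$classes) {
    Ti <- standard_score(times[cl$idx, seq_len(cl$count), drop = FALSE])
    Tij <- tie_break_jitter(Ti, prep$jitter_seed)
    total <- total +
      cl$weight * ksg_mi_nats_cpp(Tij, cl$Yj, prep$k) / log(2)
  }
  total
}

#' k-th-neighbour distance diagnostics under added noise
#'
#' For each spike-count class and each noise level, corrupts the spike
#' times with uniform noise, forms the joint standard-scored
#' (times, scores) space, and records the median (and quartiles) of the
#' k-th-nearest-neighbour max-norm distances. The difference from the
#' zero-noise median is also reported in milliseconds by undoing the
#' standard scoring (multiplying by the mean standard deviation of the
#' corrupted spike-time columns), showing how far noise shifts the scale at
#' which the estimator operates.
#'
#' @param spikes A [spike_matrix()].
#' @param motor A [motor_scores()].
#' @param noise_grid Noise widths r_c in ms (should include 0).
#' @param k Neighbour count.
#' @param seed Seed for the corruption draws.
#' @param min_class_size Smallest count class diagnosed.
#' @return A tibble of class `knn_diagnostics`: `count`, `r_c_ms`,
#'   `median_dist_sd`, `q25_sd`, `q75_sd`, `median_dist_ms`, `delta_ms`.
#' @export
knn_distance_diagnostics <- function(spikes, motor,
                                     noise_grid = noise_grid_default(20),
                                     k = 4L, seed = 1L,
                                     min_class_size = max(k + 2L, 10L)) {
  stopifnot(inherits(spikes, "spike_matrix"), inherits(motor, "motor_scores"))
  counts <- spikes$counts
  obs_counts <- sort(unique(counts[counts >= 1L]))
  obs_counts <- obs_counts[vapply(obs_counts, function(ci)
    sum(counts == ci) >= max(min_class_size, k + 2L), logical(1))]
  if (length(obs_counts) == 0L) abort("no count class large enough to diagnose")
  out <- purrr::map(seq_along(noise_grid), function(gi) {
    r_c <- noise_grid[gi]
    sp <- corrupt_spikes(spikes, r_c, seed = derive_seed(seed, "diag", gi))
    purrr::map(obs_counts, function(ci) {
      idx <- which(counts == ci)
      Ti <- sp$times[idx, seq_len(ci), drop = FALSE]
      Z <- cbind(standard_score(Ti),
                 standard_score(motor$scores[idx, , drop = FALSE]))
      Z <- tie_break_jitter(Z, derive_seed(seed, "diagjit"))
      dk <- knn_kth_dist_cpp(Z, as.integer(k))
      t_sds <- apply(Ti, 2L, sd)
      tibble(count = ci, r_c_ms = r_c,
             median_dist_sd = median(dk),
             q25_sd = unname(quantile(dk, 0.25)),
             q75_sd = unname(quantile(dk, 0.75)),
             time_sd_ms = mean(t_sds))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out$median_dist_ms <- out$median_dist_sd * out$time_sd_ms
  base <- out[out$r_c_ms == min(out$r_c_ms), c("count", "median_dist_ms")]
  names(base)[2L] <- "median0_ms"
  out <- dplyr::left_join(out, base, by = "count")
  out$delta_ms <- out$median_dist_ms - out$median0_ms
  out$median0_ms <- NULL
  class(out) <- c("knn_diagnostics", class(out))
  out
}
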