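# End-to-end validation: recover known ground-truth precision from
# synthetic data, and compare selection methods / estimators.

#' Continuous-method precision estimate for one data set
#'
#' Convenience wrapper: compute the noise curve and apply one or more
#' selection rules.
#'
#' @param spikes A [spike_matrix()] (or a [pair_dataset()] handle).
#' @param motor A [motor_scores()]; ignored if `spikes` is a pair.
#' @param config A [run_config()].
#' @param methods Subset of `c("std_threshold", "derivative", "two_line")`.
#' @return A `precision_estimate` tibble with one row per method, with the
#'   `noise_curve` attached as attribute `"curve"`.
#' @export
estimate_precision_continuous <- function(spikes, motor = NULL,
                                          config = run_config(),
                                          methods = "std_threshold") {
  curve <- noise_curve(spikes, motor, config)
  precision_from_curve(curve, methods)
}

#' @rdname estimate_precision_continuous
#' @param curve A precomputed [noise_curve()].
#' @export
precision_from_curve <- function(curve, methods = "std_threshold") {
  known <- c(std_threshold = precision_std,
             derivative = precision_derivative,
             two_line = precision_twoline)
  if (length(methods) == 0L) abort("config error: empty method list")
  bad <- setdiff(methods, names(known))
  if (length(bad)) abort(sprintf("unknown method(s): %s", paste(bad, collapse = ", ")))
  out <- purrr::map(methods, function(m) known[[m]](curve)) |>
    dplyr::bind_rows()
  class(out) <- c("precision_estimate", class(out))
  attr(out, "curve") <- curve
  out
}

validate_one <- function(generator, truth_ms, method_set, config, seed) {
  gen <- switch(generator,
    gaussian_pair = gaussian_pair(seed = seed),
    moth_like = moth_like(seed = seed),
    abort(sprintf("unknown generator '%s'", generator)))
  spikes <- fix_precision(gen$spikes, truth_ms)
  cfg <- config
  cfg$seed <- seed
  rows <- list()
  cont <- intersect(method_set, c("std_threshold", "derivative", "two_line"))
  if (length(cont)) {
    est <- estimate_precision_continuous(spikes, gen$motor, cfg, cont)
    rows <- c(rows, list(tibble(method = est$method, value_ms = est$value_ms,
                                resolved = est$resolved)))
  }
  if ("nsb_peak" %in% method_set) {
    est <- precision_nsb_peak(spikes, gen$motor, cfg)
    rows <- c(rows, list(tibble(method = est$method, value_ms = est$value_ms,
                                resolved = est$resolved)))
  }
  dplyr::bind_rows(rows)
}

#' Ground-truth recovery experiment
#'
#' For each generator and each ground-truth precision, generates fresh
#' synthetic data, fixes its precision by rounding, runs the requested
#' precision estimators, and aggregates the estimates over repeats. This
#' is the package's core validation: a trustworthy estimator should
#' recover the imposed resolution.
#'
#' @param truths_ms Ground-truth precisions in ms (imposed by rounding).
#' @param generators Any of `"gaussian_pair"`, `"moth_like"`.
#' @param methods Any of `"std_threshold"`, `"derivative"`, `"two_line"`,
#'   `"nsb_peak"`.
#' @param repeats Repeats per condition (fresh data and fresh noise each).
#' @param config A [run_config()]; its seed anchors all repeats.
#' @return A tibble of class `validation_report`: one row per condition,
#'   method and repeat, with columns `generator`, `truth_ms`, `method`,
#'   `repeat_id`, `value_ms`, `resolved`, plus a per-condition summary
#'   available via [glance()]. The resolved configuration and seed are
#'   stored as attributes.
#' @export
run_validation <- function(truths_ms = c(1, 2, 3, 4),
                           generators = "gaussian_pair",
                           methods = "std_threshold",
                           repeats = 4L,
                           config = run_config()) {
  if (length(methods) == 0L) abort("config error: empty method list")
  if (repeats < 1L) abort("config error: repeats must be >= 1")
  if (repeats == 1L) warn("repeats = 1: per-condition std reported as 0")
  grid <- tidyr::expand_grid(generator = generators, truth_ms = truths_ms,
                             rep_id = seq_len(repeats))
  out <- purrr::pmap(grid, function(generator, truth_ms, rep_id) {
    seed <- derive_seed(config$seed, "validate", generator, truth_ms, rep_id)
    res <- tryCatch(
      validate_one(generator, truth_ms, methods, config, seed),
      error = function(e) abort(sprintf(
        "validation failed at generator=%s, truth=%.3g ms, repeat %d: %s",
        generator, truth_ms, rep_id, conditionMessage(e))))
    dplyr::mutate(res, generator = generator, truth_ms = truth_ms,
                  repeat_id = rep_id, .before = 1L)
  }) |> dplyr::bind_rows()
  attr(out, "config") <- config
  attr(out, "version") <- as.character(utils::packageVersion("spikeprec"))
  class(out) <- c("validation_report", class(out))
  out
}

#' @export
glance.validation_report <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x, .data$generator, .data$truth_ms, .data$method),
    n_repeats = dplyr::n(),
    mean_ms = mean(.data$value_ms[.data$resolved]),
    std_ms = if (sum(.data$resolved) > 1L) sd(.data$value_ms[.data$resolved]) else 0,
    n_unresolved = sum(!.data$resolved),
    .groups = "drop")
}

#' Compare precision-estimation methods
#'
#' Summarises a [run_validation()] report into mean absolute error and
#' estimate spread per method over the conditions they share, ranked by
#' accuracy.
#'
#' @param report A `validation_report`.
#' @return A tibble with one row per method: `method`, `mae_ms`,
#'   `mean_bias_ms`, `estimate_std_ms`, `n_conditions`, `rank`.
#' @export
compare_methods <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  methods <- unique(report$method)
  if (length(methods) < 2L)
    abort("method comparison needs at least 2 methods on common conditions")
  common <- dplyr::count(report, .data$generator, .data$truth_ms, .data$method)
  keep <- dplyr::summarise(
    dplyr::group_by(common, .data$generator, .data$truth_ms),
    all_methods = dplyr::n_distinct(.data$method) == length(methods),
    .groups = "drop")
  keep <- keep[keep$all_methods, c("generator", "truth_ms")]
  if (nrow(keep) == 0L) abort("no conditions common to all methods")
  if (nrow(keep) == 1L) warn("MAE computed over a single condition")
  sub <- dplyr::inner_join(report, keep, by = c("generator", "truth_ms"))
  out <- dplyr::summarise(
    dplyr::group_by(sub, .data$method),
    mae_ms = mean(abs(.data$value_ms - .data$truth_ms), na.rm = TRUE),
    mean_bias_ms = mean(.data$value_ms - .data$truth_ms, na.rm = TRUE),
    estimate_std_ms = sd(.data$value_ms, na.rm = TRUE),
    n_conditions = dplyr::n_distinct(paste(.data$generator, .data$truth_ms)),
    .groups = "drop")
  out$rank <- rank(out$mae_ms, ties.method = "min")
  dplyr::arrange(out, .data$rank)
}

#' Write a validation report (CSV + JSON metadata)
#'
#' @param report A `validation_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(report),
                   file.path(dir, "validation.csv"), row.names = FALSE)
  cfg <- attr(report, "config")
  meta <- list(config = unclass(cfg), seed = cfg$seed,
               version = attr(report, "version"),
               summary = as.data.frame(glance(report)))
  jsonlite::write_json(meta, file.path(dir, "validation_meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
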