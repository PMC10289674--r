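# Delimited-text readers/writers for spike and motor-score tables.
# Dialect: comma-separated, optional single header row, "NaN"/empty cell for
# absent spikes. One row per trial.

read_delim_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("no trials: %s is empty", path))
  cells <- strsplit(lines, ",", fixed = TRUE)
  # header detection: any cell of the first row non-numeric and non-missing
  parse_cell <- function(s) {
    s <- trimws(s)
    if (s == "" || toupper(s) %in% c("NA", "NAN")) return(NA_real_)
    suppressWarnings(as.numeric(s))
  }
  first <- vapply(cells[[1L]], parse_cell, numeric(1))
  raw_first <- trimws(cells[[1L]])
  has_header <- any(is.na(first) &
                      !(raw_first == "" | toupper(raw_first) %in% c("NA", "NAN")))
  if (has_header) {
    cells <- cells[-1L]
    if (length(cells) == 0L) abort(sprintf("no trials: %s has only a header", path))
  }
  ncol_max <- max(lengths(cells))
  out <- matrix(NA_real_, nrow = length(cells), ncol = ncol_max)
  for (i in seq_along(cells)) {
    row_raw <- cells[[i]]
    vals <- vapply(row_raw, parse_cell, numeric(1))
    bad <- is.na(vals) &
      !(trimws(row_raw) == "" | toupper(trimws(row_raw)) %in% c("NA", "NAN"))
    if (any(bad)) {
      abort(sprintf("parse error in %s: non-numeric cell at row %d, column %d",
                    path, i + has_header, which(bad)[1L]))
    }
    out[i, seq_along(vals)] <- vals
  }
  out
}

#' Read a spike matrix from a delimited text file
#'
#' One row per trial; comma-separated spike times in ms; empty cells or
#' `NaN` mark absent spikes; an optional single header row is skipped.
#'
#' @param path File path.
#' @param resolution Sampling resolution in ms per sample (default 0.1).
#' @return A [spike_matrix()].
#' @export
read_spike_matrix <- function(path, resolution = 0.1) {
  spike_matrix(read_delim_matrix(path), resolution = resolution)
}

#' Read motor-output PC scores from a delimited text file
#'
#' Exactly two numeric columns; an optional header row (e.g. `pc1,pc2`)
#' is detected and skipped.
#'
#' @param path File path.
#' @return A [motor_scores()].
#' @export
read_motor_scores <- function(path) {
  m <- read_delim_matrix(path)
  if (ncol(m) != 2L)
    abort(sprintf("shape error: %s has %d columns, expected 2", path, ncol(m)))
  if (any(is.na(m))) abort(sprintf("motor scores in %s contain missing values", path))
  motor_scores(m)
}

#' Write a spike matrix to a delimited text file
#' @param x A [spike_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_matrix <- function(x, path) {
  stopifnot(inherits(x, "spike_matrix"))
  rows <- apply(x$times, 1L, function(r) {
    s <- format(r, digits = 17, trim = TRUE, scientific = FALSE)
    s[is.na(r)] <- "NaN"
    paste(s, collapse = ",")
  })
  writeLines(rows, path)
  invisible(path)
}

#' Write motor scores to a delimited text file
#' @param x A [motor_scores()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_motor_scores <- function(x, path) {
  stopifnot(inherits(x, "motor_scores"))
  rows <- apply(x$scores, 1L, function(r) {
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = ",")
  })
  writeLines(c("pc1,pc2", rows), path)
  invisible(path)
}
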