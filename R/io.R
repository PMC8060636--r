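# File I/O for every external representation the pipeline touches:
# plain-text interval lists (watch-export style), sampled-signal CSV,
# and result tables (CSV + JSON variant).
#
# Dialects: UTF-8, "." decimal separator, "," field separator. Interval
# files carry one positive interval in ms per line; "#" starts a comment.

#' Read a plain-text inter-beat interval file
#'
#' One positive interval in ms per line (heart-rate watch export style);
#' lines starting with `#` are ignored. All quality flags are initialized to
#' "normal".
#'
#' @param path file path
#' @param label posture/context tag to attach
#' @return a [beat_series()]
#' @export
read_interval_file <- function(path, label = "unspecified") {
  check_that(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals)) {
    bad <- idx[which(is.na(vals))[1]]
    sc_abort(sprintf("line %d of %s is not numeric: '%s'", bad, path, lines[bad]),
             "sc_parse_error")
  }
  if (any(vals <= 0)) {
    bad <- idx[which(vals <= 0)[1]]
    sc_abort(sprintf("line %d of %s: interval must be positive (got %g ms)",
                     bad, path, vals[which(vals <= 0)[1]]),
             "sc_validation_error")
  }
  beat_series(vals, label = label)
}

#' Write a beat or NN series as a plain-text interval file
#'
#' @param x a [beat_series()], [nn_series()] or numeric vector (ms)
#' @param path output path
#' @export
write_interval_file <- function(x, path) {
  vals <- if (inherits(x, "nn_series")) x$nn_ms
          else if (inherits(x, "beat_series")) x$intervals_ms
          else as.numeric(x)
  writeLines(format(vals, digits = 10, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Read a uniformly sampled multi-channel CSV
#'
#' Expects a header row with a time column `t_s` in seconds followed by one
#' column per channel. The time grid must be uniform: every step within
#' `1e-6 + 1e-6 * step` of the median step. The sampling rate is inferred
#' from the median step and `t0` is the first timestamp.
#'
#' @param path CSV path
#' @param expected_columns optional channel names that must be present
#' @param units optional named character vector of unit labels per channel
#' @return a single [sampled_signal()] if the file has one channel, otherwise
#'   a named list of [sampled_signal()] sharing `fs` and `t0`
#' @export
read_sampled_csv <- function(path, expected_columns = NULL, units = NULL) {
  check_that(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"t_s" %in% names(df)) {
    sc_abort(sprintf("%s: missing required time column 't_s'", path), "sc_format_error")
  }
  chans <- setdiff(names(df), "t_s")
  if (!is.null(expected_columns)) {
    missing <- setdiff(expected_columns, chans)
    if (length(missing)) {
      sc_abort(sprintf("%s: missing column(s): %s", path,
                       paste(missing, collapse = ", ")), "sc_format_error")
    }
    chans <- expected_columns
  }
  t <- df$t_s
  check_that(length(t) >= 2, "need at least two samples to infer a rate")
  steps <- diff(t)
  if (any(steps <= 0)) sc_abort("time column must be strictly increasing", "sc_format_error")
  med <- stats::median(steps)
  if (any(abs(steps - med) > 1e-6 + 1e-6 * med)) {
    sc_abort(sprintf("%s: non-uniform sampling (max step deviation %.3g s)",
                     path, max(abs(steps - med))), "sc_format_error")
  }
  fs <- 1 / med
  out <- lapply(chans, function(ch) {
    sampled_signal(df[[ch]], fs = fs, t0 = t[1],
                   unit = if (!is.null(units) && ch %in% names(units)) units[[ch]] else NA_character_)
  })
  names(out) <- chans
  if (length(out) == 1L) out[[1]] else out
}

#' Write one or more sampled signals to CSV
#'
#' Inverse of [read_sampled_csv()]: writes `t_s` plus one column per channel.
#' All channels must share `fs`, `t0` and length.
#'
#' @param sig a [sampled_signal()] or named list of them
#' @param path output path
#' @param channel column name used when `sig` is a single signal
#' @export
write_sampled_csv <- function(sig, path, channel = "value") {
  if (inherits(sig, "sampled_signal")) {
    sig <- stats::setNames(list(sig), channel)
  }
  check_that(length(sig) >= 1 && !is.null(names(sig)), "need a named list of signals")
  fs <- sig[[1]]$fs; t0 <- sig[[1]]$t0; n <- length(sig[[1]]$values)
  for (s in sig) {
    check_that(isTRUE(all.equal(s$fs, fs)) && isTRUE(all.equal(s$t0, t0)) &&
               length(s$values) == n, "channels must share fs, t0 and length")
  }
  df <- data.frame(t_s = t0 + (seq_len(n) - 1) / fs)
  for (nm in names(sig)) df[[nm]] <- sig[[nm]]$values
  write_results_table(df, path)
  invisible(path)
}

#' Write a result table as CSV
#'
#' Header row, comma separated, floats rendered with at least 6 significant
#' digits, rows in input order.
#'
#' @param records a data.frame (or list of identically named rows)
#' @param path output path; intermediate directories are not created
#' @export
write_results_table <- function(records, path) {
  if (!is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
    if (is.null(records)) records <- data.frame()
  }
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v) {
        if (is.na(v)) NA_character_
        else format(v, digits = 9, trim = TRUE, scientific = FALSE)
      }, character(1))
    }
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) sc_abort(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
                            "sc_io_error")
  invisible(path)
}

#' Write a result table (or any record) as JSON
#'
#' JSON variant of [write_results_table()] with identical field names.
#'
#' @param records data.frame or list
#' @param path output path
#' @export
write_results_json <- function(records, path) {
  jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
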