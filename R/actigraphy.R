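# Wrist-actigraphy sleep windowing: per-epoch arm angle and activity from
# the triaxial signal, then detection of the overnight still window
# (sleep onset, wake) used to select the PPG last-hour window.

# default detector configuration
acti_defaults <- function() {
  list(epoch_length_s = 5, angle_threshold_deg = 5, block_minutes = 5,
       min_block_minutes = 30, bridge_minutes = 10)
}

#' Per-epoch arm angle and activity from triaxial accelerometry
#'
#' Within each epoch: the arm angle is
#' `atan(median(z) / sqrt(median(x)^2 + median(y)^2)) * 180/pi` (degrees,
#' positive when gravity loads the z axis), and the activity is the mean
#' absolute deviation of the Euclidean norm from its epoch median (g).
#'
#' @param acc named list of three [sampled_signal()] (`x`, `y`, `z`) sharing
#'   fs and length, fs >= 10 Hz
#' @param epoch_length_s epoch length in seconds (default 5)
#' @return an `epoch_series`: `epoch_length_s`, `t_start_s` (epoch starts),
#'   `arm_angle_deg`, `activity_g`
#' @export
epoch_features <- function(acc, epoch_length_s = 5) {
  check_that(is.list(acc) && length(acc) == 3L, "acc must be three channels")
  ax <- acc[[1]]; ay <- acc[[2]]; az <- acc[[3]]
  check_that(length(ax$values) == length(ay$values) &&
             length(ay$values) == length(az$values),
             "channel lengths differ")
  check_that(isTRUE(all.equal(ax$fs, ay$fs)) && isTRUE(all.equal(ay$fs, az$fs)),
             "channel sampling rates differ")
  check_that(ax$fs >= 10, "need fs >= 10 Hz")
  spe <- round(epoch_length_s * ax$fs)
  n_epoch <- length(ax$values) %/% spe
  check_that(n_epoch >= 1, "record shorter than one epoch")
  idx <- seq_len(n_epoch * spe)
  ep <- rep(seq_len(n_epoch), each = spe)
  med_by <- function(v) as.numeric(tapply(v[idx], ep, stats::median))
  mx <- med_by(ax$values); my <- med_by(ay$values); mz <- med_by(az$values)
  angle <- atan2(mz, sqrt(mx^2 + my^2)) * 180 / pi
  nrm <- sqrt(ax$values[idx]^2 + ay$values[idx]^2 + az$values[idx]^2)
  act <- as.numeric(tapply(nrm, ep, function(v) mean(abs(v - stats::median(v)))))
  structure(list(epoch_length_s = epoch_length_s,
                 t_start_s = ax$t0 + (seq_len(n_epoch) - 1) * epoch_length_s,
                 arm_angle_deg = angle, activity_g = act),
            class = "epoch_series")
}

#' Detect the overnight sleep window from epoch features
#'
#' Epochs whose arm-angle change from the previous epoch stays below
#' `angle_threshold_deg`, sustained over at least `block_minutes`, are
#' "still". Still blocks separated by gaps shorter than `bridge_minutes` are
#' merged; sleep onset is the start of the first merged still block of at
#' least `min_block_minutes`, wake the end of the last such block. With no
#' qualifying block the result is an explicit empty window, not an error.
#'
#' @param epochs an `epoch_series` from [epoch_features()] covering >= 30 min
#' @param angle_threshold_deg successive-epoch angle-change threshold (deg)
#' @param block_minutes sustainment required to call epochs still (min)
#' @param min_block_minutes minimal still-block length kept (min)
#' @param bridge_minutes gaps shorter than this are bridged (min)
#' @return a `sleep_window` list: `onset_s`, `wake_s` (both NA when empty),
#'   `empty`, and `still_blocks` (data.frame of merged block bounds)
#' @export
detect_sleep_window <- function(epochs, angle_threshold_deg = 5,
                                block_minutes = 5, min_block_minutes = 30,
                                bridge_minutes = 10) {
  check_that(inherits(epochs, "epoch_series"), "epochs must be an epoch_series")
  e <- epochs$epoch_length_s
  n <- length(epochs$arm_angle_deg)
  check_that(n * e >= 1800, "record shorter than 30 min")
  dang <- abs(diff(epochs$arm_angle_deg))
  small <- c(dang[1] < angle_threshold_deg, dang < angle_threshold_deg)
  min_run <- max(1L, ceiling(block_minutes * 60 / e))
  r <- rle(small)
  still <- logical(n)
  pos <- 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= min_run) {
      still[pos:(pos + r$lengths[k] - 1L)] <- TRUE
    }
    pos <- pos + r$lengths[k]
  }
  empty_win <- function() structure(list(onset_s = NA_real_, wake_s = NA_real_,
                                         empty = TRUE,
                                         still_blocks = data.frame(start_s = numeric(0),
                                                                   end_s = numeric(0))),
                                    class = "sleep_window")
  if (!any(still)) return(empty_win())
  rs <- rle(still)
  ends <- cumsum(rs$lengths); starts <- ends - rs$lengths + 1L
  blocks <- data.frame(start = starts[rs$values], end = ends[rs$values])
  # bridge short gaps between still blocks
  bridge_epochs <- bridge_minutes * 60 / e
  merged <- blocks[1, , drop = FALSE]
  for (k in seq_len(nrow(blocks))[-1]) {
    gap <- blocks$start[k] - merged$end[nrow(merged)] - 1L
    if (gap < bridge_epochs) {
      merged$end[nrow(merged)] <- blocks$end[k]
    } else {
      merged <- rbind(merged, blocks[k, ])
    }
  }
  t0 <- epochs$t_start_s[1]
  merged$start_s <- t0 + (merged$start - 1L) * e
  merged$end_s <- t0 + merged$end * e
  long <- merged[(merged$end - merged$start + 1L) * e >= min_block_minutes * 60, ]
  if (!nrow(long)) return(empty_win())
  structure(list(onset_s = long$start_s[1], wake_s = long$end_s[nrow(long)],
                 empty = FALSE,
                 still_blocks = merged[, c("start_s", "end_s")]),
            class = "sleep_window")
}

#' @export
print.sleep_window <- function(x, ...) {
  if (x$empty) cat("<sleep_window> empty (no still block long enough)\n")
  else cat(sprintf("<sleep_window> onset %.0f s, wake %.0f s (%.1f h)\n",
                   x$onset_s, x$wake_s, (x$wake_s - x$onset_s) / 3600))
  invisible(x)
}

#' Sleep window straight from a triaxial recording
#'
#' Convenience wrapper: [epoch_features()] then [detect_sleep_window()].
#'
#' @param acc named list of three [sampled_signal()]
#' @param config optional overrides of `acti_defaults()`
#' @return a `sleep_window`
#' @export
sleep_window_from_acc <- function(acc, config = list()) {
  cfg <- utils::modifyList(acti_defaults(), config)
  detect_sleep_window(epoch_features(acc, cfg$epoch_length_s),
                      cfg$angle_threshold_deg, cfg$block_minutes,
                      cfg$min_block_minutes, cfg$bridge_minutes)
}
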