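# Study-level aggregation: phase labelling (BSL / SDP1-3 / RCV1 / RCV2 /
# RCV3-7), per-participant time-point averaging, Cohen's d effect sizes
# with the conventional size categories, and PVT reaction-time summaries.

study_timepoints <- c("BSL", "SDP1", "SDP2", "SDP3", "RCV1", "RCV2", "RCV3-7")

# expected number of days entering each averaged time point
phase_day_range <- list(BSL = 1:7, SDP = 1:3, RCV = 1:7)

#' Aggregate daily measurements into study time points
#'
#' Per participant and metric: `BSL` is the mean of the available baseline
#' days (up to 7); the three sleep-deprivation days `SDP1`-`SDP3` and the
#' first two recovery days `RCV1`, `RCV2` pass through unaveraged;
#' `RCV3-7` is the mean of recovery days 3-7. Missing days reduce the
#' denominator and are counted in `n_days` / `n_expected`.
#'
#' @param rows data.frame with columns `participant_id`, `phase`
#'   ("BSL"/"SDP"/"RCV"), `day_index` (1-based within phase), `metric`,
#'   `value`
#' @return data.frame with one row per participant x metric x time point:
#'   `participant_id`, `metric`, `timepoint`, `value`, `n_days`,
#'   `n_expected`, `note` ("missing baseline" rows carry NA value)
#' @export
phase_aggregate <- function(rows) {
  need <- c("participant_id", "phase", "day_index", "metric", "value")
  check_that(is.data.frame(rows) && all(need %in% names(rows)),
             paste("rows must have columns:", paste(need, collapse = ", ")))
  check_that(all(rows$phase %in% names(phase_day_range)), "phase must be BSL, SDP or RCV")
  ok_day <- mapply(function(p, d) d %in% phase_day_range[[p]], rows$phase, rows$day_index)
  check_that(all(ok_day), "day_index out of range for its phase")
  out <- list()
  for (pid in unique(rows$participant_id)) {
    for (m in unique(rows$metric[rows$participant_id == pid])) {
      sub <- rows[rows$participant_id == pid & rows$metric == m, ]
      cell <- function(timepoint, vals, n_expected, note = "") {
        data.frame(participant_id = pid, metric = m, timepoint = timepoint,
                   value = if (length(vals)) mean(vals) else NA_real_,
                   n_days = length(vals), n_expected = n_expected,
                   note = if (length(vals)) note
                          else if (nzchar(note)) note else "no data")
      }
      bsl <- sub$value[sub$phase == "BSL"]
      out[[length(out) + 1L]] <-
        if (length(bsl)) cell("BSL", bsl, 7L)
        else cell("BSL", numeric(0), 7L, "missing baseline")
      for (d in 1:3) {
        v <- sub$value[sub$phase == "SDP" & sub$day_index == d]
        out[[length(out) + 1L]] <- cell(paste0("SDP", d), v, 1L)
      }
      for (d in 1:2) {
        v <- sub$value[sub$phase == "RCV" & sub$day_index == d]
        out[[length(out) + 1L]] <- cell(paste0("RCV", d), v, 1L)
      }
      v <- sub$value[sub$phase == "RCV" & sub$day_index %in% 3:7]
      out[[length(out) + 1L]] <- cell("RCV3-7", v, 5L)
    }
  }
  res <- do.call(rbind, out)
  res$timepoint <- factor(res$timepoint, levels = study_timepoints)
  res[order(res$participant_id, res$metric, res$timepoint), ]
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean(g1) - mean(g2)) / s_pooled` with
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' The size category is assigned on |d|: small when |d| < 0.20, medium when
#' 0.20 <= |d| < 0.80, large when |d| >= 0.80.
#'
#' @param group1,group2 numeric vectors, each of length >= 2
#' @return an `effect_size` list: `d`, `category` (NA with `reason` when the
#'   pooled SD is zero)
#' @export
cohens_d <- function(group1, group2) {
  g1 <- as.numeric(group1); g2 <- as.numeric(group2)
  check_that(length(g1) >= 2 && length(g2) >= 2,
             "each group needs at least 2 values")
  check_that(all(is.finite(g1)) && all(is.finite(g2)), "values must be finite")
  n1 <- length(g1); n2 <- length(g2)
  sp <- sqrt(((n1 - 1) * stats::var(g1) + (n2 - 1) * stats::var(g2)) / (n1 + n2 - 2))
  if (sp == 0) {
    if (mean(g1) == mean(g2)) {
      return(structure(list(d = 0, category = "small"), class = "effect_size"))
    }
    return(structure(list(d = NA_real_, category = NA_character_,
                          reason = "zero pooled SD with unequal means"),
                     class = "effect_size"))
  }
  d <- (mean(g1) - mean(g2)) / sp
  structure(list(d = d, category = d_category(d)), class = "effect_size")
}

#' Effect-size category from a d value
#'
#' @param d Cohen's d (sign ignored)
#' @return "small" (|d| < 0.20), "medium" (0.20 <= |d| < 0.80) or "large"
#'   (|d| >= 0.80)
#' @export
d_category <- function(d) {
  a <- abs(d)
  ifelse(a < 0.20, "small", ifelse(a < 0.80, "medium", "large"))
}

#' @export
print.effect_size <- function(x, ...) {
  if (is.na(x$d)) cat(sprintf("<effect_size> undefined (%s)\n", x$reason))
  else cat(sprintf("<effect_size> d = %.3f (%s)\n", x$d, x$category))
  invisible(x)
}

#' Psychomotor vigilance task summary
#'
#' Mean and sample SD (n-1 denominator) of reaction times after discarding
#' false starts below `floor_ms` (standard PVT convention, default 100 ms).
#'
#' @param reaction_times_ms numeric vector of response times (ms)
#' @param floor_ms false-start floor; responses below it are discarded
#' @return list `RT_ms`, `SD_RT_ms`, `n`, `n_discarded` (NAs with `reason`
#'   when everything is discarded)
#' @export
pvt_summary <- function(reaction_times_ms, floor_ms = 100) {
  rt <- as.numeric(reaction_times_ms)
  check_that(length(rt) >= 2, "need at least 2 responses")
  keep <- rt >= floor_ms
  n_disc <- sum(!keep)
  rt <- rt[keep]
  if (length(rt) < 2) {
    return(list(RT_ms = NA_real_, SD_RT_ms = NA_real_, n = length(rt),
                n_discarded = n_disc, reason = "fewer than 2 responses retained"))
  }
  list(RT_ms = mean(rt), SD_RT_ms = stats::sd(rt), n = length(rt),
       n_discarded = n_disc)
}
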