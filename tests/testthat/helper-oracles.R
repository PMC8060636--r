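# Independent brute-force oracles used by the module tests. These mirror the
# stated contracts by direct enumeration and deliberately share no code with
# the package implementation.

# local-median artifact flagging by direct enumeration: for each interval,
# scan outward for the 5 nearest input-unflagged neighbours on each side
oracle_flag <- function(rr, flags, rel_threshold) {
  n <- length(rr)
  out <- flags
  for (i in seq_len(n)) {
    left <- c(); j <- i - 1
    while (j >= 1 && length(left) < 5) { if (flags[j] == "normal") left <- c(left, j); j <- j - 1 }
    right <- c(); j <- i + 1
    while (j <= n && length(right) < 5) { if (flags[j] == "normal") right <- c(right, j); j <- j + 1 }
    ref <- rr[c(left, right)]
    if (!length(ref)) next
    m <- stats::median(ref)
    if (flags[i] == "normal" && abs(rr[i] - m) / m > rel_threshold) out[i] <- "ectopic"
  }
  out
}

# exhaustive sequence-method oracle: every window of >= min_len beats whose
# steps all qualify in one direction, kept only if maximal, then r-filtered
oracle_sequences <- function(sbp, ibi, min_dsbp = 1, min_dibi = 5,
                             min_len = 3, min_r = 0.85) {
  n <- length(sbp)
  step_ok <- function(a, b, dir) {
    ds <- sbp[b] - sbp[a]; di <- ibi[b] - ibi[a]
    if (dir > 0) ds >= min_dsbp && di >= min_dibi else ds <= -min_dsbp && di <= -min_dibi
  }
  win_ok <- function(i, j, dir) {
    for (k in i:(j - 1)) if (!step_ok(k, k + 1, dir)) return(FALSE)
    TRUE
  }
  found <- list()
  for (dir in c(1, -1)) {
    for (i in seq_len(n - min_len + 1)) {
      for (j in (i + min_len - 1):n) {
        if (!win_ok(i, j, dir)) break
        maximal <- TRUE
        if (i > 1 && step_ok(i - 1, i, dir)) maximal <- FALSE
        if (j < n && step_ok(j, j + 1, dir)) maximal <- FALSE
        if (!maximal) next
        s <- sbp[i:j]; v <- ibi[i:j]
        r <- suppressWarnings(stats::cor(s, v))
        if (!is.finite(r) || r < min_r) next
        found[[length(found) + 1]] <- data.frame(
          start_index = as.integer(i), length_beats = as.integer(j - i + 1),
          direction = if (dir > 0) "up" else "down",
          slope_ms_per_mmhg = stats::coef(stats::lm(v ~ s))[2], r = r)
      }
    }
  }
  if (!length(found)) {
    return(data.frame(start_index = integer(0), length_beats = integer(0),
                      direction = character(0), slope_ms_per_mmhg = numeric(0),
                      r = numeric(0)))
  }
  out <- do.call(rbind, found)
  rownames(out) <- NULL
  out[order(out$start_index, out$direction), ]
}

# random SBP/IBI series that exercises ramps, plateaus and reversals
random_beat_series <- function(n, seed) {
  set.seed(seed)
  sbp <- 120 + cumsum(sample(c(-3, -1.5, -0.5, 0, 0.5, 1.5, 3), n, replace = TRUE))
  ibi <- 900 + 8 * (sbp - 120) + stats::rnorm(n, 0, 12)
  list(sbp_mmhg = sbp, ibi_ms = pmax(ibi, 300), beat_times_s = cumsum(pmax(ibi, 300)) / 1000)
}
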