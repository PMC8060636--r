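# Internal helpers shared across the pipeline.

#' Signal a classed pipeline error
#'
#' @param msg message text
#' @param class condition subclass (e.g. "sc_validation_error")
#' @noRd
sc_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "sc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Evaluate an expression with a local RNG state
#'
#' Restores the caller's .Random.seed afterwards so generators do not leak
#' random state.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    sc_abort("seed must be a single integer", "sc_validation_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Centered running mean with odd window, edges truncated
#' @noRd
running_mean <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || length(x) < width) return(x)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Indices of strict-ish local maxima (plateau-tolerant, leftmost sample)
#' @noRd
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(diff(sign(diff(x))) < 0) + 1L
  idx[x[idx] > x[pmax(idx - 1L, 1L)] | x[idx] > x[pmin(idx + 1L, n)]]
}

#' Topographic prominence of peaks within a segment
#' @noRd
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    v <- x[p]
    left <- x[seq_len(p)]
    higher_l <- which(left > v)
    lmin <- if (length(higher_l)) min(left[max(higher_l):p]) else min(left)
    right <- x[p:length(x)]
    higher_r <- which(right > v)
    rmin <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    v - max(lmin, rmin)
  }, numeric(1))
}

#' Stopifnot-style scalar check with a friendlier error
#' @noRd
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) sc_abort(msg, "sc_validation_error")
  invisible(TRUE)
}
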