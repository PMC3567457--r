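#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from a single integer seed. Stages and
#' subjects draw from named substreams so that, e.g., adding a reporting stage
#' can never change the simulated data. The substream seed is a deterministic
#' 31-bit hash of the master seed and a label.
#'
#' @param seed master integer seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return An integer in `[0, 2^31 - 1]`.
#' @export
substream_seed <- function(seed, ...) {
  lab <- paste(c(format(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

with_substream <- function(seed, ..., code) {
  withr::with_seed(substream_seed(seed, ...), code)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Convert a time window to a sample selector
#'
#' Windows are half-open `[lo, hi)` in milliseconds throughout the package;
#' a sample at time `t` belongs to the window iff `lo <= t < hi`.
#'
#' @param time numeric vector of sample times (ms).
#' @param window numeric length-2, `c(lo, hi)` in ms.
#' @return logical vector marking samples inside the window.
#' @export
in_window <- function(time, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  time >= window[1] & time < window[2]
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 1 && x == round(x)
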