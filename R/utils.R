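# Shared small helpers: seed substreams and window arithmetic.

#' Derive a reproducible substream seed from a global seed and a stage name
#'
#' Each pipeline stage draws its randomness from a named substream so stages
#' can be re-run independently. The derivation is a fixed integer hash kept
#' below 2^31.
#'
#' @param seed integer global seed
#' @param name character stage name
#' @return integer seed
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

#' Window index on a fixed grid anchored at coordinate 1
#'
#' Windows are half-open `[start, start + window_bp)` with the first window
#' starting at 1; positions are 1-based inclusive. Returns the 1-based index
#' of the window containing each position.
#'
#' @param pos integer vector of 1-based positions
#' @param window_bp window size in bp
#' @return integer vector of window indices (1-based)
#' @export
window_index <- function(pos, window_bp) {
  stopifnot(window_bp >= 1)
  as.integer((pos - 1) %/% window_bp) + 1L
}

#' Convert a window index back to its 1-based start/end span
#' @param idx 1-based window index
#' @param window_bp window size in bp
#' @return data.frame with start and end (1-based inclusive)
#' @export
window_span <- function(idx, window_bp) {
  start <- (as.integer(idx) - 1L) * as.integer(window_bp) + 1L
  data.frame(start = start, end = start + as.integer(window_bp) - 1L)
}

# internal: check a scalar probability
.chk_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

.chk_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop(sprintf("'%s' must be a non-negative number", name), call. = FALSE)
  invisible(x)
}
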