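# Internal helpers: seed substreams, argument checks.

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from a single user seed. Each stage
#' (simulation, NMF restarts, rewiring, surrogates, ...) draws from its own
#' named substream so that changing one stage's consumption of random numbers
#' does not perturb any other stage.
#'
#' @param seed Integer master seed.
#' @param stream Character name of the substream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.character(stream), length(stream) == 1L)
  codes <- utf8ToInt(stream)
  # deterministic polynomial hash of the stream name, kept in double range
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 1000003
  val <- (abs(seed) %% 2147483647) * 1009 + h * 97 + 1
  as.integer(val %% 2147483646) + 1L
}

with_stream_seed <- function(seed, stream, code) {
  withr::with_seed(stream_seed(seed, stream), code)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %s, got %s",
                  name, format(min), deparse(substitute(x))),
          class = "cortsub_invalid_argument")
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x <= hi && (if (lo_open) x > lo else x >= lo)
  if (!ok) {
    abort(sprintf("`%s` must lie in %s%s, %s]", name,
                  if (lo_open) "(" else "[", format(lo), format(hi)),
          class = "cortsub_invalid_argument")
  }
  as.numeric(x)
}

abort_invalid <- function(msg) abort(msg, class = "cortsub_invalid_argument")
abort_input <- function(msg) abort(msg, class = "cortsub_invalid_input")

roi_columns <- function(df) grep("^roi_[0-9]+$", names(df), value = TRUE)

# Order roi_<id> column names numerically by id.
order_roi_names <- function(nms) nms[order(as.integer(sub("^roi_", "", nms)))]
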