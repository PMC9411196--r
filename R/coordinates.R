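#' Interval coordinate conversions
#'
#' All stored positions in this package are 1-based inclusive; internal
#' interval arithmetic uses 0-based half-open intervals. These converters are
#' exact inverses of one another.
#'
#' `intervalToHalfOpen(s, e)` maps a 1-based closed interval `[s, e]` to the
#' 0-based half-open `[s - 1, e)`; `intervalToOneBased` is its inverse.
#'
#' @param start,end integer vectors (recycled to common length)
#' @return a data.frame with columns `start` and `end`
#' @examples
#' intervalToHalfOpen(1, 10)        # [0, 10)
#' intervalToOneBased(0, 10)        # [1, 10]
#' @export
intervalToHalfOpen <- function(start, end) {
  if (any(end < start)) stop("end must be >= start for closed intervals")
  data.frame(start = start - 1L, end = end)
}

#' @rdname intervalToHalfOpen
#' @export
intervalToOneBased <- function(start, end) {
  if (any(end < start)) stop("end must be >= start for half-open intervals")
  data.frame(start = start + 1L, end = end)
}
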