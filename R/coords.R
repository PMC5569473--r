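#' Convert 1-based inclusive coordinates to 0-based half-open
#'
#' Genome browsers and most publications print intervals as 1-based inclusive
#' positions; this package stores all intervals 0-based half-open (BED
#' convention), where the span is simply `end - start`. A 1-based inclusive
#' interval \[a, b\] maps to the half-open interval \[a - 1, b).
#'
#' @param start,end Integer vectors of 1-based inclusive positions
#'   (`start <= end`).
#' @return A data.frame with columns `start` and `end` in 0-based half-open
#'   convention.
#' @examples
#' # chr2: 106,246,527-106,251,789 (1-based) spans 5263 bp
#' iv <- onebased_to_halfopen(106246527, 106251789)
#' iv$end - iv$start
#' @seealso [halfopen_to_onebased()]
#' @export
onebased_to_halfopen <- function(start, end) {
  if (any(end < start)) stop("1-based inclusive interval requires end >= start")
  data.frame(start = start - 1L, end = end)
}

#' Convert 0-based half-open coordinates to 1-based inclusive
#'
#' Inverse of [onebased_to_halfopen()]; the printed span `b - a + 1` of the
#' 1-based interval equals the half-open span `end - start`.
#'
#' @param start,end Integer vectors of 0-based half-open coordinates
#'   (`end > start`).
#' @return A data.frame with columns `start` and `end`, 1-based inclusive.
#' @export
halfopen_to_onebased <- function(start, end) {
  if (any(end <= start)) stop("half-open interval requires end > start")
  data.frame(start = start + 1L, end = end)
}

#' Width of the intersection of two half-open intervals
#'
#' @param start1,end1,start2,end2 Interval coordinates, 0-based half-open.
#'   Vectors are recycled.
#' @return Integer vector of shared bases; 0 when the intervals are disjoint
#'   (adjacent intervals such as \[0,10) and \[10,20) share no base).
#' @export
interval_overlap <- function(start1, end1, start2, end2) {
  pmax(0L, pmin(end1, end2) - pmax(start1, start2))
}
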