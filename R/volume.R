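#' Subsample a series to a coarser slice interval
#'
#' Keeps slices at indices \code{offsetSlices, offsetSlices + m,
#' offsetSlices + 2m, ...} (0-based, \code{m = interval / spacing}) up to
#' the last reachable index; the result is a uniformly spaced series with
#' the new interval as its spacing. Slices beyond the last reachable
#' multiple are dropped here; see [runIntervalExperiment()] for how the
#' estimators close the remaining end span.
#'
#' @param series an \linkS4class{ACSASeries}.
#' @param interval target interval in cm; must be a positive integer
#'   multiple of the source spacing (relative tolerance 1e-9).
#' @param offsetSlices integer offset in source slices, in \code{[0, m)}.
#' @return the subsampled \linkS4class{ACSASeries}.
#' @export
subsampleSeries <- function(series, interval, offsetSlices = 0L) {
  stopifnot(is(series, "ACSASeries"))
  delta <- sliceSpacing(series)
  m <- round(interval / delta)
  if (m < 1L || abs(interval - m * delta) > .spacing_rtol * delta)
    stop(sprintf("interval %g cm is not a positive integer multiple of the spacing %g cm",
                 interval, delta))
  offsetSlices <- as.integer(offsetSlices)
  if (offsetSlices < 0L || offsetSlices >= m)
    stop(sprintf("offsetSlices must lie in [0, %d)", m))
  n <- nSlices(series)
  sel <- seq(offsetSlices + 1L, n, by = m)
  if (length(sel) < 2L)
    stop(sprintf("subsampling at %g cm leaves fewer than 2 slices", interval))
  ACSASeries(subjectId(series), positions = positions(series)[sel],
             areas = areas(series)[sel], spacing = m * delta,
             unitsNote = series@unitsNote,
             metadata = c(series@metadata,
                          list(subsample = list(interval_cm = m * delta,
                                                offset_slices = offsetSlices,
                                                source_indices = sel - 1L))))
}

#' Cylindrical (Cavalieri) muscle volume
#'
#' Each slice's area is extruded over one slice interval:
#' \deqn{MV = \sum_{n} CSA_n \times \Delta}
#' where \eqn{\Delta} is the slice spacing. The estimate therefore covers
#' \code{nSlices * spacing} cm, one interval beyond the last slice position.
#'
#' @param series an \linkS4class{ACSASeries} (uniform spacing).
#' @return the volume in cm^3.
#' @export
volumeCylinder <- function(series) {
  stopifnot(is(series, "ACSASeries"))
  sum(areas(series)) * sliceSpacing(series)
}

#' Truncated-cone (frustum) muscle volume
#'
#' Consecutive slices bound a conical frustum:
#' \deqn{MV = \sum_{n} \frac{\Delta}{3}\left(CSA_n +
#'   \sqrt{CSA_n \, CSA_{n+1}} + CSA_{n+1}\right)}
#' The estimate covers \code{(nSlices - 1) * spacing} cm, the span between
#' the first and last slice. Exact for any profile whose square-root area is
#' affine in z (a cone or frustum), at every interval and offset.
#'
#' @param series an \linkS4class{ACSASeries} with at least 2 slices.
#' @return the volume in cm^3.
#' @export
volumeTruncatedCone <- function(series) {
  stopifnot(is(series, "ACSASeries"))
  a <- areas(series)
  n <- length(a)
  if (n < 2L) stop("truncated-cone volume needs at least 2 slices")
  sum(frustumSegment(sliceSpacing(series), a[-n], a[-1L]))
}

## Volume of one frustum segment of height h between areas a1 and a2.
frustumSegment <- function(h, a1, a2) {
  (h / 3) * (a1 + sqrt(a1 * a2) + a2)
}

## One (equation, interval, offset) estimate with end-segment handling.
## endRule "partial": the estimate is closed at the true end of the 1 cm
## series -- the last analysed slice is extruded only to the end of the
## source series (cylinder), or a final frustum of the true remaining height
## is added against the last source slice (cone). endRule "drop": the
## literal stride-k equations on the selected slices only.
.estimateOne <- function(series, equation, interval, offsetSlices, endRule) {
  sub <- subsampleSeries(series, interval, offsetSlices)
  delta <- sliceSpacing(series)
  m <- as.integer(round(interval / delta))
  n <- nSlices(series)
  N <- nSlices(sub)
  aSub <- areas(sub)
  nUsed <- N
  if (equation == "cylinder") {
    v <- volumeCylinder(sub)
    if (endRule == "partial") {
      overshoot <- (offsetSlices + N * m) - n      # in source slices
      if (overshoot > 0L)
        v <- v - overshoot * delta * aSub[N]
    }
  } else if (equation == "truncated_cone") {
    v <- volumeTruncatedCone(sub)
    if (endRule == "partial") {
      lastSel <- offsetSlices + (N - 1L) * m       # 0-based source index
      r <- (n - 1L) - lastSel                      # remaining source slices
      if (r > 0L) {
        v <- v + frustumSegment(r * delta, aSub[N], areas(series)[n])
        nUsed <- N + 1L
      }
    }
  } else {
    stop(sprintf("unknown equation '%s'", equation))
  }
  data.frame(subject_id = subjectId(series), equation = equation,
             interval_cm = interval, offset_cm = offsetSlices * delta,
             volume_cm3 = v, n_slices = nUsed, stringsAsFactors = FALSE)
}

#' Run the slice-interval x equation experiment on one series
#'
#' Computes one volume estimate per combination of equation, interval and
#' subsampling offset. With \code{offsetPolicy = "first"} only offset 0 is
#' used (the distal-most slice is always retained, matching a segmenter who
#' starts distally and works proximally); \code{"all"} enumerates every
#' offset for sensitivity analysis.
#'
#' The default \code{endRule = "partial"} closes each estimate at the end of
#' the source series so that every interval measures volume over the same
#' physical span as the reference: the cylinder extrudes its last analysed
#' slice only over the distance actually remaining, and the cone adds a
#' final frustum of the true remaining height against the last source
#' slice. When the stride divides the series evenly this coincides with the
#' literal stride-k equations. \code{endRule = "drop"} instead ignores the
#' remainder entirely, so coarser intervals may cover a different span than
#' the reference; see the methods vignette for why "partial" is the default.
#'
#' @param series an \linkS4class{ACSASeries} (typically ROI-restricted,
#'   1 cm spacing).
#' @param intervals intervals in cm (default \code{c(1, 2, 3, 4)}).
#' @param equations subset of \code{c("cylinder", "truncated_cone")}.
#' @param offsetPolicy \code{"first"} (offset 0 only) or \code{"all"}.
#' @param endRule \code{"partial"} (span-matched, default) or \code{"drop"}.
#' @return a data.frame of estimates with columns \code{subject_id},
#'   \code{equation}, \code{interval_cm}, \code{offset_cm},
#'   \code{volume_cm3}, \code{n_slices}.
#' @examples
#' s <- ACSASeries("demo", 0:22, 40 + 5 * sin(seq(0, pi, length.out = 23)))
#' runIntervalExperiment(s)
#' @export
runIntervalExperiment <- function(series, intervals = c(1, 2, 3, 4),
                                  equations = c("cylinder", "truncated_cone"),
                                  offsetPolicy = c("first", "all"),
                                  endRule = c("partial", "drop")) {
  stopifnot(is(series, "ACSASeries"))
  offsetPolicy <- match.arg(offsetPolicy)
  endRule <- match.arg(endRule)
  equations <- match.arg(equations, c("cylinder", "truncated_cone"),
                         several.ok = TRUE)
  delta <- sliceSpacing(series)
  out <- list()
  for (interval in sort(intervals)) {
    m <- as.integer(round(interval / delta))
    offsets <- if (offsetPolicy == "all") seq_len(m) - 1L else 0L
    for (eq in equations)
      for (off in offsets)
        out[[length(out) + 1L]] <-
          .estimateOne(series, eq, interval, off, endRule)
  }
  do.call(rbind, out)
}
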