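#' @rdname accessors
#' @aliases subjectId,ACSASeries-method
setMethod("subjectId", "ACSASeries", function(x) x@subjectId)

#' @rdname accessors
#' @aliases positions,ACSASeries-method
setMethod("positions", "ACSASeries", function(x) x@positions)

#' @rdname accessors
#' @aliases areas,ACSASeries-method
setMethod("areas", "ACSASeries", function(x) x@areas)

#' @rdname accessors
#' @aliases sliceSpacing,ACSASeries-method
setMethod("sliceSpacing", "ACSASeries", function(x) x@spacing)

#' @rdname accessors
#' @aliases nSlices,ACSASeries-method
setMethod("nSlices", "ACSASeries", function(x) length(x@positions))

setMethod("show", "ACSASeries", function(object) {
  n <- length(object@positions)
  cat(sprintf("ACSASeries '%s': %d slices, spacing %g cm, span [%g, %g] cm\n",
              object@subjectId, n, object@spacing,
              object@positions[1L], object@positions[n]))
  cat(sprintf("  areas (cm^2): min %.2f, median %.2f, max %.2f\n",
              min(object@areas), stats::median(object@areas),
              max(object@areas)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
  invisible(NULL)
})

#' Tabular view of a series
#'
#' @param series an \linkS4class{ACSASeries}.
#' @return a data.frame with columns \code{subject_id}, \code{index}
#'   (0-based), \code{position_cm}, \code{area_cm2}.
#' @export
asSliceTable <- function(series) {
  stopifnot(is(series, "ACSASeries"))
  data.frame(
    subject_id = subjectId(series),
    index = seq_along(positions(series)) - 1L,
    position_cm = positions(series),
    area_cm2 = areas(series),
    stringsAsFactors = FALSE
  )
}
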