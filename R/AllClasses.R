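#' @import methods
NULL

## Relative tolerance used when checking that slice positions form a uniform
## grid and that an interval is an integer multiple of the slice spacing.
.spacing_rtol <- 1e-9

#' ACSASeries: an ordered series of muscle cross-sectional areas
#'
#' The universal currency of the package: one anatomical cross-sectional area
#' (ACSA, cm^2) per axial slice, at uniformly spaced positions (cm) along the
#' limb axis, increasing distal to proximal. Slice indices are 0-based.
#'
#' @slot subjectId single character identifier.
#' @slot positions numeric, slice positions in cm, strictly increasing and
#'   uniformly spaced (relative tolerance 1e-9).
#' @slot areas numeric, non-negative contractile-tissue areas in cm^2, one per
#'   slice. Interior zeros are legal (e.g. complete fat-infiltration exclusion
#'   on a slice) and are treated as genuine zeros by the estimators.
#' @slot spacing numeric scalar, distance between consecutive slices in cm.
#' @slot unitsNote free-text reminder of the units convention.
#' @slot metadata list of provenance entries (source file, ROI cuts,
#'   subsampling parameters, ...).
#'
#' @exportClass ACSASeries
setClass("ACSASeries",
  representation(
    subjectId = "character",
    positions = "numeric",
    areas     = "numeric",
    spacing   = "numeric",
    unitsNote = "character",
    metadata  = "list"
  )
)

setValidity("ACSASeries", function(object) {
  msgs <- character()
  if (length(object@subjectId) != 1L || is.na(object@subjectId))
    msgs <- c(msgs, "subjectId must be a single non-NA string")
  n <- length(object@positions)
  if (n < 2L)
    msgs <- c(msgs, "an ACSASeries needs at least 2 slices")
  if (length(object@areas) != n)
    msgs <- c(msgs, "positions and areas must have equal length")
  if (anyNA(object@positions) || anyNA(object@areas))
    msgs <- c(msgs, "positions and areas must not contain NA")
  if (length(object@areas) && any(object@areas < 0)) {
    bad <- which(object@areas < 0) - 1L
    msgs <- c(msgs, sprintf("negative areas at slice index (0-based): %s",
                            paste(bad, collapse = ", ")))
  }
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0) {
    msgs <- c(msgs, "spacing must be a single positive number")
  } else if (n >= 2L) {
    d <- diff(object@positions)
    if (any(d <= 0))
      msgs <- c(msgs, "positions must be strictly increasing")
    off <- abs(d - object@spacing) > .spacing_rtol * object@spacing
    if (any(off)) {
      bad <- which(off)
      msgs <- c(msgs, sprintf(
        "non-uniform spacing: gap(s) before slice index (0-based) %s differ from spacing %g",
        paste(bad, collapse = ", "), object@spacing))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ACSASeries
#'
#' Rows are sorted by position; the spacing is inferred from the median
#' consecutive position difference unless supplied. Construction fails when
#' the sorted positions are not uniformly spaced within relative tolerance
#' 1e-9, or when any area is negative.
#'
#' @param subjectId subject identifier (single string).
#' @param positions slice positions in cm along the limb axis.
#' @param areas ACSA values in cm^2, same length as \code{positions}.
#' @param spacing optional slice spacing in cm; inferred when \code{NULL}.
#' @param unitsNote free-text units reminder.
#' @param metadata provenance list.
#' @return a validated \linkS4class{ACSASeries}.
#' @examples
#' s <- ACSASeries("demo", positions = 0:4, areas = rep(10, 5))
#' volumeCylinder(s)
#' @export
ACSASeries <- function(subjectId, positions, areas, spacing = NULL,
                       unitsNote = "positions in cm, areas in cm^2",
                       metadata = list()) {
  positions <- as.numeric(positions)
  areas <- as.numeric(areas)
  if (length(positions) != length(areas))
    stop("positions and areas must have equal length")
  ord <- order(positions)
  positions <- positions[ord]
  areas <- areas[ord]
  if (is.null(spacing)) {
    if (length(positions) < 2L)
      stop("cannot infer spacing from fewer than 2 slices")
    spacing <- stats::median(diff(positions))
  }
  new("ACSASeries", subjectId = as.character(subjectId),
      positions = positions, areas = areas, spacing = as.numeric(spacing),
      unitsNote = unitsNote, metadata = metadata)
}

#' Anatomical landmarks bounding the restricted quadriceps ROI
#'
#' Slice indices are 0-based and increase distal to proximal, so the patella
#' landmark (distal) must precede the lesser-trochanter landmark (proximal).
#' The distal cut removes the fraction \code{distalFraction} of the
#' patella-to-trochanter distance, measured from the patella.
#'
#' @slot patellaIndex 0-based slice index at the proximal aspect of the
#'   patella.
#' @slot trochanterIndex 0-based slice index of the first appearance of the
#'   lesser trochanter.
#' @slot distalFraction fraction in [0, 1) of the patella-to-trochanter
#'   distance cut away distally (default 0.20).
#' @exportClass RoiLandmarks
setClass("RoiLandmarks",
  representation(patellaIndex = "integer", trochanterIndex = "integer",
                 distalFraction = "numeric")
)

setValidity("RoiLandmarks", function(object) {
  msgs <- character()
  if (object@patellaIndex < 0L)
    msgs <- c(msgs, "patellaIndex must be >= 0")
  if (object@trochanterIndex <= object@patellaIndex)
    msgs <- c(msgs,
      "trochanterIndex must exceed patellaIndex (indices increase distal to proximal)")
  if (object@distalFraction < 0 || object@distalFraction >= 1)
    msgs <- c(msgs, "distalFraction must lie in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' @rdname RoiLandmarks-class
#' @param patellaIndex,trochanterIndex 0-based landmark slice indices.
#' @param distalFraction fraction of the patella-to-trochanter distance cut
#'   away distally.
#' @return a validated \linkS4class{RoiLandmarks}.
#' @export
roiLandmarks <- function(patellaIndex, trochanterIndex, distalFraction = 0.20) {
  new("RoiLandmarks", patellaIndex = as.integer(patellaIndex),
      trochanterIndex = as.integer(trochanterIndex),
      distalFraction = as.numeric(distalFraction))
}

#' PhantomSpec: a parametric muscle phantom with known area profile
#'
#' Families: \code{"constant"} (A(z) = a), \code{"frustum"} (linear radius,
#' circular section), \code{"quadratic"} (A(z) = c0 + c1 z + c2 z^2) and
#' \code{"spline"} (natural cubic spline through control areas). The first
#' three have closed-form volumes; the spline is integrated by adaptive
#' quadrature between knots to relative tolerance 1e-10.
#'
#' @slot family one of \code{constant}, \code{frustum}, \code{quadratic},
#'   \code{spline}.
#' @slot parameters named list of family-specific parameters.
#' @slot length phantom length in cm (z runs over [0, length]).
#' @slot name display name.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(family = "character", parameters = "list",
                 length = "numeric", name = "character")
)

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  if (!object@family %in% c("constant", "frustum", "quadratic", "spline"))
    msgs <- c(msgs, sprintf("unknown phantom family '%s'", object@family))
  if (length(object@length) != 1L || !is.finite(object@length) ||
      object@length <= 0)
    msgs <- c(msgs, "length must be a single positive number")
  if (!length(msgs)) {
    z <- seq(0, object@length, length.out = 2001L)
    a <- areaAt(object, z)
    if (any(a < -1e-9))
      msgs <- c(msgs, "area profile A(z) must be non-negative on [0, length]")
  }
  if (length(msgs)) msgs else TRUE
})

#' CohortSpec: configuration of a synthetic muscle cohort
#'
#' Describes a cohort of subjects sharing one base phantom profile, each
#' subject rescaled by an independent lognormal factor and sampled with
#' optional slice-area noise and IMAT-style dropout. All randomness flows
#' from \code{seed} through a documented per-subject sub-seed.
#'
#' @slot nSubjects number of subjects (>= 1).
#' @slot basePhantom the shared \linkS4class{PhantomSpec} profile.
#' @slot scaleSdLog SD of the log of the per-subject area scale factor.
#' @slot roiSlices slices per subject over the restricted ROI (default 23).
#' @slot spacing slice spacing in cm (default 1).
#' @slot areaNoiseSd per-slice Gaussian area noise SD in cm^2.
#' @slot imatDropout per-slice multiplicative dropout ceiling in [0, 1);
#'   each slice area is multiplied by 1 - U with U ~ Uniform(0, imatDropout).
#' @slot seed integer cohort seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nSubjects = "integer", basePhantom = "PhantomSpec",
                 scaleSdLog = "numeric", roiSlices = "integer",
                 spacing = "numeric", areaNoiseSd = "numeric",
                 imatDropout = "numeric", seed = "integer")
)

setValidity("CohortSpec", function(object) {
  msgs <- character()
  if (object@nSubjects < 1L) msgs <- c(msgs, "nSubjects must be >= 1")
  if (object@roiSlices < 2L) msgs <- c(msgs, "roiSlices must be >= 2")
  if (object@spacing <= 0) msgs <- c(msgs, "spacing must be positive")
  if (object@scaleSdLog < 0 || object@areaNoiseSd < 0)
    msgs <- c(msgs, "noise parameters must be >= 0")
  if (object@imatDropout < 0 || object@imatDropout >= 1)
    msgs <- c(msgs, "imatDropout must lie in [0, 1)")
  span <- (object@roiSlices - 1L) * object@spacing
  if (span > object@basePhantom@length * (1 + 1e-9))
    msgs <- c(msgs, sprintf(
      "sampled span %g cm exceeds phantom length %g cm",
      span, object@basePhantom@length))
  if (length(msgs)) msgs else TRUE
})
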