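#' Read an ACSA series from a CSV table
#'
#' Expects a UTF-8 CSV with header
#' \code{subject_id,index,position_cm,area_cm2} describing a single subject.
#' Rows may arrive in any order; they are sorted by position. The slice
#' spacing is inferred from the median consecutive position difference and
#' the positions must form a uniform grid within relative tolerance 1e-9.
#'
#' @param path path to the CSV file.
#' @return an \linkS4class{ACSASeries}.
#' @seealso [writeAcsaTable()] for the exact-round-trip writer.
#' @export
readAcsaTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "index", "position_cm", "area_cm2")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  if (nrow(tab) < 2L)
    stop(sprintf("%s: need at least 2 slices", path))
  ids <- unique(tab$subject_id)
  if (length(ids) != 1L)
    stop(sprintf("%s: expected a single subject, found: %s", path,
                 paste(ids, collapse = ", ")))
  if (any(tab$area_cm2 < 0)) {
    bad <- tab$index[tab$area_cm2 < 0]
    stop(sprintf("%s: negative area at slice index %s", path,
                 paste(bad, collapse = ", ")))
  }
  ACSASeries(ids, positions = tab$position_cm, areas = tab$area_cm2,
             metadata = list(source = path))
}

#' Write an ACSA series as a CSV table
#'
#' Numeric columns are written with 17 significant digits so that
#' \code{readAcsaTable(writeAcsaTable(s))} reproduces positions and areas
#' bit-exactly.
#'
#' @param series an \linkS4class{ACSASeries}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeAcsaTable <- function(series, path) {
  stopifnot(is(series, "ACSASeries"))
  tab <- asSliceTable(series)
  lines <- c("subject_id,index,position_cm,area_cm2",
             sprintf("%s,%d,%.17g,%.17g", tab$subject_id, tab$index,
                     tab$position_cm, tab$area_cm2))
  writeLines(lines, path)
  invisible(path)
}

#' Derive an ACSA series from a 3D integer label mask
#'
#' Per axial slice, the area is the count of voxels equal to \code{label}
#' times the in-plane voxel area (converted to cm^2); slice positions are
#' slice index times the slice spacing (converted to cm). Leading and
#' trailing all-zero slices are trimmed; interior zero-area slices are
#' retained with area 0.
#'
#' @param mask a 3D integer array, or a path to a NIfTI file (read with
#'   \pkg{RNifti}).
#' @param label the target label value (default 1).
#' @param voxelDims voxel dimensions \code{c(dx, dy, dz)} in mm; taken from
#'   the NIfTI header when \code{mask} is a file path and
#'   \code{voxelDims} is \code{NULL}.
#' @param axis axial dimension of the array (default 3).
#' @param subjectId subject identifier for the resulting series.
#' @return an \linkS4class{ACSASeries}.
#' @export
seriesFromMask <- function(mask, label = 1L, voxelDims = NULL, axis = 3L,
                           subjectId = "mask") {
  src <- NULL
  if (is.character(mask)) {
    src <- mask
    img <- RNifti::readNifti(mask)
    if (is.null(voxelDims))
      voxelDims <- RNifti::pixdim(img)[1:3]
    mask <- as.array(img)
  }
  if (length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  if (is.null(voxelDims) || length(voxelDims) != 3L)
    stop("voxelDims must be c(dx, dy, dz) in mm")
  dx <- voxelDims[1L]; dy <- voxelDims[2L]; dz <- voxelDims[3L]
  if (any(c(dx, dy, dz) <= 0)) stop("voxel dimensions must be positive")
  if (abs(dx - dy) > 1e-9 * max(dx, dy))
    warning(sprintf("anisotropic in-plane voxels (dx %g mm, dy %g mm)", dx, dy))
  counts <- apply(mask == label, axis, sum)
  if (!any(counts > 0))
    stop(sprintf("label %d not present anywhere in the mask", label))
  nz <- which(counts > 0)
  keep <- seq(min(nz), max(nz))       # trim leading/trailing empties only
  if (length(keep) < 2L)
    stop("label occupies fewer than 2 axial slices")
  ACSASeries(subjectId,
             positions = (keep - 1L) * dz / 10,    # mm -> cm
             areas = counts[keep] * dx * dy / 100, # mm^2 -> cm^2
             metadata = list(source = if (is.null(src)) "array" else src,
                             label = label,
                             voxelDims_mm = c(dx, dy, dz)))
}

#' Restrict a series to the analysed quadriceps ROI
#'
#' Returns the contiguous sub-series from the distal cut to the lesser
#' trochanter slice (inclusive). The distal cut index is the smallest slice
#' index whose position is at least
#' \code{position(patella) + distalFraction * (position(trochanter) -
#' position(patella))}. Areas are never modified; the cut indices are
#' recorded in the result's metadata.
#'
#' @param series an \linkS4class{ACSASeries}.
#' @param landmarks a \linkS4class{RoiLandmarks}.
#' @return the restricted \linkS4class{ACSASeries}.
#' @export
restrictRoi <- function(series, landmarks) {
  stopifnot(is(series, "ACSASeries"), is(landmarks, "RoiLandmarks"))
  n <- nSlices(series)
  pat <- landmarks@patellaIndex
  tro <- landmarks@trochanterIndex
  if (tro > n - 1L)
    stop(sprintf("trochanterIndex %d outside series (last index %d)",
                 tro, n - 1L))
  p <- positions(series)
  cutPos <- p[pat + 1L] +
    landmarks@distalFraction * (p[tro + 1L] - p[pat + 1L])
  tol <- .spacing_rtol * sliceSpacing(series)
  cut0 <- which(p >= cutPos - tol)[1L] - 1L   # 0-based
  sel <- seq(cut0 + 1L, tro + 1L)
  if (length(sel) < 2L)
    stop("restricted ROI contains fewer than 2 slices")
  ACSASeries(subjectId(series), positions = p[sel],
             areas = areas(series)[sel], spacing = sliceSpacing(series),
             unitsNote = series@unitsNote,
             metadata = c(series@metadata,
                          list(roi = list(distalCutIndex = cut0,
                                          trochanterIndex = tro,
                                          cutPosition_cm = cutPos,
                                          distalFraction = landmarks@distalFraction))))
}
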