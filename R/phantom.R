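#' Phantom constructors
#'
#' Parametric muscle phantoms with analytically known area profiles and
#' volumes, used as ground truth for validating the volume estimators.
#'
#' \describe{
#'   \item{\code{constantPhantom}}{A(z) = \code{area}.}
#'   \item{\code{frustumPhantom}}{circular cross-section whose radius varies
#'     linearly from \code{r0} at z = 0 to \code{r1} at z = length; the
#'     truncated-cone equation is exact on it at any interval and offset.}
#'   \item{\code{quadraticPhantom}}{A(z) = c0 + c1 z + c2 z^2.}
#'   \item{\code{splinePhantom}}{natural cubic spline through control areas
#'     placed at fractions of the phantom length.}
#'   \item{\code{quadricepsPhantom}}{the default study profile: a fixed
#'     spline template over a 22 cm restricted ROI rising steeply from
#'     33 cm^2 at the distal cut to a 46.5 cm^2 peak at 60% of ROI length,
#'     declining mildly to 40 cm^2 at the lesser trochanter (integral about
#'     964 cm^3 at scale 1). The net distal-to-proximal rise (+7 cm^2) and
#'     the end-slope difference (about 3.9 cm^2/cm) set the coarse-interval
#'     bias of the cylinder and cone estimators respectively.}
#' }
#'
#' @param area constant area, cm^2.
#' @param r0,r1 end radii in cm (frustum family).
#' @param c0,c1,c2 polynomial coefficients (quadratic family).
#' @param controlFractions,controlAreas spline knots: fractions of
#'   \code{length} in [0, 1] (first 0, last 1) and areas in cm^2.
#' @param scale multiplicative area scale for the quadriceps template.
#' @param length phantom length in cm.
#' @param name display name.
#' @return a validated \linkS4class{PhantomSpec}.
#' @name phantoms
NULL

#' @rdname phantoms
#' @export
constantPhantom <- function(area, length, name = "constant") {
  new("PhantomSpec", family = "constant", parameters = list(area = area),
      length = as.numeric(length), name = name)
}

#' @rdname phantoms
#' @export
frustumPhantom <- function(r0, r1, length, name = "frustum") {
  stopifnot(r0 >= 0, r1 >= 0)
  new("PhantomSpec", family = "frustum", parameters = list(r0 = r0, r1 = r1),
      length = as.numeric(length), name = name)
}

#' @rdname phantoms
#' @export
quadraticPhantom <- function(c0, c1, c2, length, name = "quadratic") {
  new("PhantomSpec", family = "quadratic",
      parameters = list(c0 = c0, c1 = c1, c2 = c2),
      length = as.numeric(length), name = name)
}

#' @rdname phantoms
#' @export
splinePhantom <- function(controlFractions, controlAreas, length,
                          name = "spline") {
  stopifnot(length(controlFractions) == length(controlAreas),
            length(controlFractions) >= 3L,
            abs(controlFractions[1L]) < 1e-12,
            abs(controlFractions[length(controlFractions)] - 1) < 1e-12,
            !is.unsorted(controlFractions, strictly = TRUE))
  new("PhantomSpec", family = "spline",
      parameters = list(fractions = as.numeric(controlFractions),
                        areas = as.numeric(controlAreas)),
      length = as.numeric(length), name = name)
}

#' @rdname phantoms
#' @export
quadricepsPhantom <- function(scale = 1, length = 22) {
  splinePhantom(c(0, 0.2, 0.6, 0.8, 1),
                scale * c(33, 43, 46.5, 45, 40),
                length, name = "quadriceps template")
}

#' @rdname accessors
#' @aliases phantomLength,PhantomSpec-method
setMethod("phantomLength", "PhantomSpec", function(x) x@length)

.splineProfile <- function(spec) {
  stats::splinefun(spec@parameters$fractions * spec@length,
                   spec@parameters$areas, method = "natural")
}

#' @rdname areaAt
#' @aliases areaAt,PhantomSpec-method
setMethod("areaAt", "PhantomSpec", function(spec, z) {
  p <- spec@parameters
  switch(spec@family,
    constant  = rep(p$area, length(z)),
    frustum   = {
      r <- p$r0 + (p$r1 - p$r0) * z / spec@length
      pi * r^2
    },
    quadratic = p$c0 + p$c1 * z + p$c2 * z^2,
    spline    = .splineProfile(spec)(z)
  )
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec '%s' (%s family), length %g cm\n",
              object@name, object@family, object@length))
  cat(sprintf("  A(0) = %.3f cm^2, A(L) = %.3f cm^2, volume = %.3f cm^3\n",
              areaAt(object, 0), areaAt(object, object@length),
              analyticVolume(object)))
  invisible(NULL)
})

#' Analytic phantom volume
#'
#' Ground-truth volume of a phantom between two axial positions: the
#' closed-form integral of A(z) for the constant, frustum and quadratic
#' families, and knot-wise adaptive quadrature (relative tolerance 1e-10)
#' for the spline family.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param z0,z1 integration bounds in cm, \code{0 <= z0 < z1 <= length};
#'   default the whole phantom.
#' @return the volume in cm^3.
#' @export
analyticVolume <- function(spec, z0 = 0, z1 = phantomLength(spec)) {
  stopifnot(is(spec, "PhantomSpec"))
  L <- spec@length
  if (!(z0 >= -1e-12 && z0 < z1 && z1 <= L * (1 + 1e-12)))
    stop(sprintf("invalid bounds [%g, %g] for phantom of length %g", z0, z1, L))
  p <- spec@parameters
  switch(spec@family,
    constant  = p$area * (z1 - z0),
    frustum   = {
      rAt <- function(z) p$r0 + (p$r1 - p$r0) * z / L
      r1 <- rAt(z0); r2 <- rAt(z1)
      pi * (z1 - z0) * (r1^2 + r1 * r2 + r2^2) / 3
    },
    quadratic = {
      antider <- function(z) p$c0 * z + p$c1 * z^2 / 2 + p$c2 * z^3 / 3
      antider(z1) - antider(z0)
    },
    spline    = {
      f <- .splineProfile(spec)
      kz <- p$fractions * L
      knots <- unique(sort(c(z0, z1, kz[kz > z0 & kz < z1])))
      ## integrate knot-wise: the integrand is a smooth cubic on each piece
      total <- 0
      for (i in seq_len(length(knots) - 1L))
        total <- total + stats::integrate(f, knots[i], knots[i + 1L],
                                          rel.tol = 1e-10,
                                          abs.tol = 1e-10)$value
      total
    }
  )
}

#' Sample an ACSA series from a phantom
#'
#' Slice areas are \code{A(z_i) + noise}, clipped at zero, at positions
#' \code{0, spacing, 2 spacing, ...}; optional IMAT-style dropout then
#' multiplies each slice independently by \code{1 - U} with
#' \code{U ~ Uniform(0, imatDropout)}, modelling slice-wise exclusion of
#' fat-infiltrated tissue. Deterministic given \code{seed} (the caller's
#' RNG state is preserved).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param spacing slice spacing in cm (must be <= length / 2).
#' @param nSlices number of slices; default covers the whole phantom.
#' @param noiseSd Gaussian area noise SD in cm^2.
#' @param imatDropout dropout ceiling in [0, 1).
#' @param seed optional integer seed.
#' @param subjectId identifier for the resulting series.
#' @return an \linkS4class{ACSASeries}.
#' @export
sampleSeries <- function(spec, spacing = 1, nSlices = NULL, noiseSd = 0,
                         imatDropout = 0, seed = NULL,
                         subjectId = spec@name) {
  stopifnot(is(spec, "PhantomSpec"))
  L <- spec@length
  if (spacing > L / 2) stop("spacing must not exceed half the phantom length")
  if (is.null(nSlices)) nSlices <- floor(L / spacing + 1e-9) + 1L
  if ((nSlices - 1L) * spacing > L * (1 + 1e-9))
    stop("requested slices extend beyond the phantom")
  z <- (seq_len(nSlices) - 1L) * spacing
  a <- areaAt(spec, z)
  if (!is.null(seed)) {
    hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  if (noiseSd > 0) a <- a + stats::rnorm(nSlices, 0, noiseSd)
  a <- pmax(a, 0)
  if (imatDropout > 0) a <- a * (1 - stats::runif(nSlices, 0, imatDropout))
  ACSASeries(subjectId, positions = z, areas = a, spacing = spacing,
             metadata = list(phantom = spec@name, noiseSd = noiseSd,
                             imatDropout = imatDropout, seed = seed))
}

#' Voxelize a phantom into a 3D label mask
#'
#' Each axial slice rasterizes a centred disc of area A(z) (radius
#' \code{sqrt(A / pi)}) on a square in-plane grid, using the centre-of-voxel
#' inclusion rule: a voxel belongs to the muscle (label 1) when its centre
#' lies inside the disc. Intended as a fixture generator for
#' [seriesFromMask()].
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param inPlaneMm in-plane voxel size in mm (dx = dy).
#' @param sliceMm slice spacing in mm.
#' @return a list with \code{mask} (3D integer array, axial = 3rd
#'   dimension) and \code{voxelDims} (mm).
#' @export
voxelizePhantom <- function(spec, inPlaneMm = 0.5, sliceMm = 10) {
  stopifnot(is(spec, "PhantomSpec"), inPlaneMm > 0, sliceMm > 0)
  zCm <- seq(0, spec@length, by = sliceMm / 10)
  aCm2 <- pmax(areaAt(spec, zCm), 0)
  rMm <- sqrt(aCm2 / pi) * 10
  posR <- rMm[aCm2 > 0]
  if (length(posR) && inPlaneMm > min(posR))
    stop(sprintf(
      "in-plane resolution %g mm is coarser than the smallest phantom radius %g mm",
      inPlaneMm, min(posR)))
  half <- max(rMm) + 2 * inPlaneMm
  nxy <- 2L * ceiling(half / inPlaneMm)
  centres <- (seq_len(nxy) - 0.5 - nxy / 2) * inPlaneMm
  d2 <- outer(centres^2, centres^2, `+`)
  mask <- array(0L, dim = c(nxy, nxy, length(zCm)))
  for (k in seq_along(zCm))
    if (rMm[k] > 0)
      mask[, , k][d2 <= rMm[k]^2] <- 1L
  list(mask = mask, voxelDims = c(inPlaneMm, inPlaneMm, sliceMm))
}

#' Write a voxelized phantom as NIfTI
#'
#' @param vox result of [voxelizePhantom()].
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
writeMaskNifti <- function(vox, path) {
  img <- RNifti::asNifti(vox$mask,
                         reference = list(pixdim = c(-1, vox$voxelDims,
                                                     0, 0, 0, 0)),
                         datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}
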