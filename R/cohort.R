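#' Build a cohort specification
#'
#' Defaults emulate the study geometry: 38 subjects, 23 contiguous 1 cm
#' slices over the restricted quadriceps ROI, the quadriceps spline template
#' as the shared profile (cohort mean true volume about 965 cm^3),
#' between-subject variability as a lognormal area scale (sdlog 0.15, about
#' 15% CV), mild per-slice segmentation noise (SD 0.5 cm^2), and no IMAT
#' dropout.
#'
#' @param nSubjects number of subjects.
#' @param basePhantom shared \linkS4class{PhantomSpec} profile; its length
#'   must cover \code{(roiSlices - 1) * spacing}.
#' @param scaleSdLog SD of log per-subject scale factor.
#' @param roiSlices slices per subject.
#' @param spacing slice spacing in cm.
#' @param areaNoiseSd per-slice Gaussian area noise SD in cm^2.
#' @param imatDropout dropout ceiling in [0, 1).
#' @param seed integer cohort seed.
#' @return a validated \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nSubjects = 38, basePhantom = quadricepsPhantom(),
                       scaleSdLog = 0.15, roiSlices = 23, spacing = 1,
                       areaNoiseSd = 0.5, imatDropout = 0, seed = 1) {
  new("CohortSpec", nSubjects = as.integer(nSubjects),
      basePhantom = basePhantom, scaleSdLog = as.numeric(scaleSdLog),
      roiSlices = as.integer(roiSlices), spacing = as.numeric(spacing),
      areaNoiseSd = as.numeric(areaNoiseSd),
      imatDropout = as.numeric(imatDropout), seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d subjects, %d slices at %g cm, phantom '%s'\n",
    object@nSubjects, object@roiSlices, object@spacing,
    object@basePhantom@name))
  cat(sprintf(
    "  scale sdlog %g, area noise SD %g cm^2, IMAT dropout %g, seed %d\n",
    object@scaleSdLog, object@areaNoiseSd, object@imatDropout, object@seed))
  invisible(NULL)
})

#' Per-subject sub-seed derivation
#'
#' All cohort randomness flows from the cohort seed; subject i's series is
#' drawn with \code{(seed * 10007 + i) mod (2^31 - 1)}, so any subject can
#' be regenerated in isolation from the manifest.
#'
#' @param seed cohort seed.
#' @param i subject number (1-based).
#' @return integer sub-seed.
#' @export
subjectSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(i)) %% 2147483647)
}

#' Generate a synthetic cohort with known true volumes
#'
#' Each subject's profile is the base phantom scaled by an independent
#' lognormal factor; the ACSA series is then sampled with the configured
#' noise and dropout via [sampleSeries()] using the subject's sub-seed. The
#' true volume is the analytic volume of the scaled, noiseless profile over
#' the sampled span \code{[0, (roiSlices - 1) * spacing]} (the span between
#' the first and last slice).
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @return an object of class \code{muscleCohort}: a list with
#'   \code{series} (list of \linkS4class{ACSASeries}), \code{manifest}
#'   (data.frame \code{subject_id}, \code{seed}, \code{scale},
#'   \code{true_volume_cm3}) and \code{spec}.
#' @examples
#' coh <- generateCohort(cohortSpec(nSubjects = 3, seed = 7))
#' coh$manifest
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  n <- spec@nSubjects
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(spec@seed)
  scales <- exp(stats::rnorm(n, 0, spec@scaleSdLog))
  seeds <- vapply(seq_len(n), function(i) subjectSeed(spec@seed, i),
                  integer(1))
  span <- (spec@roiSlices - 1L) * spec@spacing
  ids <- sprintf("S%03d", seq_len(n))
  series <- vector("list", n)
  trueVol <- numeric(n)
  for (i in seq_len(n)) {
    ph <- scalePhantom(spec@basePhantom, scales[i])
    series[[i]] <- sampleSeries(ph, spacing = spec@spacing,
                                nSlices = spec@roiSlices,
                                noiseSd = spec@areaNoiseSd,
                                imatDropout = spec@imatDropout,
                                seed = seeds[i], subjectId = ids[i])
    trueVol[i] <- analyticVolume(ph, 0, span)
  }
  names(series) <- ids
  structure(list(
    series = series,
    manifest = data.frame(subject_id = ids, seed = seeds, scale = scales,
                          true_volume_cm3 = trueVol,
                          stringsAsFactors = FALSE),
    spec = spec), class = "muscleCohort")
}

#' @export
print.muscleCohort <- function(x, ...) {
  cat(sprintf("muscleCohort: %d subjects, mean true volume %.1f cm^3\n",
              length(x$series), mean(x$manifest$true_volume_cm3)))
  invisible(x)
}

#' Scale a phantom's area profile
#'
#' Multiplies A(z) by \code{factor} everywhere (for the frustum family the
#' radii are scaled by \code{sqrt(factor)}).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param factor positive area scale factor.
#' @return the scaled \linkS4class{PhantomSpec}.
#' @export
scalePhantom <- function(spec, factor) {
  stopifnot(is(spec, "PhantomSpec"), factor > 0)
  p <- spec@parameters
  p <- switch(spec@family,
    constant  = list(area = p$area * factor),
    frustum   = list(r0 = p$r0 * sqrt(factor), r1 = p$r1 * sqrt(factor)),
    quadratic = list(c0 = p$c0 * factor, c1 = p$c1 * factor,
                     c2 = p$c2 * factor),
    spline    = list(fractions = p$fractions, areas = p$areas * factor)
  )
  new("PhantomSpec", family = spec@family, parameters = p,
      length = spec@length, name = spec@name)
}

#' Write a cohort as per-subject CSV files plus a manifest
#'
#' @param cohort a \code{muscleCohort} from [generateCohort()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "muscleCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$series)
    writeAcsaTable(s, file.path(dir, paste0(subjectId(s), ".csv")))
  man <- cohort$manifest
  lines <- c("subject_id,seed,true_volume_cm3",
             sprintf("%s,%d,%.17g", man$subject_id, man$seed,
                     man$true_volume_cm3))
  writeLines(lines, file.path(dir, "cohort_manifest.csv"))
  invisible(dir)
}
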