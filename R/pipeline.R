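#' Read and validate a run configuration
#'
#' The YAML mirrors the arguments of [runStudy()]: \code{input_mode}
#' (\code{synthetic}, \code{csv_dir} or \code{mask_dir}), \code{cohort}
#' (a mapping of [cohortSpec()] arguments, synthetic mode), \code{input_dir},
#' \code{intervals}, \code{equations}, \code{offset_policy}, \code{end_rule},
#' \code{roi} (mapping with \code{patella_index}, \code{trochanter_index},
#' \code{distal_fraction}, or absent for pre-restricted input),
#' \code{output_dir}, \code{seed}, \code{plots}.
#'
#' @param path YAML file path.
#' @return a validated config list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param config a config list as produced by [readRunConfig()] or built in
#'   code.
#' @export
validateRunConfig <- function(config) {
  defaults <- list(input_mode = "synthetic", intervals = c(1, 2, 3, 4),
                   equations = c("cylinder", "truncated_cone"),
                   offset_policy = "first", end_rule = "partial",
                   seed = 1L, plots = FALSE, log_level = "info")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (!config$input_mode %in% c("synthetic", "csv_dir", "mask_dir"))
    stop(sprintf("unknown input_mode '%s'", config$input_mode))
  if (length(config$intervals) < 2L)
    stop("intervals must include the reference and at least one comparison")
  if (is.null(config$output_dir)) stop("output_dir is required")
  config$intervals <- sort(as.numeric(config$intervals))
  config
}

.studyRoi <- function(config) {
  if (is.null(config$roi)) return(NULL)
  roiLandmarks(config$roi$patella_index, config$roi$trochanter_index,
               if (is.null(config$roi$distal_fraction)) 0.20
               else config$roi$distal_fraction)
}

.loadStudySeries <- function(config) {
  if (config$input_mode == "csv_dir") {
    files <- list.files(config$input_dir, pattern = "\\.csv$",
                        full.names = TRUE)
    files <- files[basename(files) != "cohort_manifest.csv"]
    if (!length(files)) stop(sprintf("no CSV files in %s", config$input_dir))
    lapply(files, function(f)
      tryCatch(readAcsaTable(f),
               error = function(e) stop(sprintf(
                 "failed to read '%s': %s", f, conditionMessage(e)),
                 call. = FALSE)))
  } else {
    files <- list.files(config$input_dir, pattern = "\\.nii(\\.gz)?$",
                        full.names = TRUE)
    if (!length(files)) stop(sprintf("no NIfTI files in %s", config$input_dir))
    lapply(files, function(f)
      tryCatch(seriesFromMask(f, label = config$label %||% 1L,
                              subjectId = sub("\\.nii(\\.gz)?$", "",
                                              basename(f))),
               error = function(e) stop(sprintf(
                 "failed to read '%s': %s", f, conditionMessage(e)),
                 call. = FALSE)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeStudyTable <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer,
                                                      logical(1))
  out <- df
  for (nm in names(df)[num]) out[[nm]] <- sprintf("%.12g", df[[nm]])
  lines <- c(paste(names(out), collapse = ","),
             do.call(paste, c(unname(as.list(out)), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full slice-interval study
#'
#' Orchestrates the experiment end to end: obtain a cohort of ACSA series
#' (synthetic via [generateCohort()], or loaded from per-subject CSV tables
#' or NIfTI label masks), optionally restrict the ROI, run the
#' interval-by-equation experiment for every subject, and write the volume,
#' error and agreement tables (plus Bland-Altman plots on request) to the
#' output directory. Outputs are deterministic given the configuration and
#' seed. If any subject fails, partial outputs are removed and the error
#' names the subject.
#'
#' @param config configuration list (see [readRunConfig()]) or a YAML path.
#' @param outputDir overrides \code{config$output_dir}.
#' @param seed overrides \code{config$seed}.
#' @return invisibly, a list with \code{volumes}, \code{errors},
#'   \code{agreement}, and (synthetic mode) \code{manifest} and
#'   \code{oracle}.
#' @export
runStudy <- function(config, outputDir = NULL, seed = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- validateRunConfig(config)
  if (!is.null(outputDir)) config$output_dir <- outputDir
  if (!is.null(seed)) config$seed <- as.integer(seed)
  outDir <- config$output_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  cleanup <- function() unlink(written)

  manifest <- NULL
  if (config$input_mode == "synthetic") {
    cargs <- config$cohort %||% list()
    names(cargs) <- sub("^n_subjects$", "nSubjects",
                   sub("^scale_sd_log$", "scaleSdLog",
                   sub("^roi_slices$", "roiSlices",
                   sub("^area_noise_sd$", "areaNoiseSd",
                   sub("^imat_dropout$", "imatDropout", names(cargs))))))
    cargs$seed <- config$seed
    spec <- do.call(cohortSpec, cargs)
    cohort <- generateCohort(spec)
    seriesList <- cohort$series
    manifest <- cohort$manifest
  } else {
    seriesList <- .loadStudySeries(config)
  }

  roi <- .studyRoi(config)
  volumes <- tryCatch({
    do.call(rbind, lapply(seriesList, function(s) {
      if (!is.null(roi)) s <- restrictRoi(s, roi)
      runIntervalExperiment(s, intervals = config$intervals,
                            equations = config$equations,
                            offsetPolicy = config$offset_policy,
                            endRule = config$end_rule)
    }))
  }, error = function(e) {
    cleanup()
    stop(sprintf("study aborted: %s", conditionMessage(e)), call. = FALSE)
  })
  rownames(volumes) <- NULL
  errors <- computeErrors(volumes)
  agreement <- summarizeByCell(errors)

  paths <- file.path(outDir, c("volumes.csv", "errors.csv", "agreement.csv"))
  .writeStudyTable(volumes, paths[1L]); written <- c(written, paths[1L])
  .writeStudyTable(errors, paths[2L]); written <- c(written, paths[2L])
  .writeStudyTable(agreement, paths[3L]); written <- c(written, paths[3L])

  oracle <- NULL
  if (!is.null(manifest)) {
    ref <- volumes[volumes$interval_cm == min(volumes$interval_cm) &
                   volumes$offset_cm == 0 &
                   volumes$equation == "truncated_cone", , drop = FALSE]
    oracle <- merge(manifest[, c("subject_id", "true_volume_cm3")],
                    ref[, c("subject_id", "volume_cm3")], by = "subject_id")
    names(oracle)[names(oracle) == "volume_cm3"] <- "estimate_1cm_cone_cm3"
    oracle$rel_err_pct <- 100 *
      abs(oracle$estimate_1cm_cone_cm3 - oracle$true_volume_cm3) /
      oracle$true_volume_cm3
    manPath <- file.path(outDir, "cohort_manifest.csv")
    .writeStudyTable(manifest, manPath); written <- c(written, manPath)
    orPath <- file.path(outDir, "oracle_vs_estimate.csv")
    .writeStudyTable(oracle, orPath); written <- c(written, orPath)
  }

  cfgPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(config, cfgPath)
  logPath <- file.path(outDir, "run_log.txt")
  writeLines(c(sprintf("musclevol runStudy; seed %d", config$seed),
               sprintf("input_mode: %s; subjects: %d", config$input_mode,
                       length(seriesList)),
               sprintf("intervals: %s; equations: %s; end_rule: %s",
                       paste(config$intervals, collapse = ","),
                       paste(config$equations, collapse = ","),
                       config$end_rule)),
             logPath)

  if (isTRUE(config$plots)) {
    refInt <- min(config$intervals)
    for (eq in unique(errors$equation))
      for (k in unique(errors$interval_cm)) {
        cell <- errors[errors$equation == eq & errors$interval_cm == k &
                       errors$offset_cm == 0, , drop = FALSE]
        if (nrow(cell) < 3L) next
        f <- file.path(outDir, sprintf("bland_altman_%s_%gcm.pdf", eq, k))
        grDevices::pdf(f, width = 5, height = 4)
        plotBlandAltman(cell$reference_cm3, cell$comparison_cm3,
                        main = sprintf("%s, %g cm vs %g cm", eq, refInt, k))
        grDevices::dev.off()
      }
  }

  invisible(list(volumes = volumes, errors = errors, agreement = agreement,
                 manifest = manifest, oracle = oracle))
}

#' Correlate muscle volume with L3 skeletal muscle index
#'
#' Joins a volumes table with per-subject L3 SMI values (cm^2/m^2) and
#' computes the Pearson correlation, by default on the truncated-cone 4 cm
#' estimates. Unmatched subjects are dropped with a warning; fewer than 3
#' matches is an error. L3 SMI is always an input column, never computed.
#'
#' @param volumes estimates table from [runIntervalExperiment()] /
#'   [runStudy()].
#' @param smi data.frame with columns \code{subject_id} and \code{l3_smi}.
#' @param equation,intervalCm which estimate to correlate (defaults:
#'   truncated cone at 4 cm).
#' @return a list with \code{r}, \code{rSquared}, \code{pValue}, \code{n}
#'   and the matched \code{data}.
#' @export
correlateWithSmi <- function(volumes, smi, equation = "truncated_cone",
                             intervalCm = 4) {
  stopifnot(all(c("subject_id", "l3_smi") %in% names(smi)))
  sel <- volumes[volumes$equation == equation &
                 volumes$interval_cm == intervalCm &
                 volumes$offset_cm == 0, c("subject_id", "volume_cm3")]
  matched <- merge(sel, smi, by = "subject_id")
  dropped <- setdiff(union(sel$subject_id, smi$subject_id),
                     matched$subject_id)
  if (length(dropped))
    warning(sprintf("dropping %d unmatched subject(s): %s", length(dropped),
                    paste(dropped, collapse = ", ")))
  if (nrow(matched) < 3L)
    stop("fewer than 3 matched subjects")
  ct <- pearsonCorrelation(matched$volume_cm3, matched$l3_smi)
  c(ct, list(data = matched))
}
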