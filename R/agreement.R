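#' Per-subject error records against the reference interval
#'
#' For every (subject, equation, interval) with interval above the
#' reference, computes the signed difference reference minus comparison,
#' its absolute value (cm^3) and the relative error as a percentage of the
#' reference volume. The reference is the estimate of the same subject and
#' equation at the smallest interval present (1 cm in the study design),
#' offset 0.
#'
#' @param estimates estimates table from [runIntervalExperiment()] (rows
#'   from several subjects may be concatenated).
#' @param referenceInterval reference interval in cm; defaults to the
#'   smallest interval in the table.
#' @return a data.frame with columns \code{subject_id}, \code{equation},
#'   \code{interval_cm}, \code{offset_cm}, \code{reference_cm3},
#'   \code{comparison_cm3}, \code{signed_diff_cm3}, \code{abs_err_cm3},
#'   \code{rel_err_pct}.
#' @export
computeErrors <- function(estimates, referenceInterval = NULL) {
  needed <- c("subject_id", "equation", "interval_cm", "offset_cm",
              "volume_cm3")
  stopifnot(all(needed %in% names(estimates)))
  if (is.null(referenceInterval))
    referenceInterval <- min(estimates$interval_cm)
  out <- list()
  for (sid in unique(estimates$subject_id)) {
    for (eq in unique(estimates$equation[estimates$subject_id == sid])) {
      sub <- estimates[estimates$subject_id == sid &
                       estimates$equation == eq, , drop = FALSE]
      refRow <- sub[sub$interval_cm == referenceInterval &
                    sub$offset_cm == 0, , drop = FALSE]
      if (nrow(refRow) != 1L)
        stop(sprintf(
          "subject '%s', equation '%s': no unique %g cm reference estimate",
          sid, eq, referenceInterval))
      ref <- refRow$volume_cm3
      cmp <- sub[sub$interval_cm > referenceInterval, , drop = FALSE]
      if (!nrow(cmp)) next
      d <- ref - cmp$volume_cm3
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, equation = eq, interval_cm = cmp$interval_cm,
        offset_cm = cmp$offset_cm, reference_cm3 = ref,
        comparison_cm3 = cmp$volume_cm3, signed_diff_cm3 = d,
        abs_err_cm3 = abs(d), rel_err_pct = 100 * abs(d) / ref,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no comparison intervals above the reference")
  do.call(rbind, out)
}

#' Bland-Altman agreement between two measurement sets
#'
#' Differences are reference minus comparison; the bias is their mean and
#' the 95% limits of agreement (LOA) are bias +/- 1.96 times the sample SD
#' (denominator n - 1). Points are counted as within the LOA on the closed
#' interval (boundary points included).
#'
#' @param reference,comparison paired numeric vectors (n >= 3).
#' @return a list with \code{n}, \code{meanBias}, \code{sdDiff},
#'   \code{loaLow}, \code{loaHigh}, \code{nWithinLoa}, and the per-pair
#'   \code{differences} and \code{means} (for plotting).
#' @export
blandAltman <- function(reference, comparison) {
  if (length(reference) != length(comparison))
    stop("reference and comparison must have equal length")
  n <- length(reference)
  if (n < 3L) stop("Bland-Altman needs at least 3 pairs (SD unstable)")
  d <- reference - comparison
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1.96, 1.96) * s
  list(n = n, meanBias = bias, sdDiff = s, loaLow = loa[1L],
       loaHigh = loa[2L],
       nWithinLoa = sum(d >= loa[1L] & d <= loa[2L]),
       differences = d, means = (reference + comparison) / 2)
}

#' Bland-Altman plot
#'
#' Differences (reference minus comparison) against pair means, with the
#' mean-bias line (solid) and the 95% limits of agreement (dashed).
#'
#' @param reference,comparison paired numeric vectors.
#' @param main plot title.
#' @param xlab,ylab axis labels.
#' @return the [blandAltman()] summary, invisibly.
#' @export
plotBlandAltman <- function(reference, comparison,
                            main = "Bland-Altman",
                            xlab = "Mean volume (cm³)",
                            ylab = "Difference, 1 cm - k cm (cm³)") {
  ba <- blandAltman(reference, comparison)
  graphics::plot(ba$means, ba$differences, pch = 19, main = main,
                 xlab = xlab, ylab = ylab,
                 ylim = range(c(ba$differences, ba$loaLow, ba$loaHigh)))
  graphics::abline(h = ba$meanBias, col = "blue", lwd = 2)
  graphics::abline(h = c(ba$loaLow, ba$loaHigh), col = "red", lty = 2)
  invisible(ba)
}

#' Two-way mixed intraclass correlation for inter-rater reliability
#'
#' Single-rater ICC from the two-way (subjects x raters) mean squares.
#' The default \code{type = "consistency"} is ICC(3,1),
#' \eqn{(MS_R - MS_E) / (MS_R + (k-1) MS_E)}, appropriate for a fixed set
#' of raters and invariant to a constant shift in one rater's scores;
#' \code{type = "agreement"} is the absolute-agreement form ICC(A,1).
#' 95% confidence intervals follow the F-distribution bounds of
#' McGraw & Wong.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns
#'   (>= 5 subjects, >= 2 raters, no missing cells).
#' @param type \code{"consistency"} (default) or \code{"agreement"}.
#' @param conf confidence level (default 0.95).
#' @param clip if \code{TRUE} (default), a negative point estimate is
#'   reported as 0 with a warning.
#' @return a list with \code{icc}, \code{ciLow}, \code{ciHigh},
#'   \code{type}, \code{nSubjects}, \code{nRaters} and the mean squares.
#' @export
iccTwoWayMixed <- function(ratings, type = c("consistency", "agreement"),
                           conf = 0.95, clip = TRUE) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings must not contain missing cells")
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 5L) stop("need at least 5 subjects")
  if (k < 2L) stop("need at least 2 raters")
  g <- mean(ratings)
  rm <- rowMeans(ratings)
  cm <- colMeans(ratings)
  msr <- k * sum((rm - g)^2) / (n - 1)
  msc <- n * sum((cm - g)^2) / (k - 1)
  mse <- sum((ratings - outer(rm, rep(1, k)) -
              outer(rep(1, n), cm) + g)^2) / ((n - 1) * (k - 1))
  alpha <- 1 - conf
  if (type == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    fobs <- msr / mse
    fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    ci <- c(
      n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr),
      n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr))
  }
  if (clip && is.finite(icc) && icc < 0) {
    warning("negative ICC estimate clipped to 0")
    icc <- 0
  }
  list(icc = icc, ciLow = min(ci), ciHigh = max(ci), type = type,
       nSubjects = n, nRaters = k, msSubjects = msr, msRaters = msc,
       msError = mse)
}

#' Pearson correlation with r-squared and two-sided p-value
#'
#' Thin wrapper over [stats::cor.test()] with precondition checks (equal
#' lengths, n >= 3, non-constant vectors).
#'
#' @param x,y numeric vectors.
#' @return a list with \code{r}, \code{rSquared}, \code{pValue}, \code{n}.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, rSquared = r^2, pValue = ct$p.value, n = length(x))
}

#' Agreement summary per (equation x interval) cell
#'
#' Aggregates the error records of [computeErrors()] into one row per
#' equation and interval: Bland-Altman bias and 95% LOA of the signed
#' differences, the within-LOA count, and mean +/- SD of the absolute and
#' relative errors. This is the per-cell table a downstream two-way ANOVA
#' would consume. With a single subject the SDs are reported as 0 and
#' flagged via \code{n = 1}.
#'
#' @param errors error records from [computeErrors()] (offset 0 rows are
#'   used).
#' @return a data.frame with columns \code{equation}, \code{interval_cm},
#'   \code{n}, \code{mean_bias_cm3}, \code{loa_low_cm3}, \code{loa_high_cm3},
#'   \code{n_within_loa}, \code{mean_abs_err_cm3}, \code{sd_abs_err_cm3},
#'   \code{mean_rel_err_pct}, \code{sd_rel_err_pct}.
#' @export
summarizeByCell <- function(errors) {
  stopifnot(nrow(errors) > 0)
  errors <- errors[errors$offset_cm == 0, , drop = FALSE]
  cells <- unique(errors[, c("equation", "interval_cm")])
  cells <- cells[order(cells$equation, cells$interval_cm), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- errors[errors$equation == cells$equation[i] &
                   errors$interval_cm == cells$interval_cm[i], , drop = FALSE]
    d <- cell$signed_diff_cm3
    n <- length(d)
    s <- if (n > 1L) stats::sd(d) else 0
    loa <- mean(d) + c(-1.96, 1.96) * s
    data.frame(
      equation = cells$equation[i], interval_cm = cells$interval_cm[i],
      n = n, mean_bias_cm3 = mean(d), loa_low_cm3 = loa[1L],
      loa_high_cm3 = loa[2L],
      n_within_loa = sum(d >= loa[1L] & d <= loa[2L]),
      mean_abs_err_cm3 = mean(cell$abs_err_cm3),
      sd_abs_err_cm3 = if (n > 1L) stats::sd(cell$abs_err_cm3) else 0,
      mean_rel_err_pct = mean(cell$rel_err_pct),
      sd_rel_err_pct = if (n > 1L) stats::sd(cell$rel_err_pct) else 0,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
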