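makeEstimates <- function(sid, eq, intervals, volumes) {
  data.frame(subject_id = sid, equation = eq, interval_cm = intervals,
             offset_cm = 0, volume_cm3 = volumes, n_slices = 10,
             stringsAsFactors = FALSE)
}

test_that("error records carry sign, absolute and relative error correctly", {
  est <- rbind(makeEstimates("a", "cylinder", c(1, 2, 3),
                             c(1000, 990, 1010)),
               makeEstimates("b", "cylinder", c(1, 2), c(500, 500)))
  err <- computeErrors(est)
  a2 <- err[err$subject_id == "a" & err$interval_cm == 2, ]
  expect_equal(a2$signed_diff_cm3, 10)
  expect_equal(a2$abs_err_cm3, 10)
  expect_equal(a2$rel_err_pct, 1.0)
  a3 <- err[err$subject_id == "a" & err$interval_cm == 3, ]
  expect_equal(a3$signed_diff_cm3, -10)      # overestimation
  expect_equal(a3$abs_err_cm3, 10)
  expect_equal(a3$rel_err_pct, 1.0)
  b2 <- err[err$subject_id == "b", ]
  expect_equal(b2$signed_diff_cm3, 0)        # identity comparison
  expect_equal(b2$rel_err_pct, 0)

  noRef <- makeEstimates("c", "cylinder", c(2, 3), c(1, 1))
  expect_error(computeErrors(noRef, referenceInterval = 1), "c")
})

test_that("Bland-Altman bias and LOA match hand-computed values", {
  ba <- blandAltman(c(1, -1, 1, -1), rep(0, 4))
  expect_equal(ba$meanBias, 0)
  expect_equal(ba$sdDiff, sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(ba$loaHigh, 1.96 * sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(ba$loaLow, -1.96 * sqrt(4 / 3), tolerance = 1e-12)

  # zero variance collapses the LOA onto the bias; boundary counts as within
  ba5 <- blandAltman(c(6, 6, 6), c(1, 1, 1))
  expect_equal(ba5$meanBias, 5)
  expect_equal(ba5$loaLow, 5)
  expect_equal(ba5$loaHigh, 5)
  expect_equal(ba5$nWithinLoa, 3L)

  expect_error(blandAltman(1:2, 1:2), "at least 3")
})

test_that("bias is antisymmetric and LOA width invariant under swapping", {
  set.seed(3)
  x <- rnorm(40, 900, 80)
  y <- x + rnorm(40, 5, 8)
  ab <- blandAltman(x, y)
  ba <- blandAltman(y, x)
  expect_equal(ab$meanBias, -ba$meanBias)
  expect_equal(ab$loaHigh - ab$loaLow, ba$loaHigh - ba$loaLow)
})

test_that("error metrics scale correctly under uniform volume rescaling", {
  est <- rbind(makeEstimates("a", "cylinder", c(1, 2), c(1000, 980)),
               makeEstimates("b", "cylinder", c(1, 2), c(800, 790)))
  err1 <- computeErrors(est)
  est2 <- est
  est2$volume_cm3 <- est2$volume_cm3 * 3
  err3 <- computeErrors(est2)
  expect_equal(err3$rel_err_pct, err1$rel_err_pct)       # invariant
  expect_equal(err3$abs_err_cm3, 3 * err1$abs_err_cm3)   # linear
})

test_that("ICC(3,1) matches an independent aov-based route and is consistent", {
  set.seed(21)
  subj <- rnorm(12, 900, 90)
  ratings <- cbind(subj + rnorm(12, 0, 6), subj + rnorm(12, 0, 6))
  res <- iccTwoWayMixed(ratings)
  expect_equal(res$icc, iccViaAov(ratings), tolerance = 1e-12)
  expect_gt(res$ciHigh, res$icc)
  expect_lt(res$ciLow, res$icc)

  # perfect agreement
  perfect <- cbind(subj[1:8], subj[1:8])
  expect_equal(iccTwoWayMixed(perfect)$icc, 1)

  # consistency form is invariant to a constant shift in one rater
  shifted <- ratings
  shifted[, 2] <- shifted[, 2] + 50
  expect_equal(iccTwoWayMixed(shifted)$icc, res$icc, tolerance = 1e-12)
  # ... unlike absolute agreement
  expect_lt(iccTwoWayMixed(shifted, type = "agreement")$icc,
            iccTwoWayMixed(ratings, type = "agreement")$icc)

  expect_error(iccTwoWayMixed(ratings[1:3, ]), "at least 5")
  ratings[2, 2] <- NA
  expect_error(iccTwoWayMixed(ratings), "missing")
})

test_that("independent raters give near-zero ICC at large n", {
  set.seed(31)
  r1 <- rnorm(5000, 900, 90)
  r2 <- sample(r1)
  res <- iccTwoWayMixed(cbind(r1, r2), clip = FALSE)
  expect_lt(abs(res$icc), 0.05)
  # negative estimates are clipped to zero with a warning by default
  anti <- cbind(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1))
  expect_warning(resClip <- iccTwoWayMixed(anti), "clipped")
  expect_equal(resClip$icc, 0)
})

test_that("Pearson wrapper handles exact linearity and degenerate input", {
  x <- c(1, 3, 5, 9, 11)
  expect_equal(pearsonCorrelation(x, 2 * x + 3)$r, 1)
  expect_equal(pearsonCorrelation(x, 2 * x + 3)$rSquared, 1)
  expect_equal(pearsonCorrelation(x, -x)$r, -1)
  expect_error(pearsonCorrelation(x, rep(2, 5)), "constant")
  expect_error(pearsonCorrelation(x, 1:4), "equal length")
})

test_that("sample r^2 concentrates near the population value 0.44", {
  set.seed(77)
  rho <- sqrt(0.44)
  r2 <- replicate(2000, {
    x <- rnorm(30)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(30)
    pearsonCorrelation(x, y)$rSquared
  })
  expect_lt(abs(mean(r2) - 0.44), 0.05)
})

test_that("cell summaries aggregate errors with flagged degenerate SDs", {
  est <- rbind(makeEstimates("a", "cylinder", 1:4, c(1000, 995, 990, 985)),
               makeEstimates("a", "truncated_cone", 1:4,
                             c(1000, 998, 996, 994)),
               makeEstimates("b", "cylinder", 1:4, c(900, 897, 894, 891)),
               makeEstimates("b", "truncated_cone", 1:4,
                             c(900, 899, 898, 897)))
  cells <- summarizeByCell(computeErrors(est))
  expect_equal(nrow(cells), 6L)            # 2 equations x 3 intervals
  expect_equal(unique(cells$n), 2L)

  single <- summarizeByCell(computeErrors(
    makeEstimates("a", "cylinder", c(1, 2), c(1000, 990))))
  expect_equal(single$n, 1L)
  expect_equal(single$sd_abs_err_cm3, 0)
  expect_equal(single$loa_low_cm3, single$mean_bias_cm3)
})
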