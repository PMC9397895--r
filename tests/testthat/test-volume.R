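test_that("subsampling selects the arithmetic stride and validates input", {
  s <- makeSeries(1:9)                       # 9 slices at 1 cm
  sub2 <- subsampleSeries(s, 2)
  expect_equal(sub2@metadata$subsample$source_indices, c(0, 2, 4, 6, 8))
  expect_equal(sliceSpacing(sub2), 2)
  sub4 <- subsampleSeries(s, 4)
  expect_equal(sub4@metadata$subsample$source_indices, c(0, 4, 8))
  expect_equal(areas(subsampleSeries(s, 1)), areas(s))  # identity

  sub41 <- subsampleSeries(s, 4, offsetSlices = 1)
  expect_equal(sub41@metadata$subsample$source_indices, c(1, 5))

  expect_error(subsampleSeries(s, 2.5), "integer multiple")
  expect_error(subsampleSeries(s, 4, offsetSlices = 4), "offsetSlices")
  expect_error(subsampleSeries(makeSeries(1:3), 3), "fewer than 2")
})

test_that("cylindrical volume is the literal area sum times spacing", {
  expect_equal(volumeCylinder(makeSeries(rep(10, 5))), 50)
  expect_equal(volumeCylinder(makeSeries(c(10, 20, 30), spacing = 2)), 120)
})

test_that("cylinder at 1 cm tracks the quadrature oracle of a smooth profile", {
  # A(z) = 60 + 8z - 0.4z^2; the 1 cm cylinder sum covers [0, 21] cm
  ph <- quadraticPhantom(60, 8, -0.4, length = 21)
  s <- phantomSeries(ph, spacing = 1, nSlices = 21)  # slices at 0..20
  expect_equal(volumeCylinder(s), 1792)      # direct sum, frozen
  oracle <- analyticVolume(ph, 0, 21)        # closed form = 1789.2
  expect_equal(oracle, 1789.2, tolerance = 1e-12)
  expect_lt(abs(volumeCylinder(s) - oracle) / oracle, 0.005)
})

test_that("truncated cone matches frustum closed forms", {
  # two equal slices degenerate to a cylinder
  expect_equal(volumeTruncatedCone(makeSeries(c(12, 12))), 12)
  # circular frustum, radii 1 and 2 cm over 3 cm: V = 7*pi
  s <- ACSASeries("f", positions = c(0, 3), areas = c(pi, 4 * pi))
  expect_equal(volumeTruncatedCone(s), 7 * pi, tolerance = 1e-12)
  # single-slice series cannot even be constructed
  expect_error(ACSASeries("x", positions = 0, areas = 5, spacing = 1),
               "2 slices")
})

test_that("truncated cone is exact on conical phantoms at any interval and offset", {
  ph <- frustumPhantom(r0 = 2, r1 = 3.5, length = 24)
  s <- phantomSeries(ph, spacing = 1)        # 25 slices, 0..24
  for (interval in 1:4) {
    for (off in seq_len(interval) - 1L) {
      sub <- subsampleSeries(s, interval, off)
      span <- range(positions(sub))
      truth <- analyticVolume(ph, span[1], span[2])
      expect_lt(abs(volumeTruncatedCone(sub) - truth) / truth, 1e-9)
    }
  }
  # the partial end rule stays exact: estimate covers [offset, L]
  est <- runIntervalExperiment(s, intervals = c(3), equations = "truncated_cone",
                               offsetPolicy = "all", endRule = "partial")
  for (i in seq_len(nrow(est))) {
    truth <- analyticVolume(ph, est$offset_cm[i], 24)
    expect_lt(abs(est$volume_cm3[i] - truth) / truth, 1e-9)
  }
})

test_that("constant profiles expose the end-segment asymmetry exactly", {
  s <- makeSeries(rep(7, 11), spacing = 1)
  expect_equal(volumeCylinder(s), 11 * 7)        # N * A * spacing
  expect_equal(volumeTruncatedCone(s), 10 * 7)   # (N - 1) * A * spacing
  # zero-area slices are legal and sqrt(0 * A) = 0 is handled exactly
  z <- makeSeries(c(4, 0, 4))
  expect_equal(volumeTruncatedCone(z), 8 / 3)
})

test_that("experiment cardinality follows intervals x equations x offsets", {
  s <- makeSeries(40 + sin(1:23))
  est <- runIntervalExperiment(s)
  expect_equal(nrow(est), 8L)
  expect_equal(sort(unique(est$interval_cm)), 1:4)

  all4 <- runIntervalExperiment(s, intervals = 4, offsetPolicy = "all")
  expect_equal(nrow(all4), 8L)                   # 4 offsets x 2 equations
  expect_equal(sort(unique(all4$offset_cm)), 0:3)
})

test_that("end rules differ by exactly the analytic remainder terms", {
  a <- 30 + sqrt(seq_len(23))
  s <- makeSeries(a)
  drop4 <- runIntervalExperiment(s, intervals = 4, endRule = "drop")
  part4 <- runIntervalExperiment(s, intervals = 4, endRule = "partial")
  sel <- c(1, 5, 9, 13, 17, 21)                  # 0,4,...,20 in 0-based terms
  cylDrop <- 4 * sum(a[sel])
  expect_equal(drop4$volume_cm3[drop4$equation == "cylinder"], cylDrop)
  # partial: last selected slice extruded only 3 cm (to the series end at 23)
  expect_equal(part4$volume_cm3[part4$equation == "cylinder"],
               cylDrop - 1 * a[21])
  coneDrop <- sum((4 / 3) * (a[sel[-6]] + sqrt(a[sel[-6]] * a[sel[-1]]) +
                             a[sel[-1]]))
  expect_equal(drop4$volume_cm3[drop4$equation == "truncated_cone"], coneDrop)
  # partial: closing frustum of height 2 cm between slices 20 and 22
  expect_equal(part4$volume_cm3[part4$equation == "truncated_cone"],
               coneDrop + (2 / 3) * (a[21] + sqrt(a[21] * a[23]) + a[23]))
  # no remainder at 1 cm: the rules coincide
  expect_equal(runIntervalExperiment(s, intervals = 1, endRule = "drop"),
               runIntervalExperiment(s, intervals = 1, endRule = "partial"))
})

test_that("volumes are equivariant under area and spacing rescaling", {
  set.seed(11)
  a <- runif(17, 20, 50)
  s <- makeSeries(a, spacing = 1)
  for (c in c(0.5, 3)) {
    sa <- makeSeries(c * a, spacing = 1)
    expect_equal(volumeCylinder(sa), c * volumeCylinder(s))
    expect_equal(volumeTruncatedCone(sa), c * volumeTruncatedCone(s))
    ss <- makeSeries(a, spacing = c)
    expect_equal(volumeCylinder(ss), c * volumeCylinder(s))
    expect_equal(volumeTruncatedCone(ss), c * volumeTruncatedCone(s))
  }
})
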