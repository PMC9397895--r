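# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

makeSeries <- function(areas, spacing = 1, id = "T01", start = 0) {
  ACSASeries(id, positions = start + (seq_along(areas) - 1) * spacing,
             areas = areas, spacing = spacing)
}

# Series sampled exactly from a phantom at given positions.
phantomSeries <- function(spec, spacing, nSlices = NULL, id = spec@name) {
  sampleSeries(spec, spacing = spacing, nSlices = nSlices, subjectId = id)
}

# Default study cohort at a given seed.
studyCohort <- function(seed = 1, n = 38, ...) {
  generateCohort(cohortSpec(nSubjects = n, seed = seed, ...))
}

cohortSummary <- function(cohort, ...) {
  vols <- do.call(rbind, lapply(cohort$series, runIntervalExperiment, ...))
  summarizeByCell(computeErrors(vols))
}

# Independent ICC(3,1) route via stats::aov mean squares, used as a
# cross-check oracle against the closed-form implementation.
iccViaAov <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  d <- data.frame(y = as.vector(ratings),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; mse <- ms[3]
  unname((msr - mse) / (msr + (k - 1) * mse))
}
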