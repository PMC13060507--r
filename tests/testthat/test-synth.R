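alphaOnlySpec <- function(seed, f0 = 10, snrDB = 20) {
  subjectSpec("x",
              c(delta = 0, theta = 0, pre_alpha = 0, alpha = 1, beta = 0),
              c(delta = 3.5, theta = 5, pre_alpha = 6.5, alpha = f0,
                beta = 13),
              snrDB = snrDB, seed = seed)
}

channelPipeline <- function(rec) {
  channelFeatures(epochPeriodogram(segmentEpochs(bandpassFilter(rec))))
}

test_that("the generator is deterministic given a seed", {
  sp <- alphaOnlySpec(99)
  r1 <- synthRecording(sp, duration = 10, fs = 128, channels = c("O1", "F3"))
  r2 <- synthRecording(sp, duration = 10, fs = 128, channels = c("O1", "F3"))
  expect_identical(recordingSamples(r1), recordingSamples(r2))
  r3 <- synthRecording(alphaOnlySpec(100), duration = 10, fs = 128,
                       channels = c("O1", "F3"))
  expect_false(identical(recordingSamples(r1), recordingSamples(r3)))
})

test_that("a pure-alpha subject yields near-total alpha prevalence", {
  cf <- channelPipeline(synthRecording(alphaOnlySpec(5), duration = 180,
                                       fs = 128, channels = "O1"))
  expect_gte(cf$summary$dfp_alpha, 95)
  expect_lt(abs(cf$summary$df - 10), 0.5)
})

test_that("a negligible oscillator leaves no band dominant", {
  for (sd in 1:10) {
    sp <- alphaOnlySpec(300 + sd, snrDB = -40)
    cf <- channelPipeline(synthRecording(sp, duration = 60, fs = 128,
                                         channels = "Pz"))
    dfp <- cf$summary[, grep("^dfp_", names(cf$summary))]
    expect_lt(max(dfp), 90)
  }
})

test_that("extracted prevalence converges to the spec'd occupancy", {
  occ <- c(delta = 0, theta = 0.2, pre_alpha = 0.3, alpha = 0.5, beta = 0)
  dfp <- matrix(0, 10, 5)
  for (sd in 1:10) {
    sp <- subjectSpec("x", occ,
                      c(delta = 3.5, theta = 5, pre_alpha = 6.5, alpha = 10,
                        beta = 13), snrDB = 20, seed = 400 + sd)
    cf <- channelPipeline(synthRecording(sp, duration = 180, fs = 128,
                                         channels = "Pz"))
    dfp[sd, ] <- as.numeric(
      cf$summary[, paste0("dfp_", names(occ))])
  }
  expect_lt(max(abs(colMeans(dfp) / 100 - occ)), 0.05)
})

test_that("identical group presets produce a null cohort", {
  diffs <- numeric(8)
  np <- nullPreset()
  for (sd in seq_along(diffs)) {
    fs <- simulateFeatureSet(nCase = 5, nControl = 5, preset = np,
                             seed = 500 + sd, duration = 60, fs = 128,
                             channels = c("F3", "T3", "Pz", "O1"))
    med <- tapply(SummarizedExperiment::assay(fs)["global_dfp_alpha", ],
                  subjectData(fs)$group, median)
    diffs[sd] <- med[["CF"]] - med[["nonCF"]]
  }
  mcse <- sd(diffs) / sqrt(length(diffs))
  expect_lte(abs(mean(diffs)), 3 * mcse + 1e-9)
})

test_that("a minimal 2+2 cohort runs through extraction and comparison", {
  co <- synthCohort(nCase = 2, nControl = 2, seed = 8, duration = 20,
                    fs = 128, channels = c("F3", "T3", "Pz", "O1"))
  expect_named(co, c("recordings", "meta", "specs"))
  expect_equal(nrow(co$meta), 4)
  fs <- extractCohortFeatures(co)
  expect_length(candidateFeatures(fs), 28)
  cmp <- compareGroups(fs, reference = "nonCF")
  expect_equal(nrow(cmp), 28)
  pruned <- pruneCorrelated(fs)          # heavy pruning at n = 4 is expected
  expect_true(length(pruned) >= 1 && all(pruned %in% candidateFeatures(fs)))
})

test_that("subject specifications are validated", {
  freqs <- c(delta = 3.5, theta = 5, pre_alpha = 6.5, alpha = 10, beta = 13)
  occ <- c(delta = .2, theta = .2, pre_alpha = .2, alpha = .2, beta = .2)
  expect_error(subjectSpec("x", occ * 2, freqs))
  badFreqs <- freqs; badFreqs["alpha"] <- 6.0     # outside its band
  expect_error(subjectSpec("x", occ, badFreqs), "inside its band")
  expect_error(subjectSpec("x", occ, freqs, moca = 35))
  sp <- subjectSpec("x", occ, freqs)
  expect_error(synthRecording(sp, duration = 3, fs = 128, channels = "Cz"),
               "whole number")
})

test_that("asynchronous switching still recovers the dominant rhythm", {
  cf <- channelPipeline(synthRecording(alphaOnlySpec(7), duration = 60,
                                       fs = 128, channels = "O1",
                                       asyncSwitch = TRUE))
  expect_gte(cf$summary$dfp_alpha, 80)
})

test_that("cohort metadata mirrors the drawn specifications", {
  co <- synthCohort(nCase = 3, nControl = 2, seed = 12, duration = 8,
                    fs = 128, channels = c("Pz", "O1"))
  expect_equal(as.integer(table(co$meta$group)[c("CF", "nonCF")]), c(3L, 2L))
  expect_true(all(co$meta$moca >= 0 & co$meta$moca <= 30))
  expect_true(all(vapply(co$recordings, recordingDuration, 0) == 8))
})
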