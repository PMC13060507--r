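test_that("periodogram concentrates an on-grid sinusoid in its bin", {
  rec <- sineRecording(10, fs = 128, duration = 4, amp = 1, channels = "O1")
  spec <- epochPeriodogram(segmentEpochs(rec))
  pow <- spectralPower(spec)
  freqs <- frequencies(spec)
  expect_equal(diff(freqs[1:2]), 0.5)                 # 2-s epochs, 0.5 Hz bins
  bin10 <- which(freqs == 10)
  for (e in 1:2) {
    expect_equal(pow[e, 1, bin10], 0.5, tolerance = 1e-10)  # A^2/2
    expect_lt(max(pow[e, 1, -bin10]), 1e-10)
  }
})

test_that("zero signal gives an all-zero spectrum", {
  rec <- new("EEGRecording", samples = matrix(0, 1, 128 * 4), fs = 128,
             channelLabels = "Cz")
  spec <- epochPeriodogram(segmentEpochs(rec))
  expect_equal(max(abs(spectralPower(spec))), 0)
})

test_that("Parseval: spectral power sums to the mean-square amplitude", {
  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(512, sd = runif(1, 0.5, 30))
    rec <- new("EEGRecording", samples = matrix(x, 1), fs = 256,
               channelLabels = "Cz")
    spec <- epochPeriodogram(segmentEpochs(rec))
    expect_equal(sum(spectralPower(spec)[1, 1, ]), mean(x^2),
                 tolerance = 1e-6)
  }
})

test_that("band classification matches the printed intervals on-grid", {
  expect_equal(classifyBand(c(3.0, 4.0)), c("delta", "delta"))
  expect_equal(classifyBand(c(4.5, 5.0, 5.5)), rep("theta", 3))
  expect_equal(classifyBand(c(6.0, 7.0, 7.5)), rep("pre_alpha", 3))
  expect_equal(classifyBand(c(8.0, 10.0, 12.0)), rep("alpha", 3))
  expect_equal(classifyBand(c(12.5, 14.0)), c("beta", "beta"))
  # half-open extension covers the printed gaps
  expect_equal(classifyBand(5.75), "pre_alpha")
  expect_equal(classifyBand(4.25), "theta")
  expect_equal(classifyBand(7.75), "alpha")
  # total over the whole grid: every bin in [3, 14] gets exactly one band
  grid <- seq(3, 14, by = 0.5)
  expect_false(anyNA(classifyBand(grid)))
})

test_that("dominant frequency is the argmax with ties toward low bins", {
  spec <- spectraFromPeaks(c(8, 10.5))
  expect_equal(as.vector(dominantFrequency(spec)), c(8, 10.5))

  # exact tie at 6 and 8 Hz resolves to 6
  freqs <- seq(0, 64, by = 0.5)
  pow <- array(0, dim = c(1, 1, length(freqs)))
  pow[1, 1, which(freqs %in% c(6, 8))] <- 1
  tied <- new("EpochSpectra", power = pow, freqs = freqs,
              channelLabels = "Cz")
  expect_equal(as.vector(dominantFrequency(tied)), 6)

  expect_error(dominantFrequency(spec, lo = 100, hi = 120), "no frequency bins")
})

test_that("DF of a 10 Hz sinusoid in white noise is stable at 20 dB SNR", {
  fs <- 128
  tt <- (0:(fs * 2 - 1)) / fs
  nEp <- 100
  set.seed(77)
  dat <- array(0, dim = c(nEp, 1, fs * 2))
  # SNR 20 dB: sinusoid power A^2/2 = 100x noise power in epoch
  for (e in seq_len(nEp))
    dat[e, 1, ] <- sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi)) +
      rnorm(fs * 2, sd = sqrt(0.5 / 100))
  ep <- new("EpochArray", data = dat, fs = fs, epochLength = 2,
            keptMask = rep(TRUE, nEp), channelLabels = "O1")
  df <- dominantFrequency(epochPeriodogram(ep))
  expect_gte(sum(df == 10), 99)
})

test_that("channel feature summaries follow their definitions", {
  # constant DF series: zero variability, all prevalence in one band
  spec <- spectraFromPeaks(rep(6, 90))
  cf <- channelFeatures(spec)
  expect_equal(cf$summary$df, 6)
  expect_equal(cf$summary$dfv, 0)
  expect_equal(cf$summary$dfp_pre_alpha, 100)
  expect_equal(cf$summary$dfp_alpha + cf$summary$dfp_theta +
                 cf$summary$dfp_delta + cf$summary$dfp_beta, 0)

  # sample standard deviation with n-1 denominator
  cf2 <- channelFeatures(spectraFromPeaks(c(5, 6, 7)))
  expect_equal(cf2$summary$dfv, 1)

  # 45/45 split across alpha and pre-alpha
  cf3 <- channelFeatures(spectraFromPeaks(c(rep(10, 45), rep(6.5, 45))))
  expect_equal(cf3$summary$dfp_alpha, 50)
  expect_equal(cf3$summary$dfp_pre_alpha, 50)

  expect_error(channelFeatures(spectraFromPeaks(8)), "at least 2 epochs")
})

test_that("prevalences sum to 100 and the IAF stays inside 8-12 Hz", {
  set.seed(31)
  sp <- subjectSpec("x", c(delta = .2, theta = .2, pre_alpha = .2,
                           alpha = .2, beta = .2),
                    c(delta = 3.5, theta = 5, pre_alpha = 6.5, alpha = 10,
                      beta = 13), snrDB = 8, seed = 13)
  rec <- synthRecording(sp, duration = 30, fs = 128, channels = c("Cz", "Pz"))
  cf <- channelFeatures(epochPeriodogram(segmentEpochs(bandpassFilter(rec))))
  dfpSum <- rowSums(cf$summary[, grep("^dfp_", names(cf$summary))])
  expect_equal(dfpSum, rep(100, 2), tolerance = 1e-9)
  expect_true(all(cf$summary$iaf >= 8 & cf$summary$iaf <= 12))
  # grid closure: every DF is an on-grid multiple of 0.5 within 3-14
  expect_true(all(cf$df %in% seq(3, 14, by = 0.5)))
})

test_that("regional aggregation averages member channels unweighted", {
  summary <- data.frame(
    channel = c("Pz", "P3", "P4", "O1", "O2"),
    df = c(8, 8, 8, 8, 8),
    dfp_alpha = c(100, 50, 50, 0, 0)
  )
  agg <- aggregateRegions(summary, regions = list(posterior = c(
    "Pz", "P3", "P4", "O1", "O2")))
  expect_equal(agg$dfp_alpha, 40)
  expect_equal(agg$df, 8)
  expect_equal(agg$n_channels, 5)

  # identical channels: every derivation equals the common value
  summary2 <- data.frame(channel = channels1020(), df = 6, dfp_alpha = 12.5)
  agg2 <- aggregateRegions(summary2)
  expect_true(all(agg2$df == 6))
  expect_true(all(agg2$dfp_alpha == 12.5))

  # a missing member shrinks the mean's support and is flagged
  anterior <- regionMap()$anterior
  summary3 <- data.frame(channel = setdiff(anterior, "F7"), df = 6)
  agg3 <- aggregateRegions(summary3, regions = list(anterior = anterior))
  expect_equal(agg3$n_channels, 6)
  expect_equal(agg3$n_defined, 7)

  expect_error(
    aggregateRegions(summary3, regions = list(posterior = c("O1", "O2"))),
    "no available member channels")
})
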