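# Independent oracles and small fixture builders used across tests.

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mwEnumerationOracle <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  rk <- rank(pooled)
  uObs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  combs <- combn(length(pooled), na)
  uAll <- apply(combs, 2, function(idx) sum(rk[idx]) - na * (na + 1) / 2)
  mu <- na * length(b) / 2
  mean(abs(uAll - mu) >= abs(uObs - mu) - 1e-12)
}

# AUC as brute-force pairwise concordance, ties counted one half.
aucBruteOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Hand implementation of the Benjamini-Hochberg step-up adjustment.
bhStepUpOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Feature set built directly from a subjects x features matrix.
fsFromMatrix <- function(X, group, age = NULL, sex = NULL, moca = NULL) {
  n <- nrow(X)
  if (is.null(rownames(X))) rownames(X) <- sprintf("S%03d", seq_len(n))
  if (is.null(age)) age <- rep(73, n)
  if (is.null(sex)) sex <- rep(c("M", "F"), length.out = n)
  if (is.null(moca)) moca <- rep(24, n)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(X)),
    rowData = S4Vectors::DataFrame(
      candidate = !grepl("_dfp_beta$", colnames(X))),
    colData = S4Vectors::DataFrame(group = group, age = age, sex = sex,
                                   moca = moca, row.names = rownames(X))
  )
  new("EEGFeatureSet", se)
}

# Matrix with the 28 candidate feature columns (plus DFP beta), filled
# with independent noise; individual columns can then be shifted.
randomFeatureMatrix <- function(n, seed = 1) {
  set.seed(seed)
  feats <- c("df", "dfv", "iaf", "dfp_alpha", "dfp_pre_alpha",
             "dfp_theta", "dfp_delta", "dfp_beta")
  cols <- as.vector(outer(c("global", "anterior", "temporal", "posterior"),
                          feats, paste, sep = "_"))
  X <- matrix(rnorm(n * length(cols)), n, length(cols),
              dimnames = list(sprintf("S%03d", seq_len(n)), cols))
  # keep global_df on a plausible scale so dfRange is meaningful
  X[, "global_df"] <- 7 + X[, "global_df"]
  X
}

# A recording holding pure sinusoids (one frequency per channel).
sineRecording <- function(freqs, fs = 128, duration = 10, amp = 10,
                          channels = NULL) {
  n <- duration * fs
  tt <- (0:(n - 1)) / fs
  if (is.null(channels)) channels <- channels1020()[seq_along(freqs)]
  samples <- t(vapply(freqs, function(f) amp * sin(2 * pi * f * tt),
                      numeric(n)))
  new("EEGRecording", samples = samples, fs = fs, channelLabels = channels)
}

# EpochSpectra with power placed at given frequencies per epoch.
spectraFromPeaks <- function(peakFreqs, fs = 128, epochLength = 2,
                            channel = "Cz", floor = 0) {
  freqs <- seq(0, fs / 2, by = 1 / epochLength)
  pow <- array(floor, dim = c(length(peakFreqs), 1, length(freqs)))
  for (e in seq_along(peakFreqs))
    pow[e, 1, which.min(abs(freqs - peakFreqs[e]))] <- 1
  new("EpochSpectra", power = pow, freqs = freqs, channelLabels = channel)
}
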