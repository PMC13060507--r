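# Filtering, epoching and artifact screening.

#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) Butterworth band-pass applied per
#' channel.  The default corners match the 3--14 Hz analysis window used
#' before spectral feature extraction; zero-phase filtering avoids phase
#' distortion at epoch boundaries.
#'
#' @param rec an [EEGRecording-class].
#' @param lo,hi corner frequencies in Hz; `0 < lo < hi < fs/2`.
#' @param order Butterworth prototype order (default 4).
#' @return a filtered [EEGRecording-class] of the same shape.
#' @export
bandpassFilter <- function(rec, lo = 3, hi = 14, order = 4) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@fs
  if (!(lo > 0 && lo < hi && hi < fs / 2))
    stop("corner frequencies must satisfy 0 < lo < hi < fs/2", call. = FALSE)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  n <- ncol(rec@samples)
  # demean + odd-reflection padding tames the forward-backward edge
  # transients (the mean is outside the passband anyway)
  padN <- min(n - 1L, as.integer(ceiling(3 * fs / lo)))
  out <- rec@samples
  for (i in seq_len(nrow(out))) {
    x <- rec@samples[i, ] - mean(rec@samples[i, ])
    padded <- c(2 * x[1] - rev(x[2:(padN + 1)]), x,
                2 * x[n] - rev(x[(n - padN):(n - 1)]))
    y <- signal::filtfilt(bf, padded)
    out[i, ] <- y[(padN + 1):(padN + n)]
  }
  initialize(rec, samples = out)
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts the recording into contiguous, non-overlapping epochs in temporal
#' order; trailing samples that do not fill a whole epoch are discarded.
#'
#' @param rec an [EEGRecording-class].
#' @param epochLength epoch length in seconds (default 2).
#' @param maxEpochs optionally keep only the first `maxEpochs` epochs
#'   (e.g. 90 to mirror a 3-minute protocol); a message notes when extra
#'   epochs are dropped.
#' @return an [EpochArray-class] with all epochs initially kept.
#' @export
segmentEpochs <- function(rec, epochLength = 2, maxEpochs = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  spe <- rec@fs * epochLength
  if (abs(spe - round(spe)) > 1e-9)
    stop("epoch length must contain a whole number of samples", call. = FALSE)
  spe <- as.integer(round(spe))
  nSamp <- ncol(rec@samples)
  nEp <- nSamp %/% spe
  if (nEp < 1)
    stop("recording shorter than one epoch (",
         sprintf("%.2f", nSamp / rec@fs), " s < ", epochLength, " s)",
         call. = FALSE)
  if (!is.null(maxEpochs) && nEp > maxEpochs) {
    message("keeping the first ", maxEpochs, " of ", nEp, " epochs")
    nEp <- maxEpochs
  }
  nCh <- nrow(rec@samples)
  dat <- array(0, dim = c(nEp, nCh, spe))
  for (e in seq_len(nEp))
    dat[e, , ] <- rec@samples[, (e - 1L) * spe + seq_len(spe), drop = FALSE]
  new("EpochArray", data = dat, fs = rec@fs, epochLength = epochLength,
      keptMask = rep(TRUE, nEp), channelLabels = rec@channelLabels)
}

#' Screen epochs for gross amplitude artifacts
#'
#' Automated stand-in for visual artifact review: an epoch is rejected
#' when any channel exceeds the absolute amplitude limit.  Data are left
#' untouched; only the keep mask changes.
#'
#' @param ep an [EpochArray-class].
#' @param ampLimit absolute amplitude limit in microvolts (default 100).
#' @return the [EpochArray-class] with an updated keep mask.
#' @export
screenEpochs <- function(ep, ampLimit = 100) {
  stopifnot(is(ep, "EpochArray"))
  if (!(is.numeric(ampLimit) && length(ampLimit) == 1L && ampLimit > 0))
    stop("ampLimit must be a single positive number", call. = FALSE)
  peak <- apply(abs(ep@data), 1, max)
  kept <- ep@keptMask & (peak <= ampLimit)
  if (!any(kept)) {
    perCh <- apply(abs(ep@data), 2, max)
    stop("all epochs rejected at |amplitude| <= ", ampLimit,
         " uV; per-channel peak uV: ",
         paste(sprintf("%s=%.1f", ep@channelLabels, perCh), collapse = ", "),
         call. = FALSE)
  }
  initialize(ep, keptMask = kept)
}
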