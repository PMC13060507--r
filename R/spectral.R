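# Per-epoch spectra and the DF / DFV / DFP / IAF feature family.

#' Per-epoch periodogram
#'
#' Rectangular-window (untapered, unpadded) one-sided periodogram of each
#' kept epoch and channel, on the grid `0, 1/T, ..., fs/2` Hz where `T`
#' is the epoch length — 0.5 Hz bins for 2-second epochs.  Power is
#' scaled so that, per epoch and channel, the sum over the grid equals
#' the mean-square amplitude of the epoch (Parseval).  Spectra are
#' computed per epoch independently; no averaging across epochs.
#'
#' @param ep an [EpochArray-class] with at least one kept epoch.
#' @return an [EpochSpectra-class] over the kept epochs.
#' @export
epochPeriodogram <- function(ep) {
  stopifnot(is(ep, "EpochArray"))
  keep <- which(ep@keptMask)
  if (!length(keep)) stop("no kept epochs to analyze", call. = FALSE)
  d <- dim(ep@data)
  n <- d[3]
  nb <- n %/% 2 + 1L
  freqs <- (seq_len(nb) - 1L) * ep@fs / n
  pow <- array(0, dim = c(length(keep), d[2], nb))
  oneSided <- c(1, rep(2, nb - 2L), if (n %% 2 == 0) 1 else 2)
  for (ei in seq_along(keep)) {
    for (ci in seq_len(d[2])) {
      X <- fft(ep@data[keep[ei], ci, ])
      p <- (Mod(X[seq_len(nb)])^2) / n^2
      pow[ei, ci, ] <- p * oneSided
    }
  }
  new("EpochSpectra", power = pow, freqs = freqs,
      channelLabels = ep@channelLabels)
}

#' Per-epoch dominant frequency
#'
#' The dominant frequency (DF) of an epoch is the single frequency bin
#' with maximum spectral power within the analysis window.  Exact power
#' ties are broken toward the lowest frequency, a deterministic choice
#' that is conservative for a slowing biomarker.
#'
#' @param spec an [EpochSpectra-class].
#' @param lo,hi analysis window in Hz (defaults 3 and 14, matching the
#'   band-pass).
#' @return numeric matrix of DF values (Hz), epochs x channels.
#' @export
dominantFrequency <- function(spec, lo = 3, hi = 14) {
  stopifnot(is(spec, "EpochSpectra"))
  bins <- which(spec@freqs >= lo & spec@freqs <= hi)
  if (!length(bins))
    stop("analysis window [", lo, ", ", hi, "] Hz contains no frequency bins",
         call. = FALSE)
  d <- dim(spec@power)
  df <- matrix(0, d[1], d[2], dimnames = list(NULL, spec@channelLabels))
  for (ci in seq_len(d[2])) {
    sub <- spec@power[, ci, bins, drop = FALSE]
    dim(sub) <- c(d[1], length(bins))
    df[, ci] <- spec@freqs[bins[max.col(sub, ties.method = "first")]]
  }
  df
}

#' Per-channel spectral feature set
#'
#' From the per-epoch DF series of each channel computes: mean DF; DF
#' variability (DFV, sample standard deviation of the DF series); DF
#' prevalence (DFP, the percentage of epochs whose DF falls in each band
#' — summing to 100 across bands); and the individual alpha peak
#' frequency (IAF, per-epoch power peak within 8--12 Hz, ties toward the
#' lowest bin, averaged over epochs).
#'
#' @param spec an [EpochSpectra-class] with at least two epochs (DFV
#'   needs a spread).
#' @param scheme a [BandScheme-class].
#' @param lo,hi DF analysis window in Hz.
#' @param alphaLo,alphaHi IAF search window in Hz (8 and 12).
#' @return a list with `df` (epochs x channels matrix), `iaf` (epochs x
#'   channels), and `summary`: a data.frame with one row per channel and
#'   columns `channel`, `df`, `dfv`, `iaf`, and `dfp_<band>`.
#' @export
channelFeatures <- function(spec, scheme = defaultBandScheme(),
                            lo = 3, hi = 14, alphaLo = 8, alphaHi = 12) {
  stopifnot(is(spec, "EpochSpectra"))
  if (dim(spec@power)[1] < 2L)
    stop("at least 2 epochs are required (DFV is a standard deviation)",
         call. = FALSE)
  df <- dominantFrequency(spec, lo, hi)
  iaf <- dominantFrequency(spec, alphaLo, alphaHi)
  bands <- scheme@bandNames
  dfBand <- matrix(classifyBand(df, scheme), nrow(df), ncol(df))
  dfp <- sapply(bands, function(b) 100 * colMeans(dfBand == b))
  if (is.null(dim(dfp))) dfp <- matrix(dfp, nrow = 1,
                                       dimnames = list(NULL, bands))
  out <- data.frame(
    channel = spec@channelLabels,
    df = colMeans(df),
    dfv = apply(df, 2, sd),
    iaf = colMeans(iaf),
    stringsAsFactors = FALSE
  )
  for (b in bands) out[[paste0("dfp_", b)]] <- dfp[, b]
  rownames(out) <- NULL
  list(df = df, iaf = iaf, summary = out)
}

#' Regional derivation map
#'
#' Channel membership of the anatomically defined derivations: anterior
#' (Fp1, Fp2, Fz, F3, F4, F7, F8), temporal (T3, T4, T5, T6), posterior
#' (Pz, P3, P4, O1, O2), and global (all analysis channels, including
#' the central row Cz/C3/C4).
#'
#' @return named list of character vectors.
#' @export
regionMap <- function() {
  list(
    global = channels1020(),
    anterior = c("Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8"),
    temporal = c("T3", "T4", "T5", "T6"),
    posterior = c("Pz", "P3", "P4", "O1", "O2")
  )
}

#' Aggregate channel features into regional derivations
#'
#' Each scalar feature of a derivation is the unweighted mean over its
#' available member channels; a completeness column records how many of
#' the defined members were present.
#'
#' @param channelSummary the `summary` data.frame from
#'   [channelFeatures()].
#' @param regions named list of member channels per derivation; default
#'   [regionMap()].
#' @return data.frame with one row per derivation: `derivation`, the
#'   averaged feature columns, `n_channels`, `n_defined`.
#' @export
aggregateRegions <- function(channelSummary, regions = regionMap()) {
  stopifnot(is.data.frame(channelSummary), "channel" %in% names(channelSummary))
  featCols <- setdiff(names(channelSummary), "channel")
  rows <- lapply(names(regions), function(rn) {
    members <- intersect(regions[[rn]], channelSummary$channel)
    if (!length(members))
      stop("derivation '", rn, "' has no available member channels",
           call. = FALSE)
    sub <- channelSummary[channelSummary$channel %in% members, featCols,
                          drop = FALSE]
    out <- as.data.frame(as.list(colMeans(sub)))
    out$derivation <- rn
    out$n_channels <- length(members)
    out$n_defined <- length(regions[[rn]])
    out
  })
  res <- do.call(rbind, rows)
  res[, c("derivation", featCols, "n_channels", "n_defined")]
}
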