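#' @describeIn EEGRecording-class sampling rate in Hz.
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)

#' @describeIn EEGRecording-class canonical channel names.
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)

#' @describeIn EEGRecording-class channels x time matrix (microvolts).
#' @export
setMethod("recordingSamples", "EEGRecording", function(x) x@samples)

#' @describeIn EEGRecording-class duration in seconds.
#' @export
setMethod("recordingDuration", "EEGRecording",
          function(x) ncol(x@samples) / x@fs)

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording:", nrow(object@samples), "channels,",
      ncol(object@samples), "samples @", object@fs, "Hz (",
      sprintf("%.1f", recordingDuration(object)), "s )\n")
  cat("  channels:", paste(object@channelLabels, collapse = " "), "\n")
  if (length(object@missingChannels))
    cat("  missing analysis channels:",
        paste(object@missingChannels, collapse = " "), "\n")
})

#' @describeIn EpochArray-class epochs x channels x samples array.
#' @export
setMethod("epochData", "EpochArray", function(x) x@data)

#' @describeIn EpochArray-class logical keep mask after screening.
#' @export
setMethod("keptEpochs", "EpochArray", function(x) x@keptMask)

#' @describeIn EpochArray-class total number of epochs.
#' @export
setMethod("nEpochs", "EpochArray", function(x) dim(x@data)[1])

#' @describeIn EpochArray-class sampling rate in Hz.
#' @export
setMethod("samplingRate", "EpochArray", function(x) x@fs)

#' @describeIn EpochArray-class canonical channel names.
#' @export
setMethod("channelLabels", "EpochArray", function(x) x@channelLabels)

setMethod("show", "EpochArray", function(object) {
  d <- dim(object@data)
  cat("EpochArray:", d[1], "epochs x", d[2], "channels x", d[3],
      "samples (", object@epochLength, "s @", object@fs, "Hz );",
      sum(object@keptMask), "kept\n")
})

#' @describeIn EpochSpectra-class epochs x channels x bins power array.
#' @export
setMethod("spectralPower", "EpochSpectra", function(x) x@power)

#' @describeIn EpochSpectra-class frequency grid in Hz.
#' @export
setMethod("frequencies", "EpochSpectra", function(x) x@freqs)

#' @describeIn EpochSpectra-class canonical channel names.
#' @export
setMethod("channelLabels", "EpochSpectra", function(x) x@channelLabels)

setMethod("show", "EpochSpectra", function(object) {
  d <- dim(object@power)
  cat("EpochSpectra:", d[1], "epochs x", d[2], "channels,",
      d[3], "bins (", object@freqs[1], "-", object@freqs[d[3]],
      "Hz, spacing", diff(object@freqs[1:2]), "Hz )\n")
})

#' @describeIn BandScheme-class band names, slowest first.
#' @export
setMethod("bandNames", "BandScheme", function(x) x@bandNames)

setMethod("show", "BandScheme", function(object) {
  lo <- c(0, object@edges)
  hi <- c(object@edges, Inf)
  cat("BandScheme:\n")
  for (i in seq_along(object@bandNames))
    cat(sprintf("  %-9s [%4.2f, %s) Hz\n", object@bandNames[i], lo[i],
                ifelse(is.finite(hi[i]), sprintf("%5.2f", hi[i]), "Inf")))
})

#' @describeIn EEGFeatureSet-class names of the candidate modeling
#'   features.
#' @export
setMethod("candidateFeatures", "EEGFeatureSet",
          function(x) rownames(x)[rowData(x)$candidate])

#' @describeIn EEGFeatureSet-class subjects x features numeric matrix
#'   (all features, candidates and internal ones).
#' @export
setMethod("featureMatrix", "EEGFeatureSet", function(x) t(assay(x)))

#' @describeIn EEGFeatureSet-class subject covariates as a data.frame.
#' @export
setMethod("subjectData", "EEGFeatureSet",
          function(x) as.data.frame(colData(x)))
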