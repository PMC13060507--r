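#' @rdname EEGRecording-class
#' @param object,x an object.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EEGRecording-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname EEGRecording-class
#' @export
setGeneric("recordingSamples", function(x) standardGeneric("recordingSamples"))

#' @rdname EEGRecording-class
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))

#' @rdname EpochArray-class
#' @param x an object.
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname EpochArray-class
#' @export
setGeneric("keptEpochs", function(x) standardGeneric("keptEpochs"))

#' @rdname EpochArray-class
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname EpochSpectra-class
#' @param x an object.
#' @export
setGeneric("spectralPower", function(x) standardGeneric("spectralPower"))

#' @rdname EpochSpectra-class
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname BandScheme-class
#' @param x an object.
#' @export
setGeneric("bandNames", function(x) standardGeneric("bandNames"))

#' @rdname EEGFeatureSet-class
#' @param x an object.
#' @export
setGeneric("candidateFeatures", function(x) standardGeneric("candidateFeatures"))

#' @rdname EEGFeatureSet-class
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname EEGFeatureSet-class
#' @export
setGeneric("subjectData", function(x) standardGeneric("subjectData"))
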