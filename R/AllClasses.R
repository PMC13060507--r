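#' Canonical 10-20 scalp channel names
#'
#' The 19-electrode International 10-20 montage using the legacy temporal
#' labels (T3/T4/T5/T6) under which the regional derivations are defined.
#'
#' @return Character vector of 19 canonical labels.
#' @export
#' @examples
#' channels1020()
channels1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "O2")
}

#' Multichannel EEG recording
#'
#' An in-memory resting-state EEG recording: a channels x time matrix of
#' scalp potentials in microvolts, the sampling rate, and canonical 10-20
#' channel labels.
#'
#' @slot samples numeric matrix, channels x time, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector of canonical channel names, one
#'   per row of `samples`.
#' @slot missingChannels canonical names of analysis channels that were
#'   requested but absent from the source file.
#'
#' @export
setClass("EEGRecording",
  representation(
    samples = "matrix",
    fs = "numeric",
    channelLabels = "character",
    missingChannels = "character"
  ),
  prototype(missingChannels = character(0))
)

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@samples) != length(object@channelLabels))
    msg <- c(msg, "one channel label per sample row required")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (length(msg)) msg else TRUE
})

#' Epoched EEG data
#'
#' Contiguous fixed-length epochs cut from a filtered recording, plus a
#' per-epoch keep mask produced by artifact screening.
#'
#' @slot data numeric array, epochs x channels x samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot epochLength epoch length in seconds.
#' @slot keptMask logical vector, one entry per epoch.
#' @slot channelLabels canonical channel names.
#'
#' @export
setClass("EpochArray",
  representation(
    data = "array",
    fs = "numeric",
    epochLength = "numeric",
    keptMask = "logical",
    channelLabels = "character"
  )
)

setValidity("EpochArray", function(object) {
  msg <- character(0)
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-d array (epochs x channels x samples)")
  else {
    spe <- object@fs * object@epochLength
    if (abs(spe - round(spe)) > 1e-9 || d[3] != round(spe))
      msg <- c(msg, "samples per epoch must equal fs * epochLength exactly")
    if (d[1] != length(object@keptMask))
      msg <- c(msg, "keptMask must have one entry per epoch")
    if (d[2] != length(object@channelLabels))
      msg <- c(msg, "one channel label per channel slab required")
  }
  if (length(msg)) msg else TRUE
})

#' Per-epoch power spectra
#'
#' One-sided periodogram power for every kept epoch and channel on the
#' fixed frequency grid implied by the epoch length (0.5 Hz bins for
#' 2-second epochs).  Power is scaled so that its sum over the grid equals
#' the epoch's mean-square amplitude (Parseval).
#'
#' @slot power numeric array, epochs x channels x frequency bins
#'   (microvolts squared).
#' @slot freqs frequency grid in Hz.
#' @slot channelLabels canonical channel names.
#'
#' @export
setClass("EpochSpectra",
  representation(
    power = "array",
    freqs = "numeric",
    channelLabels = "character"
  )
)

setValidity("EpochSpectra", function(object) {
  msg <- character(0)
  d <- dim(object@power)
  if (length(d) != 3L)
    msg <- c(msg, "power must be a 3-d array (epochs x channels x bins)")
  else {
    if (d[3] != length(object@freqs))
      msg <- c(msg, "one frequency per power bin required")
    if (d[2] != length(object@channelLabels))
      msg <- c(msg, "one channel label per channel slab required")
    if (any(object@power < -1e-12))
      msg <- c(msg, "power must be non-negative")
  }
  if (is.unsorted(object@freqs, strictly = TRUE))
    msg <- c(msg, "freqs must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Frequency band scheme
#'
#' The five named bands used to classify dominant frequencies.  The
#' printed clinical definitions (delta <= 4.0, theta 4.5--5.5, pre-alpha
#' 6.0--7.5, alpha 8.0--12.0, beta > 12.0 Hz) leave gaps that no bin of
#' the 0.5 Hz analysis grid can fall into; `edges` stores the half-open
#' extension covering those gaps so classification is total while
#' agreeing with the printed intervals at every on-grid frequency.
#'
#' @slot bandNames band names, slowest first.
#' @slot edges numeric vector of interior cut points (length
#'   `length(bandNames) - 1`); band i is `[edges[i-1], edges[i])`.
#'
#' @export
setClass("BandScheme",
  representation(bandNames = "character", edges = "numeric")
)

setValidity("BandScheme", function(object) {
  msg <- character(0)
  if (length(object@edges) != length(object@bandNames) - 1L)
    msg <- c(msg, "need one interior edge fewer than bands")
  if (is.unsorted(object@edges, strictly = TRUE))
    msg <- c(msg, "edges must be strictly increasing")
  if (anyDuplicated(object@bandNames))
    msg <- c(msg, "band names must be unique")
  if (length(msg)) msg else TRUE
})

#' Per-subject EEG feature set
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay holds
#' the per-derivation spectral features (rows) for every subject
#' (columns); `colData` carries the modeling covariates (group, age, sex,
#' MoCA).  Row metadata marks the 28 candidate features used for
#' modeling (7 features x 4 derivations; DFP beta is retained internally
#' but excluded from the candidate set).
#'
#' @export
setClass("EEGFeatureSet", contains = "SummarizedExperiment")

setValidity("EEGFeatureSet", function(object) {
  msg <- character(0)
  cd <- colData(object)
  need <- c("group", "age", "sex", "moca")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData must contain: ", paste(miss, collapse = ", ")))
  if (!"candidate" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain a logical 'candidate' column")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate subject ids")
  if ("moca" %in% colnames(cd)) {
    m <- cd$moca
    if (any(!is.na(m) & (m < 0 | m > 30)))
      msg <- c(msg, "MoCA scores must lie in [0, 30]")
  }
  if (length(msg)) msg else TRUE
})
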