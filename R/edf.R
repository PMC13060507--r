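# EDF (European Data Format) reading and writing.
#
# EDF is a fixed-layout binary format: a 256-byte ASCII global header,
# 256 ASCII bytes per signal, then data records of int16 little-endian
# samples scaled by a per-signal physical/digital calibration.

.NON_EEG_PATTERNS <- c("ECG", "EKG", "EOG", "EMG", "PHOTIC", "ANNOTATION",
                       "STATUS", "EVENT", "MARKER", "RESP", "PULSE", "SPO2")

#' Canonicalize a 10-20 channel label
#'
#' Strips modality prefixes (`"EEG "`), reference suffixes (`"-REF"`,
#' `"-LE"`, `"-A1A2"`, ...), case-folds, and maps the modern 10-10
#' temporal aliases onto the legacy names under which the regional
#' derivations are defined (T7 to T3, T8 to T4, P7 to T5, P8 to T6).
#' Labels that do not resolve to a 10-20 electrode are returned as `NA`
#' and excluded from analysis by the reader.
#'
#' Canonicalization is idempotent: canonical names map to themselves.
#'
#' @param raw character vector of raw channel labels.
#' @return character vector of canonical names, `NA` where unmapped.
#' @export
#' @examples
#' canonicalizeLabel(c("EEG FP1-REF", "P8", "X1"))
canonicalizeLabel <- function(raw) {
  stopifnot(is.character(raw))
  x <- trimws(raw)
  x <- sub("^EEG[ _]+", "", x, ignore.case = TRUE)
  x <- sub("-[A-Za-z0-9]+$", "", x)   # reference suffix: -REF, -LE, -A1A2, ...
  x <- trimws(x)
  up <- toupper(x)
  alias <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
  hit <- up %in% names(alias)
  up[hit] <- alias[up[hit]]
  canon <- channels1020()
  m <- match(up, toupper(canon))
  ifelse(is.na(m), NA_character_, canon[m])
}

.isNonEEG <- function(labels) {
  up <- toupper(labels)
  vapply(up, function(l) any(vapply(.NON_EEG_PATTERNS, grepl, logical(1),
                                    x = l, fixed = TRUE)), logical(1))
}

.readAscii <- function(con, n) {
  raw <- readBin(con, "raw", n = n)
  if (length(raw) < n) stop("truncated EDF header", call. = FALSE)
  trimws(rawToChar(raw))
}

.asciiNum <- function(s, what) {
  v <- suppressWarnings(as.numeric(s))
  if (any(is.na(v))) stop("malformed EDF header field: ", what, call. = FALSE)
  v
}

#' Read an EDF recording
#'
#' Reads an EDF/EDF+ file, drops non-EEG signals (ECG, photic,
#' annotations, ...) and unmappable labels, canonicalizes the remaining
#' 10-20 labels, and rescales potentials to microvolts (EDF physical
#' dimensions `mV` and `V` are converted).
#'
#' @param path path to an EDF file.
#' @param requiredChannels canonical channel names expected for analysis;
#'   absent ones are reported in the returned object's
#'   `missingChannels` slot (extraction proceeds over available
#'   channels).  Default: the 19-channel 10-20 montage.
#' @return an [EEGRecording-class].
#' @export
readEDF <- function(path, requiredChannels = channels1020()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) < 256) stop("not a valid EDF file (too short): ",
                                  path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  .readAscii(con, 8)                       # version
  .readAscii(con, 80); .readAscii(con, 80) # patient / recording id
  .readAscii(con, 8);  .readAscii(con, 8)  # start date / time
  .asciiNum(.readAscii(con, 8), "header bytes")
  .readAscii(con, 44)                      # reserved
  nRec <- .asciiNum(.readAscii(con, 8), "record count")
  recDur <- .asciiNum(.readAscii(con, 8), "record duration")
  ns <- as.integer(.asciiNum(.readAscii(con, 4), "signal count"))
  if (ns < 1) stop("EDF file declares no signals", call. = FALSE)

  field <- function(w) vapply(seq_len(ns), function(i) .readAscii(con, w), "")
  labels   <- field(16)
  field(80)                                # transducer
  physDim  <- field(8)
  physMin  <- .asciiNum(field(8), "physical minimum")
  physMax  <- .asciiNum(field(8), "physical maximum")
  digMin   <- .asciiNum(field(8), "digital minimum")
  digMax   <- .asciiNum(field(8), "digital maximum")
  field(80)                                # prefiltering
  sampPerRec <- as.integer(.asciiNum(field(8), "samples per record"))
  field(32)                                # reserved

  if (nRec < 0) stop("EDF record count unknown (-1) is unsupported",
                     call. = FALSE)

  keep <- !.isNonEEG(labels)
  canon <- rep(NA_character_, ns)
  canon[keep] <- canonicalizeLabel(labels[keep])
  unmapped <- keep & is.na(canon)
  if (any(unmapped))
    warning("unmapped channel label(s) excluded from analysis: ",
            paste(labels[unmapped], collapse = ", "), call. = FALSE)
  keep <- keep & !is.na(canon)
  if (!any(keep)) stop("no EEG channels left after label filtering",
                       call. = FALSE)
  if (length(unique(sampPerRec[keep])) != 1L)
    stop("EEG channels with differing sampling rates are unsupported",
         call. = FALSE)

  totalPerRec <- sum(sampPerRec)
  dat <- readBin(con, "integer", n = nRec * totalPerRec, size = 2,
                 signed = TRUE, endian = "little")
  if (length(dat) < nRec * totalPerRec)
    stop("truncated EDF data section", call. = FALSE)

  fs <- sampPerRec[keep][1] / recDur
  idx <- which(keep)
  offs <- c(0L, cumsum(sampPerRec))        # within-record sample offsets
  nSamp <- nRec * sampPerRec[idx[1]]
  out <- matrix(0, nrow = length(idx), ncol = nSamp)
  recBase <- (seq_len(nRec) - 1L) * totalPerRec
  for (j in seq_along(idx)) {
    i <- idx[j]
    spr <- sampPerRec[i]
    pos <- as.vector(outer(seq_len(spr) + offs[i], recBase, "+"))
    gain <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
    x <- physMin[i] + (dat[pos] - digMin[i]) * gain
    unit <- toupper(gsub("µ|u", "U", physDim[i]))
    scale <- if (unit %in% c("UV", "")) 1
             else if (unit == "MV") 1e3
             else if (unit == "V") 1e6
             else { warning("unknown physical dimension '", physDim[i],
                            "' treated as uV", call. = FALSE); 1 }
    out[j, ] <- x * scale
  }

  labs <- canon[idx]
  if (anyDuplicated(labs)) {
    warning("duplicate canonical channel(s) dropped: ",
            paste(unique(labs[duplicated(labs)]), collapse = ", "),
            call. = FALSE)
    first <- !duplicated(labs)
    out <- out[first, , drop = FALSE]
    labs <- labs[first]
  }
  new("EEGRecording", samples = out, fs = fs, channelLabels = labs,
      missingChannels = setdiff(requiredChannels, labs))
}

#' Write a recording to EDF
#'
#' Minimal EDF writer used for fixtures and the simulation CLI.  Samples
#' are quantized to 16 bits over a symmetric physical range covering the
#' data; with 1-second data records the recording must contain a whole
#' number of seconds.
#'
#' @param rec an [EEGRecording-class].
#' @param path output file path.
#' @param physRange symmetric physical range in microvolts; default
#'   covers the data.
#' @param labelStyle `"canonical"` writes bare canonical labels,
#'   `"clinical"` writes `"EEG <name>-REF"` style labels.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path, physRange = NULL,
                     labelStyle = c("canonical", "clinical")) {
  stopifnot(is(rec, "EEGRecording"))
  labelStyle <- match.arg(labelStyle)
  fs <- rec@fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("writeEDF requires an integer sampling rate", call. = FALSE)
  nSamp <- ncol(rec@samples)
  nRec <- nSamp / fs
  if (abs(nRec - round(nRec)) > 1e-9)
    stop("recording must contain a whole number of seconds", call. = FALSE)
  nRec <- as.integer(round(nRec))
  nCh <- nrow(rec@samples)
  if (is.null(physRange))
    physRange <- max(1, ceiling(max(abs(rec@samples))))

  pad <- function(s, w) {
    s <- substr(s, 1, w)
    paste0(s, strrep(" ", w - nchar(s)))
  }
  labs <- rec@channelLabels
  if (labelStyle == "clinical") labs <- paste0("EEG ", labs, "-REF")

  hdr <- paste0(
    pad("0", 8), pad("X", 80), pad("Startdate X", 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(as.character(256L * (nCh + 1L)), 8), pad("", 44),
    pad(as.character(nRec), 8), pad("1", 8), pad(as.character(nCh), 4),
    paste(vapply(labs, pad, "", w = 16), collapse = ""),
    strrep(pad("", 80), nCh),
    strrep(pad("uV", 8), nCh),
    strrep(pad(as.character(-physRange), 8), nCh),
    strrep(pad(as.character(physRange), 8), nCh),
    strrep(pad("-32768", 8), nCh),
    strrep(pad("32767", 8), nCh),
    strrep(pad("", 80), nCh),
    strrep(pad(as.character(as.integer(fs)), 8), nCh),
    strrep(pad("", 32), nCh)
  )

  gain <- 65535 / (2 * physRange)
  dig <- round((rec@samples + physRange) * gain) - 32768
  dig[dig > 32767] <- 32767L
  dig[dig < -32768] <- -32768L
  # interleave: per record, each channel's fs samples in channel order
  recIdx <- rep(seq_len(nRec), each = nCh * fs)
  chIdx <- rep(rep(seq_len(nCh), each = fs), nRec)
  sampIdx <- rep(seq_len(fs), nCh * nRec) + (recIdx - 1L) * fs
  stream <- dig[cbind(chIdx, sampIdx)]

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(as.integer(stream), con, size = 2, endian = "little")
  invisible(path)
}
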