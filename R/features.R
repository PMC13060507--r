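# Subject-level feature extraction and the per-cohort feature table.

.FEATURE_ORDER <- c("df", "dfv", "iaf",
                    "dfp_alpha", "dfp_pre_alpha", "dfp_theta", "dfp_delta",
                    "dfp_beta")

#' Extract the per-derivation feature vector of one recording
#'
#' Runs the extraction pipeline on a single recording: band-pass filter
#' (3--14 Hz), segmentation into 2-second epochs, optional amplitude
#' screening, per-epoch periodogram, per-channel DF/DFV/DFP/IAF, and
#' regional aggregation.
#'
#' @param rec an [EEGRecording-class].
#' @param lo,hi band-pass corners and DF analysis window (Hz).
#' @param order band-pass Butterworth order.
#' @param epochLength epoch length in seconds.
#' @param maxEpochs cap on the number of epochs (default 90, the
#'   3-minute protocol); `NULL` for no cap.
#' @param screen apply amplitude screening? Off by default: the synthetic
#'   recordings the pipeline is exercised on are clean by construction.
#' @param ampLimit screening limit in microvolts.
#' @param scheme a [BandScheme-class].
#' @param regions derivation map, default [regionMap()].
#' @return a list: `regional` (the [aggregateRegions()] data.frame),
#'   `channels` (per-channel summary), `nEpochs` (kept epoch count).
#' @export
extractFeatures <- function(rec, lo = 3, hi = 14, order = 4,
                            epochLength = 2, maxEpochs = 90,
                            screen = FALSE, ampLimit = 100,
                            scheme = defaultBandScheme(),
                            regions = regionMap()) {
  filt <- bandpassFilter(rec, lo, hi, order)
  ep <- segmentEpochs(filt, epochLength, maxEpochs)
  if (screen) ep <- screenEpochs(ep, ampLimit)
  spec <- epochPeriodogram(ep)
  cf <- channelFeatures(spec, scheme, lo, hi)
  avail <- lapply(regions, intersect, y = rec@channelLabels)
  empty <- lengths(avail) == 0
  if (any(empty)) {
    message("derivation(s) with no available channels skipped: ",
            paste(names(regions)[empty], collapse = ", "))
    avail <- avail[!empty]
    regions <- regions[!empty]
  }
  # keep full member lists so completeness flags reflect defined montage
  list(regional = aggregateRegions(cf$summary, regions),
       channels = cf$summary,
       nEpochs = sum(keptEpochs(ep)))
}

.flattenRegional <- function(regional) {
  feats <- intersect(.FEATURE_ORDER, names(regional))
  out <- numeric(0)
  for (d in regional$derivation) {
    row <- regional[regional$derivation == d, feats]
    v <- as.numeric(row)
    names(v) <- paste0(d, "_", feats)
    out <- c(out, v)
  }
  out
}

#' Assemble the cohort feature table
#'
#' Combines per-subject regional features with subject metadata into an
#' [EEGFeatureSet-class].  Feature rows are named `<derivation>_<feature>`;
#' the 28 candidate modeling features are the 7 reported features (DF,
#' DFV, IAF, and DFP in the alpha, pre-alpha, theta and delta bands)
#' over the 4 derivations; DFP beta is retained internally but is not a
#' candidate.
#'
#' @param featureList named list (one element per subject) of results
#'   from [extractFeatures()], or of regional data.frames.
#' @param meta data.frame with columns `subject`, `group`, `age`, `sex`,
#'   `moca` (rows matched to `featureList` by `subject`).
#' @return an [EEGFeatureSet-class] with subjects as columns.
#' @export
buildFeatureTable <- function(featureList, meta) {
  stopifnot(length(featureList) >= 1, is.data.frame(meta))
  need <- c("subject", "group", "age", "sex", "moca")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ids <- names(featureList)
  if (is.null(ids)) ids <- as.character(meta$subject[seq_along(featureList)])
  if (anyDuplicated(ids))
    stop("duplicate subject ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  vecs <- lapply(featureList, function(fl) {
    reg <- if (is.data.frame(fl)) fl else fl$regional
    .flattenRegional(reg)
  })
  featNames <- names(vecs[[1]])
  mat <- vapply(vecs, function(v) v[featNames], numeric(length(featNames)))
  dimnames(mat) <- list(featNames, ids)
  m <- match(ids, as.character(meta$subject))
  if (anyNA(m))
    stop("metadata rows missing for subject(s): ",
         paste(ids[is.na(m)], collapse = ", "), call. = FALSE)
  meta <- meta[m, , drop = FALSE]
  if (anyNA(meta[, c("group", "age", "sex", "moca")]))
    stop("metadata must be complete (group, age, sex, moca) for modeling",
         call. = FALSE)
  candidate <- !grepl("_dfp_beta$", featNames)
  se <- SummarizedExperiment(
    assays = list(features = mat),
    rowData = DataFrame(candidate = candidate),
    colData = DataFrame(group = as.character(meta$group),
                        age = meta$age,
                        sex = as.character(meta$sex),
                        moca = meta$moca,
                        row.names = ids)
  )
  fs <- new("EEGFeatureSet", se)
  metadata(fs)$df_range <- dfRange(fs)
  fs
}

#' Per-group range of subject-level mean dominant frequency
#'
#' The DF range of a group is the minimum and maximum over its subjects
#' of the subject-level mean DF (the global derivation's mean DF).
#'
#' @param fs an [EEGFeatureSet-class].
#' @return data.frame with columns `group`, `min_df`, `max_df`.
#' @export
dfRange <- function(fs) {
  stopifnot(is(fs, "EEGFeatureSet"))
  df <- assay(fs)["global_df", ]
  grp <- colData(fs)$group
  out <- do.call(rbind, lapply(unique(grp), function(g) {
    data.frame(group = g, min_df = min(df[grp == g]),
               max_df = max(df[grp == g]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write / read a feature table as CSV
#'
#' One row per subject: `subject`, the covariates, then one column per
#' feature named `<derivation>_<feature>`.
#'
#' @param fs an [EEGFeatureSet-class].
#' @param path CSV file path.
#' @return `writeFeatureCSV`: `path` invisibly; `readFeatureCSV`: an
#'   [EEGFeatureSet-class].
#' @export
writeFeatureCSV <- function(fs, path) {
  stopifnot(is(fs, "EEGFeatureSet"))
  df <- cbind(subject = colnames(fs), subjectData(fs),
              as.data.frame(featureMatrix(fs)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  covar <- c("subject", "group", "age", "sex", "moca")
  miss <- setdiff(covar, names(df))
  if (length(miss))
    stop("feature CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  featNames <- setdiff(names(df), covar)
  mat <- t(as.matrix(df[, featNames, drop = FALSE]))
  colnames(mat) <- df$subject
  if (anyDuplicated(df$subject))
    stop("duplicate subject ids in feature CSV", call. = FALSE)
  se <- SummarizedExperiment(
    assays = list(features = mat),
    rowData = DataFrame(candidate = !grepl("_dfp_beta$", featNames)),
    colData = DataFrame(group = df$group, age = df$age, sex = df$sex,
                        moca = df$moca, row.names = df$subject)
  )
  fs <- new("EEGFeatureSet", se)
  metadata(fs)$df_range <- dfRange(fs)
  fs
}
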