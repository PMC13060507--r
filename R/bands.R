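#' Default clinical band scheme
#'
#' Delta (<= 4.0 Hz), theta (4.5--5.5), pre-alpha (6.0--7.5), alpha
#' (8.0--12.0) and beta (> 12.0 Hz).  The stored half-open cut points
#' (4.25, 5.75, 7.75, 12.25 Hz) extend the printed intervals across the
#' gaps between them — frequencies no 0.5 Hz analysis bin can take — so
#' that classification is total while matching the printed definition at
#' every on-grid frequency.
#'
#' @return a [BandScheme-class].
#' @export
#' @examples
#' defaultBandScheme()
defaultBandScheme <- function() {
  new("BandScheme",
      bandNames = c("delta", "theta", "pre_alpha", "alpha", "beta"),
      edges = c(4.25, 5.75, 7.75, 12.25))
}

#' Classify a frequency into a band
#'
#' @param f numeric vector of frequencies in Hz (`f >= 0`).
#' @param scheme a [BandScheme-class]; default [defaultBandScheme()].
#' @return character vector of band names.
#' @export
#' @examples
#' classifyBand(c(4, 6, 8, 12, 12.5))
classifyBand <- function(f, scheme = defaultBandScheme()) {
  stopifnot(is(scheme, "BandScheme"), is.numeric(f), all(f >= 0))
  idx <- findInterval(f, scheme@edges, left.open = FALSE) + 1L
  scheme@bandNames[idx]
}
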