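# Group-comparison layer: median/IQR summaries, Mann-Whitney U with
# effect size r, Benjamini-Hochberg FDR, and the Table-1-shaped report.

#' Median and interquartile range
#'
#' @param x numeric vector, `n >= 1`.
#' @return named vector `median`, `q1`, `q3` (type-7 linear
#'   interpolation quantiles).
#' @export
#' @examples
#' medianIQR(1:5)
medianIQR <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1)
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

#' Mann-Whitney U test with effect size r
#'
#' Two-sided Mann-Whitney U test of `a` (cases) versus `b` (reference
#' group).  For tie-free samples with `n_a + n_b <= 12` the p-value is
#' exact (full null enumeration of the U distribution); otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.  The effect size is `r = Z / sqrt(n_a + n_b)`, signed so that
#' `r > 0` when the reference group `b` tends to have larger values —
#' so features that are higher in the reference group carry positive r.
#'
#' @param a,b numeric samples with at least 2 observations each.
#' @return list with `U` (of `a` vs `b`), `p`, `r`, `exact` (logical).
#' @export
#' @examples
#' mannWhitneyR(c(1, 2, 3), c(4, 5, 6))
mannWhitneyR <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2     # pairs a>b, ties as 1/2
  mu <- na * nb / 2
  tieTab <- table(pooled)
  tieTerm <- sum(tieTab^3 - tieTab) / (N * (N - 1))
  sig2 <- na * nb / 12 * ((N + 1) - tieTerm)
  if (sig2 <= 0) {                                   # all values identical
    return(list(U = U, p = 1, r = 0, exact = FALSE))
  }
  hasTies <- any(tieTab > 1)
  exact <- !hasTies && N <= 12
  if (exact) {
    # two-sided exact p from the null U distribution
    pLow <- pwilcox(U, na, nb)
    pHigh <- 1 - pwilcox(U - 1, na, nb)
    p <- min(1, 2 * min(pLow, pHigh))
  } else {
    cc <- sign(U - mu) * 0.5                         # continuity correction
    z <- (U - mu - cc) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
  }
  z <- (U - mu) / sqrt(sig2)
  list(U = U, p = p, r = -z / sqrt(N), exact = exact)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: order-preserving, capped at 1, `q >= p`
#' elementwise.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values in the input order.
#' @export
bhFDR <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Kruskal-Wallis test across groups
#'
#' Thin wrapper for layouts with three or more groups; the primary
#' two-group contrast uses [mannWhitneyR()].
#'
#' @param x numeric values.
#' @param g group labels.
#' @return list with `statistic`, `df`, `p`.
#' @export
kruskalGroups <- function(x, g) {
  kt <- kruskal.test(x, factor(g))
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Chi-square test for a categorical covariate by group
#'
#' Pearson chi-square without Yates correction, for demographics tables
#' (sex, diagnosis mix).
#'
#' @param x categorical values.
#' @param g group labels.
#' @return list with `statistic`, `df`, `p`, `table`.
#' @export
chisqGroups <- function(x, g) {
  tab <- table(x, g)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}

#' Compare EEG features between the two study groups
#'
#' One Mann-Whitney U test per candidate feature (7 features x 4
#' derivations = 28 tests), with Benjamini-Hochberg adjustment applied
#' jointly across all of them, and median (IQR) summaries per group.
#' The effect size r is positive when the reference group tends larger.
#'
#' @param fs an [EEGFeatureSet-class] with exactly two groups, each of
#'   size at least 2.
#' @param reference group label to treat as the reference (the
#'   non-fluctuating-like group); default: the second group level in
#'   sorted order.
#' @return data.frame with one row per derivation x feature: group
#'   medians/IQRs, `U`, `p`, `q`, `r`; the per-group DF range is
#'   attached as attribute `"df_range"`.
#' @export
compareGroups <- function(fs, reference = NULL) {
  stopifnot(is(fs, "EEGFeatureSet"))
  grp <- colData(fs)$group
  lev <- sort(unique(grp))
  if (length(lev) != 2)
    stop("exactly two groups are required (found ",
         length(lev), ": ", paste(lev, collapse = ", "), ")", call. = FALSE)
  if (is.null(reference)) reference <- lev[2]
  if (!reference %in% lev)
    stop("reference group '", reference, "' not present", call. = FALSE)
  caseLev <- setdiff(lev, reference)
  if (min(table(grp)) < 2)
    stop("each group needs at least 2 subjects", call. = FALSE)

  feats <- candidateFeatures(fs)
  mat <- assay(fs)
  rows <- lapply(feats, function(f) {
    x <- mat[f, ]
    a <- x[grp == caseLev]; b <- x[grp == reference]
    mw <- mannWhitneyR(a, b)
    sa <- medianIQR(a); sb <- medianIQR(b)
    parts <- strsplit(f, "_")[[1]]
    data.frame(
      derivation = parts[1],
      feature = paste(parts[-1], collapse = "_"),
      case_median = sa["median"], case_q1 = sa["q1"], case_q3 = sa["q3"],
      ref_median = sb["median"], ref_q1 = sb["q1"], ref_q3 = sb["q3"],
      U = mw$U, p = mw$p, r = mw$r,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- feats
  out$q <- bhFDR(out$p)
  out <- out[, c("derivation", "feature", "case_median", "case_q1", "case_q3",
                 "ref_median", "ref_q1", "ref_q3", "U", "p", "q", "r")]
  attr(out, "df_range") <- dfRange(fs)
  attr(out, "groups") <- c(case = caseLev, reference = reference)
  out
}
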