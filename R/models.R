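# Modeling layer: covariate-adjusted logistic regressions, correlation
# pruning, elastic-net and forward-AIC classifiers, ROC/AUC.

.outcome01 <- function(fs, case = NULL) {
  grp <- colData(fs)$group
  lev <- sort(unique(grp))
  if (length(lev) != 2) stop("outcome must be binary", call. = FALSE)
  if (is.null(case)) case <- lev[1]
  as.integer(grp == case)
}

#' Covariate-adjusted logistic regression for one EEG feature
#'
#' Maximum-likelihood logistic fit of group membership on one feature,
#' adjusted for age, sex and MoCA.  The odds ratio is per one unit of
#' the raw feature (Hz, or percentage point for DFP), with a Wald 95%
#' confidence interval.  Complete separation is flagged and the
#' coefficient refit under a small ridge penalty, clearly labeled.
#'
#' @param fs an [EEGFeatureSet-class].
#' @param feature feature row name, e.g. `"global_df"`.
#' @param case group label modeled as the event; default: first group
#'   level in sorted order.
#' @return list with `feature`, `or`, `ci` (length-2), `p`, `logOR`,
#'   `se`, `separation` (logical).
#' @export
fitAdjustedLogistic <- function(fs, feature, case = NULL) {
  stopifnot(is(fs, "EEGFeatureSet"))
  if (!feature %in% rownames(fs))
    stop("unknown feature: ", feature, call. = FALSE)
  x <- assay(fs)[feature, ]
  if (sd(x) == 0)
    stop("feature '", feature, "' has zero variance", call. = FALSE)
  d <- data.frame(y = .outcome01(fs, case), x = x,
                  age = colData(fs)$age,
                  sex = factor(colData(fs)$sex),
                  moca = colData(fs)$moca)
  sepWarn <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x + age + sex + moca, family = binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sepWarn <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- coef(fit)["x"]
  se <- sqrt(vcov(fit)["x", "x"])
  separation <- sepWarn || !fit$converged || se > 50
  if (separation) {
    # ridge fallback: penalized estimate reported, no trustworthy Wald CI
    X <- model.matrix(~ x + age + sex + moca, d)[, -1]
    rf <- glmnet::glmnet(X, d$y, family = "binomial", alpha = 0,
                         lambda = 1e-2)
    co <- coef(rf)["x", 1]
    return(list(feature = feature, or = exp(co), ci = c(NA_real_, NA_real_),
                p = NA_real_, logOR = unname(co), se = NA_real_,
                separation = TRUE))
  }
  z <- co / se
  list(feature = feature,
       or = unname(exp(co)),
       ci = unname(exp(co + c(-1, 1) * qnorm(0.975) * se)),
       p = unname(2 * pnorm(-abs(z))),
       logOR = unname(co), se = unname(se), separation = FALSE)
}

#' Adjusted logistic models over a set of features
#'
#' Fits [fitAdjustedLogistic()] per feature and applies
#' Benjamini-Hochberg adjustment over the set tested.
#'
#' @param fs an [EEGFeatureSet-class].
#' @param features feature names; default all candidate features.
#' @param case see [fitAdjustedLogistic()].
#' @return data.frame with columns `feature`, `or`, `ci_lo`, `ci_hi`,
#'   `p`, `q`, `separation`.
#' @export
adjustedLogisticTable <- function(fs, features = candidateFeatures(fs),
                                  case = NULL) {
  rows <- lapply(features, function(f) {
    r <- fitAdjustedLogistic(fs, f, case)
    data.frame(feature = f, or = r$or, ci_lo = r$ci[1], ci_hi = r$ci[2],
               p = r$p, separation = r$separation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bhFDR(out$p[ok])
  out[, c("feature", "or", "ci_lo", "ci_hi", "p", "q", "separation")]
}

#' Prune highly correlated features
#'
#' Greedy elimination on absolute Spearman correlations: while any pair
#' exceeds the threshold, drop the member of the worst pair with the
#' higher mean absolute correlation to all remaining features (ties
#' drop the later column).  Deterministic.
#'
#' @param fs an [EEGFeatureSet-class] (or a subjects x features numeric
#'   matrix).
#' @param threshold correlation threshold in `(0, 1]` (default 0.9, which
#'   removes the near-duplicate inter-region copies while keeping
#'   cross-feature structure).
#' @param features candidate feature names to start from.
#' @return character vector of retained feature names.
#' @export
pruneCorrelated <- function(fs, threshold = 0.9,
                            features = if (is(fs, "EEGFeatureSet"))
                              candidateFeatures(fs) else colnames(fs)) {
  stopifnot(threshold > 0, threshold <= 1)
  X <- if (is(fs, "EEGFeatureSet")) featureMatrix(fs)[, features, drop = FALSE]
       else as.matrix(fs)[, features, drop = FALSE]
  if (ncol(X) < 2) return(colnames(X))
  keep <- colnames(X)[apply(X, 2, sd) > 0]   # constants carry no signal
  repeat {
    C <- abs(cor(X[, keep, drop = FALSE], method = "spearman"))
    C[is.na(C)] <- 0
    diag(C) <- 0
    mx <- max(C)
    if (mx <= threshold || length(keep) <= 1) break
    w <- which(C == mx, arr.ind = TRUE)[1, ]
    pair <- keep[sort(w)]
    meanAbs <- rowMeans(abs(C[pair, , drop = FALSE]))
    drop <- if (meanAbs[1] > meanAbs[2]) pair[1]
            else if (meanAbs[2] > meanAbs[1]) pair[2]
            else pair[which.max(match(pair, keep))]   # tie: later column
    keep <- setdiff(keep, drop)
  }
  keep
}

#' ROC curve and AUC
#'
#' AUC is the probability that a random positive outscores a random
#' negative, ties counted one half — computed as the trapezoidal
#' integral of the ROC curve over score-tie groups, which is exactly
#' equivalent.
#'
#' @param scores numeric risk scores, higher = more case-like.
#' @param labels binary labels (0/1 or logical), both classes present.
#' @return list with `auc` and `curve` (data.frame `fpr`, `tpr`,
#'   `threshold`).
#' @export
rocAUC <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0)
    stop("both classes must be present", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))               # tie groups of equal scores
  tp <- c(0, cumsum(tapply(y, grp, sum)))
  fp <- c(0, cumsum(tapply(1 - y, grp, sum)))
  tpr <- tp / nPos; fpr <- fp / nNeg
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(auc = auc,
       curve = data.frame(fpr = fpr, tpr = tpr,
                          threshold = c(Inf, unique(s))))
}

.stratifiedFolds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Elastic-net logistic classifier
#'
#' Penalized logistic regression combining L1 and L2 penalties (mixing
#' parameter 0.5 by default) on standardized features; the penalty
#' weight is chosen by stratified k-fold cross-validation maximizing CV
#' AUC.  Reports the nonzero-coefficient features, the apparent
#' (training) AUC and the cross-validated AUC, both labeled, plus the
#' selection-path metadata.
#'
#' @param fs an [EEGFeatureSet-class].
#' @param features feature names to offer; default all candidates.
#' @param alpha elastic-net mixing parameter (1 = lasso, 0 = ridge).
#' @param nfolds CV folds (default 10, stratified).
#' @param seed RNG seed for fold assignment.
#' @param case group label modeled as the event.
#' @param lambda optional fixed penalty grid override (decreasing, at
#'   least two values).
#' @param ... further arguments to [glmnet::glmnet()] (e.g. `thresh`).
#' @return list of class `"fluctexClassifier"`: `method`, `selected`,
#'   `coefficients`, `apparentAUC`, `cvAUC`, `roc`, `lambda`, `alpha`,
#'   `nfolds`, `seed`.
#' @export
fitElasticNet <- function(fs, features = candidateFeatures(fs),
                          alpha = 0.5, nfolds = 10, seed = 1,
                          case = NULL, lambda = NULL, ...) {
  stopifnot(is(fs, "EEGFeatureSet"), length(features) >= 2)
  y <- .outcome01(fs, case)
  if (length(unique(y)) < 2) stop("single-class outcome", call. = FALSE)
  if (length(y) < 10) stop("at least 10 subjects required", call. = FALSE)
  X <- featureMatrix(fs)[, features, drop = FALSE]
  X <- scale(X)
  keep <- !apply(X, 2, anyNA)                # zero-variance features drop out
  X <- X[, keep, drop = FALSE]
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                        lambda = lambda, standardize = FALSE, ...)
  lamSeq <- fit$lambda
  # cross-validated AUC from pooled out-of-fold linear predictors
  foldid <- .stratifiedFolds(y, nfolds, seed)
  oof <- matrix(NA_real_, length(y), length(lamSeq))
  for (k in seq_len(nfolds)) {
    test <- foldid == k
    fitk <- glmnet::glmnet(X[!test, , drop = FALSE], y[!test],
                           family = "binomial", alpha = alpha,
                           lambda = lamSeq, standardize = FALSE, ...)
    oof[test, ] <- predict(fitk, X[test, , drop = FALSE], s = lamSeq)
  }
  cvAuc <- apply(oof, 2, function(s) rocAUC(s, y)$auc)
  best <- which.max(cvAuc)                   # ties: largest lambda wins
  lam <- lamSeq[best]
  co <- coef(fit, s = lam, exact = FALSE)
  beta <- co[-1, 1]
  selected <- names(beta)[beta != 0]
  scores <- as.numeric(predict(fit, newx = X, s = lam))
  roc <- rocAUC(scores, y)
  structure(list(
    method = "elastic_net", selected = selected,
    coefficients = c(intercept = co[1, 1], beta),
    apparentAUC = roc$auc,
    cvAUC = unname(cvAuc[best]),
    roc = roc$curve, lambda = lam, alpha = alpha, nfolds = nfolds,
    seed = seed), class = "fluctexClassifier")
}

#' Forward selection by AIC
#'
#' Starts from the intercept-only logistic model and repeatedly adds the
#' candidate feature giving the largest AIC decrease, stopping when no
#' addition lowers AIC.  A parsimony check against the penalized model.
#'
#' @inheritParams fitElasticNet
#' @return list of class `"fluctexClassifier"`: `method`, `selected`
#'   (in selection order), `aicPath`, `apparentAUC`, `roc`,
#'   `coefficients`.
#' @export
forwardAIC <- function(fs, features = candidateFeatures(fs), case = NULL) {
  stopifnot(is(fs, "EEGFeatureSet"))
  y <- .outcome01(fs, case)
  d <- as.data.frame(featureMatrix(fs)[, features, drop = FALSE])
  d$.y <- y
  selected <- character(0)
  aicPath <- AIC(glm(.y ~ 1, binomial(), d))
  repeat {
    remaining <- setdiff(features, selected)
    if (!length(remaining)) break
    aics <- vapply(remaining, function(f) {
      fml <- as.formula(paste(".y ~", paste(c(selected, f), collapse = "+")))
      AIC(suppressWarnings(glm(fml, binomial(), d)))
    }, numeric(1))
    if (min(aics) >= tail(aicPath, 1) - 1e-9) break
    best <- remaining[which.min(aics)]
    selected <- c(selected, best)
    aicPath <- c(aicPath, min(aics))
  }
  fml <- if (length(selected))
    as.formula(paste(".y ~", paste(selected, collapse = "+"))) else .y ~ 1
  fit <- suppressWarnings(glm(fml, binomial(), d))
  scores <- predict(fit, type = "link")
  roc <- if (length(selected)) rocAUC(scores, y)
         else list(auc = 0.5, curve = NULL)
  structure(list(
    method = "forward_aic", selected = selected, aicPath = aicPath,
    apparentAUC = roc$auc, roc = roc$curve,
    coefficients = coef(fit)), class = "fluctexClassifier")
}

#' @export
print.fluctexClassifier <- function(x, ...) {
  cat("fluctex classifier (", x$method, ")\n", sep = "")
  cat("  selected:", if (length(x$selected))
    paste(x$selected, collapse = ", ") else "<intercept only>", "\n")
  cat(sprintf("  apparent AUC: %.3f\n", x$apparentAUC))
  if (!is.null(x$cvAUC)) cat(sprintf("  CV AUC:       %.3f\n", x$cvAUC))
  invisible(x)
}
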