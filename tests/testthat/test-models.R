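simulateOutcomeFS <- function(n, betas, seed, noiseFeatures = 0,
                              confounded = FALSE) {
  set.seed(seed)
  k <- length(betas) + noiseFeatures
  X <- matrix(rnorm(n * k), n, k)
  colnames(X) <- sprintf("global_f%02d", seq_len(k))
  eta <- X[, seq_along(betas), drop = FALSE] %*% betas
  if (confounded) eta <- eta   # covariates stay null by construction
  y <- rbinom(n, 1, plogis(eta))
  grp <- ifelse(y == 1, "case", "ctrl")
  fsFromMatrix(X, grp, age = rnorm(n, 73, 5),
               sex = sample(c("M", "F"), n, TRUE),
               moca = round(runif(n, 15, 30)))
}

test_that("adjusted logistic regression recovers a planted log-odds ratio", {
  fs <- simulateOutcomeFS(n = 1200, betas = -1, seed = 7)
  res <- fitAdjustedLogistic(fs, "global_f01", case = "case")
  expect_false(res$separation)
  expect_lt(abs(res$logOR - (-1)), 0.25)
  expect_gt(res$ci[1], 0)
  expect_lt(res$ci[1], res$or)
  expect_gt(res$ci[2], res$or)
})

test_that("a null feature keeps its CI around an odds ratio of 1", {
  fs <- simulateOutcomeFS(n = 1000, betas = 1, seed = 11, noiseFeatures = 1)
  res <- fitAdjustedLogistic(fs, "global_f02", case = "case")
  expect_gt(res$or, 0.8)
  expect_lt(res$or, 1.25)
  expect_true(res$ci[1] < 1 && res$ci[2] > 1)
})

test_that("zero-variance features and separation are handled explicitly", {
  X <- randomFeatureMatrix(20)
  X[, "global_df"] <- 5
  fs <- fsFromMatrix(X, rep(c("case", "ctrl"), each = 10))
  expect_error(fitAdjustedLogistic(fs, "global_df"), "zero variance")
  expect_error(fitAdjustedLogistic(fs, "nope"), "unknown feature")

  Xs <- randomFeatureMatrix(30)
  grp <- rep(c("case", "ctrl"), each = 15)
  Xs[, "global_iaf"] <- ifelse(grp == "case", 10, 0)  # complete separation
  sep <- fitAdjustedLogistic(fsFromMatrix(Xs, grp), "global_iaf",
                             case = "case")
  expect_true(sep$separation)
  expect_true(is.na(sep$p))
  expect_gt(sep$or, 1)
})

test_that("the per-feature model table applies BH across features", {
  fs <- simulateOutcomeFS(n = 300, betas = c(1, 0, 0), seed = 13)
  tab <- adjustedLogisticTable(fs, case = "case")
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$q >= tab$p, na.rm = TRUE))
  expect_equal(tab$q[!is.na(tab$p)], bhStepUpOracle(tab$p[!is.na(tab$p)]))
})

test_that("correlation pruning removes duplicates and spares independence", {
  set.seed(17)
  X <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  X <- cbind(X, f1copy = X[, "f1"])
  kept <- pruneCorrelated(X, threshold = 0.9, features = colnames(X))
  expect_length(kept, 4)
  expect_length(intersect(c("f1", "f1copy"), kept), 1)

  # threshold 1 with non-identical columns removes nothing
  expect_length(pruneCorrelated(X[, 1:4], threshold = 1,
                                features = paste0("f", 1:4)), 4)

  # mutually independent features survive a 0.9 threshold
  for (sd in 1:10) {
    set.seed(sd)
    Z <- matrix(rnorm(500 * 6), 500, 6,
                dimnames = list(NULL, paste0("z", 1:6)))
    expect_length(pruneCorrelated(Z, 0.9, features = colnames(Z)), 6)
  }
})

test_that("ROC AUC matches brute-force pairwise concordance exactly", {
  expect_equal(rocAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocAUC(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(rocAUC(1:4, rep(1, 4)), "both classes")

  set.seed(19)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    scores <- if (i %% 2) rnorm(n) else sample(1:5, n, TRUE)  # with ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(rocAUC(scores, labels)$auc,
                 aucBruteOracle(scores, labels), tolerance = 1e-12)
  }

  # independent scores hover around chance level
  set.seed(23)
  s <- rnorm(1000); y <- rbinom(1000, 1, 0.5)
  expect_lt(abs(rocAUC(s, y)$auc - 0.5), 0.05)
})

test_that("ROC curve agrees with pROC on a representative input", {
  skip_if_not_installed("pROC")
  set.seed(29)
  s <- rnorm(80); y <- rbinom(80, 1, 0.4)
  ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
  expect_equal(rocAUC(s, y)$auc, ref, tolerance = 1e-12)
})

test_that("a dominant penalty empties the elastic net", {
  fs <- simulateOutcomeFS(n = 60, betas = c(1, 0.5), seed = 31,
                          noiseFeatures = 2)
  en <- fitElasticNet(fs, features = rownames(fs), case = "case",
                      lambda = c(50, 40))
  expect_length(en$selected, 0)
  expect_equal(en$apparentAUC, 0.5)
})

test_that("a separable cohort reaches apparent AUC 1", {
  X <- randomFeatureMatrix(30)
  grp <- rep(c("case", "ctrl"), each = 15)
  X[, "global_df"] <- ifelse(grp == "case", 5, 9) + rnorm(30, 0, 0.1)
  en <- fitElasticNet(fsFromMatrix(X, grp), case = "case", seed = 2)
  expect_equal(en$apparentAUC, 1)
  expect_true("global_df" %in% en$selected)
})

test_that("elastic net selects planted informative features", {
  hits <- 0
  for (sd in 1:10) {
    fs <- simulateOutcomeFS(n = 200, betas = c(1, 1), seed = 100 + sd,
                            noiseFeatures = 8)
    en <- fitElasticNet(fs, case = "case", seed = sd)
    if (all(c("global_f01", "global_f02") %in% en$selected)) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("with a vanishing penalty the elastic net matches plain logistic", {
  fs <- simulateOutcomeFS(n = 400, betas = c(0.8, -0.6, 0.3), seed = 37)
  feats <- rownames(fs)
  en <- fitElasticNet(fs, feats, case = "case",
                      lambda = c(1e-4, 1e-5), thresh = 1e-14)
  X <- scale(featureMatrix(fs)[, feats])
  y <- as.integer(subjectData(fs)$group == "case")
  ref <- coef(glm(y ~ X, family = binomial()))
  expect_lt(max(abs(en$coefficients[-1] - ref[-1])), 1e-3)
})

test_that("forward AIC stops at the intercept under pure noise", {
  nullModels <- 0
  for (sd in 1:10) {
    set.seed(200 + sd)
    X <- matrix(rnorm(200 * 5), 200, 5,
                dimnames = list(NULL, sprintf("global_n%d", 1:5)))
    grp <- rep(c("case", "ctrl"), each = 100)
    fa <- forwardAIC(fsFromMatrix(X, grp), case = "case")
    if (length(fa$selected) == 0) nullModels <- nullModels + 1
  }
  expect_gte(nullModels, 6)
})

test_that("forward AIC picks the dominant feature first", {
  fs <- simulateOutcomeFS(n = 300, betas = c(2, 0, 0, 0), seed = 41)
  fa <- forwardAIC(fs, case = "case")
  expect_equal(fa$selected[1], "global_f01")
  expect_true(all(diff(fa$aicPath) < 0))

  empty <- forwardAIC(fs, features = character(0), case = "case")
  expect_length(empty$selected, 0)
  expect_equal(empty$apparentAUC, 0.5)
})
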