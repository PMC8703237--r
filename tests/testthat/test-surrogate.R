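test_that("AUC equals the exhaustive pairwise oracle", {
  expect_equal(rocAUC(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(rocAUC(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(rocAUC(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  set.seed(21)
  for (r in 1:25) {
    n <- sample(8:40, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(rocAUC(scores, labels), bruteForceAUC(scores, labels))
  }
  expect_error(rocAUC(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  scores <- rnorm(200)
  labels <- rbinom(200, 1, 0.3)
  expect_equal(rocAUC(scores, labels),
               as.numeric(pROC::auc(labels, scores, quiet = TRUE,
                                    direction = "<")))
})

test_that("surrogate prediction is the logistic of the linear predictor", {
  beta <- setNames(rep(0, 3), c("a", "b", "c"))
  m0 <- new("SurrogateModel", phenotype = "p", intercept = 0, beta = beta,
            alpha = 0.5, lambda = 1, center = numeric(), scale = numeric(),
            metadata = list())
  X <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(unname(predictSurrogate(m0, X)), rep(0.5, 5))

  beta["a"] <- 1
  m1 <- new("SurrogateModel", phenotype = "p", intercept = 0, beta = beta,
            alpha = 0.5, lambda = 1, center = numeric(), scale = numeric(),
            metadata = list())
  X1 <- matrix(c(log(3), 0, 0), 1, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(unname(predictSurrogate(m1, X1)), 0.75)

  # strictly increasing in the linear predictor
  Xs <- matrix(c(sort(rnorm(9)), rep(0, 18)), 9, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  expect_true(all(diff(predictSurrogate(m1, Xs)) > 0))

  # column mismatch names the missing marker
  expect_error(predictSurrogate(m1, X[, 1:2, drop = FALSE]), "c")
  # columns are matched by name, not position
  expect_equal(predictSurrogate(m1, X[, c(3, 1, 2)]),
               predictSurrogate(m1, X))
})

test_that("training honours the penalty limit and input contracts", {
  qc <- smallQC()
  X <- scaledMatrix(qc$dataset)
  y <- colData(qc$dataset)$strong_signal
  expect_error(trainSurrogate(X, rep(1, nrow(X))), "single-class")
  few <- c(which(y)[1:2], which(!y)[1])   # both classes, fewer than folds
  expect_error(trainSurrogate(X[few, ], y[few]), "folds")

  # enormous lambda: all coefficients zero, prediction = training prevalence
  m <- trainSurrogate(X, y, lambda = 1e6, phenotype = "strong_signal")
  expect_true(all(m@beta == 0))
  expect_equal(unname(predictSurrogate(m, X, scaled = TRUE)[1]),
               mean(as.numeric(y)), tolerance = 1e-6)
})

test_that("the lambda path is sparsity-monotone and selection is reproducible", {
  qc <- smallQC()
  X <- scaledMatrix(qc$dataset)
  y <- colData(qc$dataset)$moderate_signal
  m1 <- trainSurrogate(X, y, nRepeats = 2, seed = 9)
  m2 <- trainSurrogate(X, y, nRepeats = 2, seed = 9)
  expect_identical(m1@beta, m2@beta)
  expect_identical(m1@lambda, m2@lambda)
  path <- m1@metadata$cvPath
  # lambda decreasing along the path; nonzero count non-increasing in lambda
  expect_true(all(diff(path$lambda) < 0))
  expect_true(all(diff(path$nonzero) >= 0))
  # selected lambda minimises the mean inner-CV deviance
  expect_equal(m1@lambda, path$lambda[which.min(path$meanCVDeviance)])
})

test_that("projection reproduces the probabilities used in evaluation", {
  qc <- smallQC()
  X <- scaledMatrix(qc$dataset)
  y <- colData(qc$dataset)$strong_signal
  m <- trainSurrogate(X, y, nRepeats = 1, seed = 2,
                      center = qc$report@center, scale = qc$report@scale)
  pScaled <- predictSurrogate(m, X, scaled = TRUE)
  pRaw <- predictSurrogate(m, concentrations(qc$dataset))
  expect_equal(pScaled, pRaw, tolerance = 1e-12)
  expect_identical(predictSurrogate(m, X, scaled = TRUE), pScaled)
})

test_that("hyperparameter selection never sees held-out data", {
  qc <- smallQC()
  X <- scaledMatrix(qc$dataset)
  y <- as.numeric(colData(qc$dataset)$weak_signal)
  train <- seq_len(nrow(X)) <= 450
  mA <- trainSurrogate(X[train, ], y[train], nRepeats = 1, seed = 5)
  # permute the held-out labels: the trained model must be unchanged
  yB <- y
  yB[!train] <- sample(yB[!train])
  mB <- trainSurrogate(X[train, ], yB[train], nRepeats = 1, seed = 5)
  expect_identical(mA@beta, mB@beta)
  expect_identical(mA@lambda, mB@lambda)
})

test_that("double CV reports stratified folds and is seed-deterministic", {
  qc <- smallQC()
  X <- scaledMatrix(qc$dataset)
  y <- colData(qc$dataset)$strong_signal
  ev1 <- evaluateCV(X, y, nRepeatsOuter = 1, nRepeatsInner = 1,
                    phenotype = "strong_signal", seed = 3)
  ev2 <- evaluateCV(X, y, nRepeatsOuter = 1, nRepeatsInner = 1,
                    phenotype = "strong_signal", seed = 3)
  expect_identical(ev1@folds, ev2@folds)
  expect_identical(nrow(ev1@folds), 5L)
  expect_true(all(ev1@folds$auc >= 0 & ev1@folds$auc <= 1))
  # stratification keeps fold prevalences close to the overall one
  expect_lt(max(abs(ev1@folds$prevalenceTest - mean(y))), 0.05)
  expect_true(ev1@pass)
  expect_gte(ev1@weightedAUC, min(ev1@folds$auc))
  expect_lte(ev1@weightedAUC, max(ev1@folds$auc))
})

test_that("LOBOV weights by held-out size and skips single-class cohorts", {
  qc <- smallQC()
  X <- scaledMatrix(qc$dataset)
  cd <- colData(qc$dataset)
  y <- cd$strong_signal
  co <- cohorts(qc$dataset)
  lb <- evaluateLOBOV(X, y, co, nRepeatsInner = 1, seed = 6,
                      phenotype = "strong_signal")
  expect_identical(sort(unique(lb@folds$cohort)), sort(unique(co)))
  expect_equal(lb@weightedAUC,
               sum(lb@folds$auc * lb@folds$weight) / sum(lb@folds$weight))
  expect_equal(lb@folds$weight, as.integer(table(co)[lb@folds$cohort]),
               ignore_attr = TRUE)

  # a held-out cohort without positives is skipped with a warning
  y2 <- y
  y2[co == "cohort01"] <- FALSE
  expect_warning(
    lb2 <- evaluateLOBOV(X, y2, co, nRepeatsInner = 1, seed = 6),
    "cohort01")
  expect_false("cohort01" %in% lb2@folds$cohort)

  expect_error(evaluateLOBOV(X, y, rep("one", nrow(X))), "two cohorts")
})

test_that("relative importance is scale-free and sums to one in magnitude", {
  mk <- function(beta) new("SurrogateModel", phenotype = "m", intercept = 0,
                           beta = beta, alpha = 0.5, lambda = 1,
                           center = numeric(), scale = numeric(),
                           metadata = list())
  b <- setNames(c(2, -1, 1), c("a", "b", "c"))
  ri <- relativeImportance(list(mk(b)))
  expect_equal(unname(ri[1, ]), c(0.5, -0.25, 0.25))
  expect_equal(sum(abs(ri)), 1)
  expect_equal(relativeImportance(list(mk(3.7 * b))), ri)
  single <- setNames(c(0, 0.4, 0), c("a", "b", "c"))
  expect_equal(unname(relativeImportance(list(mk(single)))[1, ]),
               c(0, 1, 0))
  expect_error(relativeImportance(list(mk(b * 0))), "all-zero")
  # signed-sum variant
  expect_equal(unname(relativeImportance(list(mk(b)), signedSum = TRUE)[1, ]),
               c(1, -0.5, 0.5))
})

test_that("surrogate correlations and label separation behave", {
  set.seed(8)
  s1 <- runif(300)
  S <- cbind(x = s1, y = s1, z = runif(300))
  dep <- surrogateDependencies(S)
  expect_equal(dep$correlations["x", "y"], 1)
  expect_error(surrogateDependencies(cbind(a = rep(1, 10), b = runif(10))),
               "constant")

  lab <- data.frame(x = c(rep(TRUE, 100), rep(FALSE, 180), rep(NA, 20)))
  S2 <- cbind(x = c(rnorm(100, 1), rnorm(180, 0), rnorm(20, 0.2)),
              z = rnorm(300))
  dep2 <- surrogateDependencies(S2, lab)
  sep <- dep2$separation
  expect_identical(sep$phenotype, "x")
  expect_gt(sep$muTRUE, sep$muFALSE)
  expect_lt(sep$p, 1e-6)
  expect_equal(sep$muNA, mean(S2[is.na(lab$x), "x"]))
  expect_equal(sep$muTRUE, mean(S2[which(lab$x), "x"]))
})
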