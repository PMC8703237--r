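#' Area under the ROC curve (Mann-Whitney form)
#'
#' Equals the probability that a randomly chosen positive outscores a
#' randomly chosen negative, with ties counted one half — computed from
#' average ranks, so it is exact for any tie pattern.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (logical, 0/1 or two-level factor).
#' @return AUC in \[0, 1\].
#' @examples
#' rocAUC(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
rocAUC <- function(scores, labels) {
  y <- asBinary(labels)
  keep <- !is.na(scores) & !is.na(y)
  scores <- scores[keep]; y <- y[keep]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

asBinary <- function(labels) {
  y <- if (is.factor(labels)) {
    if (nlevels(labels) != 2)
      stop("labels must be binary", call. = FALSE)
    as.integer(labels) - 1L
  } else if (is.logical(labels)) {
    as.integer(labels)
  } else {
    as.integer(labels)
  }
  if (!all(stats::na.omit(y) %in% 0:1))
    stop("labels must be binary", call. = FALSE)
  y
}

# label-stratified fold assignment: each class spread evenly over folds
stratifiedFolds <- function(y, k) {
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    foldid[idx] <- rep_len(seq_len(k), length(idx))
  }
  foldid
}

#' Train a penalized-logistic metabolic surrogate
#'
#' Fits the elastic-net logistic regression
#' \eqn{\pi = 1/(1 + e^{-(\beta_0 + \beta^T m)})} over the scaled marker
#' matrix, with the mixing parameter fixed (default \eqn{\alpha = 0.5},
#' equal L1/L2 weighting) and the penalty weight \eqn{\lambda} selected by
#' repeated stratified 5-fold cross-validation: the path's ~100
#' log-spaced \eqn{\lambda} values (down four decades from the smallest
#' \eqn{\lambda} that zeroes all coefficients) are scored by mean held-out
#' binomial deviance across \code{nRepeats} independent fold partitions,
#' and the minimiser is taken. The L1 component makes some coefficients
#' exactly zero, so the selected \eqn{\lambda} also determines how many
#' markers the surrogate uses.
#'
#' @param X complete, z-scaled samples-by-markers matrix.
#' @param y binary labels with both classes present.
#' @param alpha elastic-net mixing parameter in \[0, 1\].
#' @param nFolds,nRepeats inner cross-validation folds and repeats.
#' @param phenotype name stored in the model.
#' @param center,scale optional named per-marker scaling parameters (from
#'   [zScale()]) stored for projection onto raw data.
#' @param lambda optional fixed \eqn{\lambda} sequence or single value
#'   (skips selection when a single value is given).
#' @param seed RNG seed for the fold partitions.
#' @return A [SurrogateModel-class].
#' @export
trainSurrogate <- function(X, y, alpha = 0.5, nFolds = 5, nRepeats = 5,
                           phenotype = "phenotype", center = numeric(),
                           scale = numeric(), lambda = NULL, seed = 1) {
  X <- as.matrix(X)
  y <- asBinary(y)
  if (length(unique(y)) < 2)
    stop("labels are single-class; cannot train a surrogate", call. = FALSE)
  if (nrow(X) < nFolds)
    stop("fewer samples than folds", call. = FALSE)
  withSeed(seed, {
    path <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                           lambda = if (length(lambda) > 1) lambda else NULL)
    if (length(lambda) == 1) {
      lambdaMin <- lambda
      cvTab <- NULL
    } else {
      lamseq <- path$lambda
      cvm <- matrix(NA_real_, length(lamseq), nRepeats)
      for (r in seq_len(nRepeats)) {
        foldid <- stratifiedFolds(y, nFolds)
        cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                                lambda = lamseq, foldid = foldid,
                                type.measure = "deviance")
        cvm[match(cv$lambda, lamseq), r] <- cv$cvm
      }
      meanDev <- rowMeans(cvm, na.rm = TRUE)
      lambdaMin <- lamseq[which.min(meanDev)]
      cvTab <- data.frame(lambda = lamseq, nonzero = path$df,
                          meanCVDeviance = meanDev)
    }
    cf <- as.matrix(coef(path, s = lambdaMin))
    beta <- setNames(cf[-1, 1], colnames(X))
    new("SurrogateModel", phenotype = phenotype, intercept = cf[1, 1],
        beta = beta, alpha = alpha, lambda = lambdaMin,
        center = center, scale = scale,
        metadata = list(n = nrow(X), prevalence = mean(y), seed = seed,
                        nFolds = nFolds, nRepeats = nRepeats,
                        cvPath = cvTab, date = format(Sys.Date())))
  })
}

#' Project a surrogate onto new samples
#'
#' Deterministically computes the surrogate value
#' \eqn{\pi = 1/(1 + e^{-(\beta_0 + \beta^T m)})} for each new sample.
#' Columns are matched to the model's panel by name; any model marker
#' absent from the new data is an explicit error naming the marker. When
#' the model carries scaling parameters the new data are assumed raw and
#' are standardized with the training parameters first; pass
#' \code{scaled = TRUE} to skip that step.
#'
#' @param model a [SurrogateModel-class].
#' @param newX samples-by-markers matrix.
#' @param scaled is \code{newX} already on the model's standardized scale?
#'   Default: TRUE when the model stores no scaling parameters.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predictSurrogate <- function(model, newX, scaled = length(model@center) == 0) {
  newX <- as.matrix(newX)
  if (!scaled) {
    newX <- applyScaling(newX, model@center, model@scale)
  } else {
    absent <- setdiff(names(model@beta), colnames(newX))
    if (length(absent))
      stop("new data is missing model marker(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    newX <- newX[, names(model@beta), drop = FALSE]
  }
  eta <- drop(model@intercept + newX %*% model@beta)
  setNames(1 / (1 + exp(-eta)), rownames(newX))
}

#' @rdname predictSurrogate
#' @param object a [SurrogateModel-class].
#' @param newdata samples-by-markers matrix.
#' @param ... passed to [predictSurrogate()].
#' @export
setMethod("predict", "SurrogateModel", function(object, newdata, ...) {
  predictSurrogate(object, newdata, ...)
})

#' Double cross-validated evaluation of a surrogate
#'
#' Outer 5-fold cross-validation repeated \code{nRepeatsOuter} times with
#' independent label-stratified partitions; within every outer training
#' split the full inner \eqn{\lambda}-selection loop of [trainSurrogate()]
#' runs from scratch, so no information from the outer test fold reaches
#' the hyperparameter choice. Performance is the AUC of the held-out
#' predictions per fold.
#'
#' @inheritParams trainSurrogate
#' @param nFoldsOuter,nRepeatsOuter outer loop settings.
#' @param nFoldsInner,nRepeatsInner inner loop settings.
#' @param aucThreshold accuracy criterion for the pass flag (default 0.7).
#' @return An [EvaluationReport-class] with mode "cv".
#' @export
evaluateCV <- function(X, y, alpha = 0.5, nFoldsOuter = 5, nRepeatsOuter = 5,
                       nFoldsInner = 5, nRepeatsInner = 5,
                       aucThreshold = 0.7, phenotype = "phenotype",
                       seed = 1) {
  X <- as.matrix(X); y <- asBinary(y)
  if (length(unique(y)) < 2)
    stop("labels are single-class", call. = FALSE)
  rows <- list()
  for (r in seq_len(nRepeatsOuter)) {
    foldid <- withSeed(stageSeed(seed, paste0("outer", r)),
                       stratifiedFolds(y, nFoldsOuter))
    for (f in seq_len(nFoldsOuter)) {
      test <- foldid == f
      fit <- trainSurrogate(X[!test, , drop = FALSE], y[!test],
                            alpha = alpha, nFolds = nFoldsInner,
                            nRepeats = nRepeatsInner, phenotype = phenotype,
                            seed = stageSeed(seed, sprintf("inner%d.%d", r, f)))
      auc <- rocAUC(predictSurrogate(fit, X[test, , drop = FALSE],
                                     scaled = TRUE), y[test])
      rows[[length(rows) + 1L]] <-
        data.frame(repeatId = r, fold = f, auc = auc, weight = sum(test),
                   nTest = sum(test), prevalenceTest = mean(y[test]))
    }
  }
  folds <- do.call(rbind, rows)
  wAUC <- sum(folds$auc * folds$weight) / sum(folds$weight)
  new("EvaluationReport", phenotype = phenotype, mode = "cv", folds = folds,
      meanAUC = mean(folds$auc), weightedAUC = wAUC,
      aucThreshold = aucThreshold, pass = wAUC > aucThreshold,
      metadata = list(seed = seed, alpha = alpha,
                      nFoldsOuter = nFoldsOuter,
                      nRepeatsOuter = nRepeatsOuter,
                      nFoldsInner = nFoldsInner,
                      nRepeatsInner = nRepeatsInner))
}

#' Leave-one-biobank-out validation of a surrogate
#'
#' Each cohort in turn is held out entirely; a surrogate is trained (with
#' its full inner \eqn{\lambda}-selection loop) on the remaining cohorts
#' and scored on the held-out one. The summary is the mean AUC weighted by
#' held-out sample count. Cohorts whose held-out samples contain only one
#' class are skipped with a warning — an undefined AUC is not evidence —
#' as are cohorts whose removal leaves single-class training data.
#'
#' @inheritParams evaluateCV
#' @param cohorts per-sample cohort labels (>= 2 distinct).
#' @return An [EvaluationReport-class] with mode "lobov".
#' @export
evaluateLOBOV <- function(X, y, cohorts, alpha = 0.5, nFoldsInner = 5,
                          nRepeatsInner = 5, aucThreshold = 0.7,
                          phenotype = "phenotype", seed = 1) {
  X <- as.matrix(X); y <- asBinary(y)
  cohorts <- as.character(cohorts)
  ids <- unique(cohorts)
  if (length(ids) < 2)
    stop("leave-one-biobank-out needs at least two cohorts", call. = FALSE)
  rows <- list()
  for (co in ids) {
    test <- cohorts == co
    if (length(unique(y[test])) < 2) {
      warning("held-out cohort '", co,
              "' lacks a class; skipped from LOBOV", call. = FALSE)
      next
    }
    if (length(unique(y[!test])) < 2) {
      warning("training data without cohort '", co,
              "' is single-class; skipped", call. = FALSE)
      next
    }
    fit <- trainSurrogate(X[!test, , drop = FALSE], y[!test], alpha = alpha,
                          nFolds = nFoldsInner, nRepeats = nRepeatsInner,
                          phenotype = phenotype,
                          seed = stageSeed(seed, paste0("lobov.", co)))
    auc <- rocAUC(predictSurrogate(fit, X[test, , drop = FALSE],
                                   scaled = TRUE), y[test])
    rows[[length(rows) + 1L]] <-
      data.frame(cohort = co, auc = auc, weight = sum(test),
                 nTest = sum(test), prevalenceTest = mean(y[test]))
  }
  if (!length(rows))
    stop("no evaluable cohort in LOBOV", call. = FALSE)
  folds <- do.call(rbind, rows)
  wAUC <- sum(folds$auc * folds$weight) / sum(folds$weight)
  new("EvaluationReport", phenotype = phenotype, mode = "lobov",
      folds = folds, meanAUC = mean(folds$auc), weightedAUC = wAUC,
      aucThreshold = aucThreshold, pass = wAUC > aucThreshold,
      metadata = list(seed = seed, alpha = alpha,
                      nFoldsInner = nFoldsInner,
                      nRepeatsInner = nRepeatsInner,
                      nCohortsEvaluated = nrow(folds)))
}

#' Relative importance of markers across surrogate models
#'
#' Scales each model's coefficient vector by the sum of its absolute
#' coefficients, so importances are comparable between models: every row
#' sums to 1 in absolute value and is invariant to rescaling the
#' coefficients by a positive constant. A signed-sum denominator is
#' available behind \code{signedSum} for models with a one-sided
#' coefficient pattern.
#'
#' @param models list of [SurrogateModel-class] objects over a common
#'   panel.
#' @param signedSum divide by the plain (signed) coefficient sum instead
#'   of the absolute sum.
#' @return Matrix (models x markers) of relative importances.
#' @export
relativeImportance <- function(models, signedSum = FALSE) {
  if (!length(models)) stop("no models given", call. = FALSE)
  out <- t(vapply(models, function(m) {
    denom <- if (signedSum) sum(m@beta) else sum(abs(m@beta))
    if (denom == 0)
      stop("model '", m@phenotype, "' has all-zero coefficients",
           call. = FALSE)
    m@beta / denom
  }, numeric(length(models[[1]]@beta))))
  rownames(out) <- vapply(models, function(m) m@phenotype, "")
  out
}

#' Surrogate correlations and label separation
#'
#' Pairwise Pearson correlations between surrogate value columns, and —
#' for every phenotype with observed labels — the Welch two-sample t test
#' of the surrogate between the TRUE and FALSE label groups together with
#' the group means for the TRUE, FALSE and missing-label strata.
#'
#' @param surrogates samples-by-surrogates numeric matrix (columns named
#'   by phenotype).
#' @param labels optional data.frame of logical label columns; phenotypes
#'   are matched to surrogate columns by name.
#' @return \code{list(correlations, separation)}; \code{separation} is a
#'   data.frame with phenotype, t, df, p, muTRUE, muFALSE, muNA.
#' @export
surrogateDependencies <- function(surrogates, labels = NULL) {
  S <- as.matrix(surrogates)
  if (ncol(S) < 2)
    stop("need at least two surrogates", call. = FALSE)
  sds <- apply(S, 2, sd)
  if (any(sds == 0))
    stop("constant surrogate column(s): ",
         paste(colnames(S)[sds == 0], collapse = ", "), call. = FALSE)
  cors <- cor(S)
  sepRows <- list()
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    for (ph in intersect(colnames(S), names(labels))) {
      lab <- as.logical(labels[[ph]])
      s <- S[, ph]
      if (length(unique(stats::na.omit(lab))) < 2) next
      tt <- t.test(s[lab %in% TRUE], s[lab %in% FALSE])
      sepRows[[ph]] <- data.frame(
        phenotype = ph, t = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value,
        muTRUE = mean(s[lab %in% TRUE]), muFALSE = mean(s[lab %in% FALSE]),
        muNA = if (anyNA(lab)) mean(s[is.na(lab)]) else NA_real_)
    }
  }
  list(correlations = cors,
       separation = if (length(sepRows)) do.call(rbind, c(sepRows, list(make.row.names = FALSE)))
       else data.frame())
}
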