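#' Rank-based inverse-normal transformation
#'
#' Maps values to standard-normal quantiles through their ranks,
#' \eqn{\Phi^{-1}((r_i - c)/(n - 2c + 1))} with the Blom offset
#' \eqn{c = 3/8} and average ranks for ties. The output is strictly
#' monotone in the input ranks (hence invariant to any monotone transform
#' of the input) and removes the right skew typical of metabolite
#' concentrations before association testing. NAs are kept in place.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @param offset rank offset constant (3/8 Blom, 1/2 van der Waerden-ish
#'   variants are possible).
#' @return Numeric vector of normal scores.
#' @examples
#' rinTransform(c(3, 1, 2))  # middle value maps to 0
#' @export
rinTransform <- function(values, offset = 3/8) {
  ok <- is.finite(values)
  if (length(unique(values[ok])) < 2)
    stop("need at least two distinct finite values", call. = FALSE)
  n <- sum(ok)
  r <- rank(values[ok], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Effective number of tests from principal components
#'
#' The smallest number of principal components of the RIN-transformed,
#' standardized marker matrix that together explain at least
#' \code{varThreshold} of the total variance. Used as the Bonferroni
#' denominator of a metabolome-wide association study, acknowledging that
#' correlated markers do not constitute independent tests. Never exceeds
#' the matrix rank and is recomputed per analysis dataset.
#'
#' @param markerMatrix complete samples-by-markers numeric matrix.
#' @param varThreshold variance fraction in (0, 1\]; 1 returns the rank.
#' @param rin apply [rinTransform()] per marker first (default).
#' @return Integer count of effective tests.
#' @export
effectiveTests <- function(markerMatrix, varThreshold = 0.99, rin = TRUE) {
  X <- as.matrix(markerMatrix)
  if (nrow(X) <= 2) stop("need more than two samples", call. = FALSE)
  if (rin) X <- apply(X, 2, rinTransform)
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  rk <- sum(ev > max(ev) * 1e-9)
  if (rk == 0) stop("degenerate marker matrix (rank 0)", call. = FALSE)
  frac <- cumsum(ev) / sum(ev)
  as.integer(min(which(frac >= varThreshold - 1e-12)[1], rk))
}

#' Bonferroni threshold for an effective number of tests
#'
#' @param kEff effective number of tests (>= 1).
#' @param alpha family-wise error target.
#' @return \code{alpha / kEff}.
#' @examples
#' bonferroniThreshold(40)  # 0.00125
#' @export
bonferroniThreshold <- function(kEff, alpha = 0.05) {
  stopifnot(kEff >= 1)
  alpha / kEff
}

#' Metabolome-wide association study
#'
#' One linear model per marker with the (RIN-transformed) marker as
#' response and the phenotype plus covariates as predictors; the reported
#' effect is the phenotype coefficient with its t-based p-value. All
#' markers share one design matrix, so the fits are computed with a single
#' QR decomposition. Significance uses the effective-number-of-tests
#' Bonferroni threshold \code{0.05 / kEff} computed on the same marker
#' matrix.
#'
#' @param markerMatrix samples-by-markers numeric matrix (raw; transformed
#'   internally when \code{rin = TRUE}).
#' @param phenotype numeric or binary vector (the tested predictor).
#' @param covariates optional data.frame / matrix of adjustment columns.
#' @param rin RIN-transform the markers first (default TRUE).
#' @param kEff override the effective test count (default: computed from
#'   the marker matrix via [effectiveTests()]).
#' @param varThreshold passed to [effectiveTests()].
#' @param alpha family-wise error target for the threshold.
#' @return A [MetaboWASResult-class].
#' @export
runMetaboWAS <- function(markerMatrix, phenotype, covariates = NULL,
                         rin = TRUE, kEff = NULL, varThreshold = 0.99,
                         alpha = 0.05) {
  X <- as.matrix(markerMatrix)
  ph <- as.numeric(phenotype)
  covariates <- if (is.null(covariates)) {
    matrix(numeric(0), nrow(X), 0)
  } else {
    cv <- as.data.frame(covariates)
    mf <- stats::model.frame(~ ., data = cv, na.action = stats::na.pass)
    stats::model.matrix(~ ., mf)[, -1, drop = FALSE]
  }
  keep <- !is.na(ph) & complete.cases(X) &
    (if (ncol(covariates)) complete.cases(covariates) else TRUE)
  X <- X[keep, , drop = FALSE]; ph <- ph[keep]
  covariates <- covariates[keep, , drop = FALSE]
  n <- nrow(X)
  design <- cbind(`(Intercept)` = 1, phenotype = ph, covariates)
  pPar <- ncol(design)
  if (n <= pPar)
    stop("not enough samples for the number of model parameters",
         call. = FALSE)
  qrD <- qr(design)
  if (qrD$rank < pPar)
    stop("design matrix is rank-deficient (collinear covariates)",
         call. = FALSE)
  if (rin) X <- apply(X, 2, rinTransform)
  if (is.null(kEff))
    kEff <- effectiveTests(X, varThreshold = varThreshold, rin = FALSE)
  coefs <- qr.coef(qrD, X)                   # pPar x markers
  res <- X - design %*% coefs
  df <- n - pPar
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrD))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  beta <- coefs["phenotype", ]
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df)
  thr <- bonferroniThreshold(kEff, alpha)
  tab <- data.frame(marker = colnames(X), beta = unname(beta),
                    se = unname(se), t = unname(tstat), p = unname(pval),
                    significant = unname(pval < thr),
                    row.names = NULL)
  new("MetaboWASResult", table = tab, kEff = as.integer(kEff),
      threshold = thr, phenotype = "phenotype",
      covariates = colnames(covariates) %||% character(),
      n = as.integer(n))
}

#' Compare two adjustment strategies of the same MetaboWAS
#'
#' Pairs the per-marker effect estimates obtained under two different
#' adjustment sets (e.g. adjusting for a measured confounder vs for its
#' metabolic surrogate), reporting the squared correlation of the estimate
#' vectors, the 2x2 significance contingency (both / A-only / B-only /
#' neither, summing to the markers tested), sign agreement, and
#' discordance rates under explicit definitions: the A-only count over the
#' A-significant count, and the B-only count over the A-nonsignificant
#' count. Raw counts are always reported alongside the rates.
#'
#' @param resultA,resultB [MetaboWASResult-class] objects over the same
#'   marker set.
#' @return List: \code{estimates} (paired data.frame), \code{r2},
#'   \code{signAgreement}, \code{contingency} (named counts),
#'   \code{rates} with their definitions.
#' @export
compareAdjustments <- function(resultA, resultB) {
  a <- resultA@table; b <- resultB@table
  if (!identical(sort(a$marker), sort(b$marker)))
    stop("the two results cover different marker sets", call. = FALSE)
  b <- b[match(a$marker, b$marker), ]
  both <- sum(a$significant & b$significant)
  aOnly <- sum(a$significant & !b$significant)
  bOnly <- sum(!a$significant & b$significant)
  neither <- sum(!a$significant & !b$significant)
  est <- data.frame(marker = a$marker, betaA = a$beta, betaB = b$beta,
                    significantA = a$significant,
                    significantB = b$significant)
  list(
    estimates = est,
    r2 = cor(a$beta, b$beta)^2,
    signAgreement = mean(sign(a$beta) == sign(b$beta)),
    contingency = c(both = both, aOnly = aOnly, bOnly = bOnly,
                    neither = neither, total = nrow(a)),
    rates = list(
      aOnlyOverASignificant =
        if (both + aOnly > 0) aOnly / (both + aOnly) else NA_real_,
      bOnlyOverANonsignificant =
        if (bOnly + neither > 0) bOnly / (bOnly + neither) else NA_real_,
      definitions = c(
        aOnlyOverASignificant = "markers significant under A only / markers significant under A",
        bOnlyOverANonsignificant = "markers significant under B only / markers not significant under A")))
}

#' Controlled confounder-substitution experiment
#'
#' Simulates the design used to ask whether a metabolic surrogate can
#' stand in for an unmeasured confounder in a metabolome-wide association
#' study: a confounder phenotype and an outcome phenotype are planted
#' with overlapping marker weights, a surrogate is trained for the
#' confounder, and the MetaboWAS of the outcome is run twice — once
#' adjusted for the true (continuous) confounder liability, once for the
#' trained surrogate — with the per-marker effect estimates compared via
#' [compareAdjustments()].
#'
#' @details The experiment runs within a single simulated cohort (as the
#'   real substitution analysis does) and plants the confounder along a
#'   compact metabolite axis — the inflammation plus glycolysis-related
#'   classes, an inflammatory-glycaemic shift of the kind adiposity
#'   produces. Two properties of this choice matter. The axis must sit
#'   close to the covariance eigenstructure, or the planted liability and
#'   the Bayes discriminant any classifier estimates (along
#'   \eqn{\Sigma^{-1}w}) diverge and no surrogate could track the truth
#'   at the required fidelity. And its footprint must be compact: the
#'   surrogate is a function of the markers, so on markers heavily loaded
#'   by the confounder it absorbs more variance than the latent liability
#'   itself does — a broad confounder axis turns that asymmetry into
#'   divergent effect estimates for a third of the panel, whereas a
#'   compact axis confines it to a handful of markers.
#'
#' @param nCohorts,cohortSizes simulated study dimensions (default: one
#'   cohort of 3,500 samples).
#' @param confounderAUC oracle AUC of the planted confounder phenotype
#'   (high, so the surrogate tracks the liability closely).
#' @param outcomeAUC,outcomePrev oracle AUC and prevalence of the outcome.
#' @param overlap weight of the confounder axis inside the outcome's
#'   liability (creates the confounding). The outcome additionally
#'   carries a fixed footprint of its own on the amino-acid and
#'   fatty-acid classes, so its effect profile is broad and not dominated
#'   by the handful of confounder-axis markers where the two adjustment
#'   strategies intrinsically differ.
#' @param seed integer seed.
#' @return List: \code{surrogateConfounderCor} (Pearson r between the
#'   surrogate and the true liability), \code{surrogateAUC},
#'   \code{comparison} (from [compareAdjustments()]; adjustment A = true
#'   confounder, B = surrogate), and the two [MetaboWASResult-class]s.
#' @export
confounderSubstitution <- function(nCohorts = 1, cohortSizes = 3500,
                                   confounderAUC = 0.95, outcomeAUC = 0.85,
                                   outcomePrev = 0.15, overlap = 0.4,
                                   seed = 1) {
  panel <- defaultPanel()
  cls <- markerClasses(panel)
  wC <- as.numeric(cls %in% c("inflammation", "glycolysis-related"))
  wO <- overlap * wC + as.numeric(cls %in% c("amino acids", "fatty acids"))
  sim <- simulateCohorts(
    nCohorts = nCohorts, cohortSizes = cohortSizes,
    phenotypes = list(
      phenotypeSpec("confounder_like", prevalence = 0.4,
                    auc = confounderAUC, weights = wC),
      phenotypeSpec("outcome_like", prevalence = outcomePrev,
                    auc = outcomeAUC, weights = wO)),
    seed = stageSeed(seed, "confounder.sim"))
  qc <- qcPreprocess(sim$dataset)
  ds <- qc$dataset
  X <- scaledMatrix(ds)
  conf <- sim$truth@liabilities[colnames(ds), "confounder_like"]
  fit <- trainSurrogate(X, colData(ds)$confounder_like, nRepeats = 1,
                        phenotype = "confounder_like",
                        seed = stageSeed(seed, "confounder.train"))
  surr <- predictSurrogate(fit, X, scaled = TRUE)
  base <- data.frame(age = colData(ds)$age, sex = colData(ds)$sex)
  resA <- runMetaboWAS(concentrations(ds), colData(ds)$outcome_like,
                       covariates = cbind(base, confounder = conf))
  resB <- runMetaboWAS(concentrations(ds), colData(ds)$outcome_like,
                       covariates = cbind(base, confounder = surr))
  list(surrogateConfounderCor = cor(surr, conf),
       surrogateAUC = rocAUC(surr, colData(ds)$confounder_like),
       comparison = compareAdjustments(resA, resB),
       adjustTrue = resA, adjustSurrogate = resB)
}
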