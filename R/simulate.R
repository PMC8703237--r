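#' Specify a planted binary phenotype
#'
#' Defines one binary phenotype of the synthetic generator in terms of its
#' target prevalence and the discriminability of its metabolite-linked
#' liability. Labels follow the equal-variance binormal liability model:
#' the standardized liability is N(0, 1) in controls and N(d, 1) in cases,
#' so the oracle AUC of the true liability is \eqn{\Phi(d/\sqrt{2})}.
#' Either \code{d} or the target \code{auc} may be given; they are
#' interconvertible through that identity.
#'
#' @param name phenotype name (becomes a logical colData column).
#' @param prevalence target prevalence in (0, 1).
#' @param auc target oracle AUC in \[0.5, 1); mapped to
#'   \code{d = sqrt(2) * qnorm(auc)}.
#' @param d standardized mean liability difference between cases and
#'   controls (>= 0); overrides \code{auc} when given.
#' @param weights optional named (or panel-length) marker weight vector for
#'   the liability direction; default: a random half of the markers with
#'   standard-normal weights, drawn from the generator seed.
#' @param sexLinked if TRUE the label is male sex itself (the liability
#'   shift is then applied between the sexes), emulating a sex phenotype.
#' @return A \code{plantedPhenotype} list understood by
#'   [simulateCohorts()].
#' @export
phenotypeSpec <- function(name, prevalence = 0.2, auc = NULL, d = NULL,
                          weights = NULL, sexLinked = FALSE) {
  if (!sexLinked && (prevalence <= 0 || prevalence >= 1))
    stop("prevalence must be in (0, 1)", call. = FALSE)
  if (is.null(d)) {
    if (is.null(auc)) stop("give either 'auc' or 'd'", call. = FALSE)
    if (auc < 0.5 || auc >= 1) stop("auc must be in [0.5, 1)", call. = FALSE)
    d <- sqrt(2) * qnorm(auc)
  }
  if (d < 0) stop("d must be non-negative", call. = FALSE)
  structure(list(name = name, prevalence = prevalence, d = d,
                 oracleAUC = pnorm(d / sqrt(2)), weights = weights,
                 sexLinked = sexLinked),
            class = "plantedPhenotype")
}

#' Default planted phenotypes of the demo configuration
#'
#' Four phenotypes spanning the discriminability range of real clinical
#' variables on this kind of panel: a strong (oracle AUC 0.95), a moderate
#' (0.90), a weak (0.75) and a null (0.50) signal, all at prevalence 0.2.
#' Their liability directions are class-aligned, the way real risk factors
#' express on such a panel — a lipid axis (lipoprotein lipids + fatty
#' acids), a glycaemic-inflammatory axis (glycolysis-related +
#' inflammation + amino acids) and an amino-acid/fluid-balance axis —
#' rather than dense random loadings, which no sparse learner could
#' recover at realistic sample sizes and which no biological phenotype
#' resembles.
#'
#' @param panel the [MetabolitePanel-class] whose classes define the axes.
#' @return List of [phenotypeSpec()] objects.
#' @export
defaultPhenotypes <- function(panel = defaultPanel()) {
  cls <- markerClasses(panel)
  axis <- function(...) as.numeric(cls %in% c(...))
  list(phenotypeSpec("strong_signal", prevalence = 0.2, auc = 0.95,
                     weights = axis("lipoprotein lipids", "fatty acids")),
       phenotypeSpec("moderate_signal", prevalence = 0.2, auc = 0.90,
                     weights = axis("glycolysis-related", "inflammation",
                                    "amino acids")),
       phenotypeSpec("weak_signal", prevalence = 0.2, auc = 0.75,
                     weights = axis("amino acids", "fluid balance")),
       phenotypeSpec("null_signal", prevalence = 0.2, auc = 0.50))
}

#' Generate a synthetic multi-biobank metabolomics dataset
#'
#' Emulates the statistical structure of a multi-cohort quantitative NMR
#' resource with known ground truth. Log-concentrations follow a latent
#' factor model with one factor per metabolite class (block correlation),
#' plus per-cohort additive batch offsets on the log scale and
#' idiosyncratic noise; concentrations are the exponential of that Gaussian,
#' hence log-normal and strictly positive. Binary phenotypes are planted
#' under the equal-variance binormal liability model (see
#' [phenotypeSpec()]): labels are Bernoulli(prevalence) and case samples
#' are shifted along the phenotype's marker weight vector so that the
#' standardized metabolite-linked liability separates the classes by
#' exactly \code{d}, giving a known oracle AUC of \eqn{\Phi(d/\sqrt 2)}.
#' The same seed always reproduces the identical dataset.
#'
#' @param nCohorts number of cohorts (biobanks).
#' @param cohortSizes integer vector of per-cohort sample counts (recycled
#'   if length 1). Default 500 per cohort (the 10 x 500 demo scale).
#' @param panel a [MetabolitePanel-class]; data are generated for all its
#'   markers, including the ones on the exclusion list, so that
#'   [selectPanel()] has real work to do.
#' @param phenotypes list of [phenotypeSpec()]s.
#' @param blockLoading latent-factor loading per metabolite class, either a
#'   single value or a named vector over [panelClassLevels()]; a loading
#'   \eqn{\ell} gives within-class log-scale correlation \eqn{\ell^2}.
#' @param nExtraFactors additional dense latent factors shared across all
#'   classes (loading 0.25 each), beyond the per-class factors.
#' @param cohortShiftSD SD of the per-cohort, per-marker additive batch
#'   offset on the standardized log scale (0 disables offsets).
#' @param cohortGainSD SD (log scale) of the per-cohort, per-marker
#'   multiplicative gain distortion. Additive offsets alone are
#'   rank-preserving within a cohort and so cannot degrade within-cohort
#'   discrimination; the gains rotate each cohort's effective
#'   discriminant direction, which is what makes transfer to an unseen
#'   biobank harder than within-distribution cross-validation (0
#'   disables gains).
#' @param clinical if TRUE, plausible raw clinical columns (lipids, blood
#'   pressure, creatinine, haemoglobin, white cells, hsCRP, BMI/waist,
#'   medication and lifestyle flags) are generated so the clinical
#'   binarization stage can run; their marginals are realistic but their
#'   cross-correlations with the metabolome are not modelled.
#' @param seed integer; fully determines the output.
#' @return \code{list(dataset, truth)}: a [CohortExperiment-class] and the
#'   matching [GenerativeTruth-class].
#' @examples
#' sim <- simulateCohorts(nCohorts = 3, cohortSizes = 60, seed = 7)
#' sim$dataset
#' oracleAUC(sim$truth)
#' @export
simulateCohorts <- function(nCohorts = 10, cohortSizes = 500,
                            panel = defaultPanel(),
                            phenotypes = defaultPhenotypes(),
                            blockLoading = 0.7, nExtraFactors = 1,
                            cohortShiftSD = 0.3, cohortGainSD = 0.2,
                            clinical = TRUE, seed = 1) {
  stopifnot(nCohorts >= 1)
  cohortSizes <- as.integer(rep_len(cohortSizes, nCohorts))
  if (any(cohortSizes <= 0)) stop("cohort sizes must be positive", call. = FALSE)
  mk <- markers(panel)
  cls <- markerClasses(panel)
  p <- length(mk)
  n <- sum(cohortSizes)
  classes <- panelClassLevels()
  if (is.null(names(blockLoading)))
    blockLoading <- setNames(rep_len(blockLoading, length(classes)), classes)

  withSeed(seed, {
    cohort <- rep(sprintf("cohort%02d", seq_len(nCohorts)), cohortSizes)
    sampleID <- sprintf("S%05d", seq_len(n))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    age <- round(runif(n, 18, 85), 1)

    # latent factor structure on the standardized log scale
    K <- length(classes) + nExtraFactors
    lambda <- matrix(0, p, K, dimnames = list(mk, NULL))
    for (i in seq_along(classes))
      lambda[cls == classes[i], i] <- blockLoading[[classes[i]]]
    if (nExtraFactors > 0)
      lambda[, length(classes) + seq_len(nExtraFactors)] <- 0.25
    commonVar <- rowSums(lambda^2)
    if (any(commonVar >= 1))
      stop("loadings imply non-positive idiosyncratic variance", call. = FALSE)
    noiseSD <- sqrt(1 - commonVar)
    FF <- matrix(rnorm(n * K), n, K)
    Z <- FF %*% t(lambda) +
      matrix(rnorm(n * p), n, p) %*% diag(noiseSD, p)
    colnames(Z) <- mk
    Sigma <- tcrossprod(lambda) + diag(noiseSD^2, p)

    # planted phenotypes: Bernoulli labels, binormal liability shift
    phTab <- data.frame(name = character(), prevalence = numeric(),
                        d = numeric(), oracleAUC = numeric(),
                        sexLinked = logical())
    weightsL <- list()
    liab <- matrix(NA_real_, n, length(phenotypes))
    labels <- matrix(NA, n, length(phenotypes))
    shift <- matrix(0, n, p)
    for (i in seq_along(phenotypes)) {
      ph <- phenotypes[[i]]
      w <- ph$weights
      if (is.null(w)) {
        w <- numeric(p)
        idx <- sample(p, max(2L, floor(p / 2)))
        w[idx] <- rnorm(length(idx))
      }
      w <- rep_len(w, p)
      v <- drop(t(w) %*% Sigma %*% w)
      if (v <= 0) stop("degenerate liability weights", call. = FALSE)
      y <- if (isTRUE(ph$sexLinked)) as.integer(sex == "M") else
        rbinom(n, 1L, ph$prevalence)
      # cases shift along Sigma %*% w, so the liability w'Z is the Bayes
      # discriminant of the two equal-covariance classes and its binormal
      # AUC phi(d/sqrt(2)) is a true ceiling no classifier can exceed
      shiftVec <- drop(Sigma %*% w) * (ph$d / sqrt(v))
      liab[, i] <- drop(Z %*% w + y * ph$d * sqrt(v)) / sqrt(v)
      shift <- shift + outer(as.numeric(y), shiftVec)
      labels[, i] <- as.logical(y)
      weightsL[[ph$name]] <- w
      phTab <- rbind(phTab, data.frame(
        name = ph$name, prevalence = ph$prevalence, d = ph$d,
        oracleAUC = ph$oracleAUC, sexLinked = isTRUE(ph$sexLinked)))
    }
    colnames(liab) <- phTab$name
    colnames(labels) <- phTab$name
    Z <- Z + shift

    # per-cohort batch structure, then map to positive concentrations.
    # Additive offsets displace cohorts but are rank-preserving within a
    # cohort; the per-marker multiplicative gains distort each cohort's
    # effective discriminant direction, which is what makes an unseen
    # biobank genuinely harder than a held-out fold.
    offsets <- matrix(rnorm(nCohorts * p, sd = cohortShiftSD), nCohorts, p,
                      dimnames = list(unique(cohort), mk))
    gains <- matrix(exp(rnorm(nCohorts * p, sd = cohortGainSD)),
                    nCohorts, p, dimnames = list(unique(cohort), mk))
    ci <- match(cohort, rownames(offsets))
    Zc <- Z * gains[ci, , drop = FALSE] + offsets[ci, , drop = FALSE]
    logMu <- runif(p, log(0.05), log(3))
    logScale <- runif(p, 0.2, 0.6)
    conc <- exp(sweep(sweep(Zc, 2, logScale, "*"), 2, logMu, "+"))

    cd <- DataFrame(sample_id = sampleID, cohort = cohort, sex = sex,
                    age = age)
    for (nm in phTab$name) cd[[nm]] <- labels[, nm]
    if (clinical) {
      male <- sex == "M"
      cd$totchol <- pmax(2, rnorm(n, 5.5, 1.0) + 0.012 * (age - 50))
      cd$hdl <- pmax(0.5, rlnorm(n, log(1.35), 0.22) + 0.15 * !male)
      cd$trig <- pmax(0.2, rlnorm(n, log(1.3), 0.45))
      cd$creatinine <- pmax(30, rnorm(n, 70, 12) + 8 * male)
      cd$bmi <- pmax(16, rnorm(n, 26, 4))
      cd$waist <- pmax(55, 80 + 2.2 * (cd$bmi - 26) + 10 * male + rnorm(n, 0, 6))
      cd$systolic <- pmax(85, rnorm(n, 130, 18) + 0.3 * (age - 50))
      cd$diastolic <- pmax(45, 75 + 0.35 * (cd$systolic - 130) + rnorm(n, 0, 8))
      cd$hgb <- pmax(4, rnorm(n, 8.8, 0.8) + 0.6 * male)
      cd$wbc <- rlnorm(n, log(6.3), 0.25)
      cd$hscrp <- rlnorm(n, log(1.1), 0.9)
      cd$diabetes <- rbinom(n, 1, 0.08) == 1
      cd$lipid_medication <- rbinom(n, 1, 0.15) == 1
      cd$blood_pressure_lowering_med <- rbinom(n, 1, 0.20) == 1
      cd$metabolic_syndrome <- rbinom(n, 1, 0.20) == 1
      cd$current_smoking <- rbinom(n, 1, 0.25) == 1
      cd$alcohol_consumption <- rbinom(n, 1, 0.60) == 1
    }

    realized <- do.call(rbind, lapply(unique(cohort), function(co) {
      sel <- cohort == co
      data.frame(cohort = co, phenotype = phTab$name,
                 prevalence = colMeans(labels[sel, , drop = FALSE]),
                 n = sum(sel), row.names = NULL)
    }))

    se <- SummarizedExperiment(
      assays = list(conc = t(conc)),
      rowData = DataFrame(marker = mk, class = unname(cls[mk]),
                          row.names = mk),
      colData = cd)
    colnames(se) <- sampleID
    dataset <- as(se, "CohortExperiment")
    rownames(liab) <- sampleID
    truth <- new("GenerativeTruth", loadings = lambda, noiseSD = noiseSD,
                 cohortOffsets = offsets, cohortGains = gains,
                 phenotypes = phTab,
                 liabilityWeights = weightsL, liabilities = liab,
                 realizedPrevalence = realized, seed = as.integer(seed))
    list(dataset = dataset, truth = truth)
  })
}

#' Inject missing cells, zeroes and gross outliers
#'
#' Randomly selected, non-overlapping cells of the concentration matrix are
#' set to missing or zero, or displaced to 8 sample SDs from the column
#' mean (computed without the displaced cell, so the injected value is
#' guaranteed to lie more than 5 SDs out however the column statistics are
#' taken). The exact set of altered cells, per artifact type, is recorded
#' in \code{metadata(dataset)$artifactMasks} so QC behaviour can be checked
#' against an exact oracle.
#'
#' @param dataset a [CohortExperiment-class].
#' @param missingRate,zeroRate,outlierRate fractions of cells in \[0, 1\].
#' @param seed integer RNG seed.
#' @return The modified dataset; masks in
#'   \code{metadata(dataset)$artifactMasks} (data.frames with
#'   \code{sample_id}, \code{marker} and matrix indices).
#' @export
injectArtifacts <- function(dataset, missingRate = 0, zeroRate = 0,
                            outlierRate = 0, seed = 1) {
  rates <- c(missing = missingRate, zero = zeroRate, outlier = outlierRate)
  if (any(rates < 0 | rates > 1))
    stop("artifact rates must lie in [0, 1]", call. = FALSE)
  X <- concentrations(dataset)  # samples x markers
  n <- nrow(X); p <- ncol(X)
  counts <- round(rates * n * p)
  maskDF <- function(cells) {
    i <- ((cells - 1L) %% n) + 1L
    j <- ((cells - 1L) %/% n) + 1L
    data.frame(sample_id = rownames(X)[i], marker = colnames(X)[j],
               row = i, col = j, stringsAsFactors = FALSE)
  }
  withSeed(seed, {
    total <- sum(counts)
    cells <- if (total > 0) sample.int(n * p, total) else integer()
    split <- rep(names(counts), counts)
    masks <- lapply(setNames(names(counts), names(counts)),
                    function(k) maskDF(cells[split == k]))
    if (counts[["missing"]] > 0)
      X[cbind(masks$missing$row, masks$missing$col)] <- NA_real_
    if (counts[["zero"]] > 0)
      X[cbind(masks$zero$row, masks$zero$col)] <- 0
    if (counts[["outlier"]] > 0) {
      for (r in seq_len(nrow(masks$outlier))) {
        i <- masks$outlier$row[r]; j <- masks$outlier$col[r]
        rest <- X[-i, j]
        X[i, j] <- mean(rest, na.rm = TRUE) +
          sample(c(-1, 1), 1) * 8 * sd(rest, na.rm = TRUE)
      }
    }
    assays(dataset)[["conc"]] <- t(X)
    metadata(dataset)$artifactMasks <- c(masks, list(seed = seed))
    dataset
  })
}

#' Plant family-clustered survival outcomes
#'
#' Appends exponential proportional-hazards event times driven by a linear
#' predictor over named sample-level columns, with a gamma-distributed
#' multiplicative frailty shared within family (families nest within
#' cohorts) and administrative censoring calibrated to a target censoring
#' fraction. This makes robust (cluster-sandwich) standard errors in the
#' downstream Cox stage testable against a known truth.
#'
#' @param dataset a [CohortExperiment-class].
#' @param logHR named numeric: log hazard ratios per unit of the named
#'   colData columns (binary phenotypes enter as 0/1).
#' @param censorRate target fraction censored in \[0, 1\]; 1 yields zero
#'   events (a degenerate input downstream stages must reject).
#' @param nFamilies total number of families, allocated to cohorts
#'   proportionally to cohort size; default one family per ~4 samples.
#' @param frailtyVar variance of the mean-1 gamma family frailty (0
#'   disables frailty).
#' @param baselineRate baseline hazard rate (events per unit follow-up
#'   time).
#' @param seed integer RNG seed.
#' @return The dataset with \code{time}, \code{event} and \code{family_id}
#'   columns; truth in \code{metadata(dataset)$survivalTruth}.
#' @export
plantSurvival <- function(dataset, logHR = numeric(), censorRate = 0.2,
                          nFamilies = NULL, frailtyVar = 0.5,
                          baselineRate = 0.05, seed = 1) {
  if (censorRate < 0) stop("censorRate must be non-negative", call. = FALSE)
  cd <- colData(dataset)
  bad <- setdiff(names(logHR), names(cd))
  if (length(bad))
    stop("logHR names absent from colData: ", paste(bad, collapse = ", "),
         call. = FALSE)
  n <- ncol(dataset)
  if (is.null(nFamilies)) nFamilies <- max(1L, n %/% 4L)
  withSeed(seed, {
    cohort <- as.character(cd$cohort)
    fam <- character(n)
    tab <- table(cohort)
    nf <- pmax(1L, round(nFamilies * as.numeric(tab) / n))
    for (k in seq_along(tab)) {
      co <- names(tab)[k]
      fam[cohort == co] <- sprintf("%s_fam%04d", co,
                                   sample.int(nf[k], tab[[k]], replace = TRUE))
    }
    frail <- if (frailtyVar > 0) {
      u <- rgamma(length(unique(fam)), shape = 1 / frailtyVar,
                  rate = 1 / frailtyVar)
      setNames(u, unique(fam))[fam]
    } else rep(1, n)
    lp <- numeric(n)
    for (nm in names(logHR)) lp <- lp + logHR[[nm]] * as.numeric(cd[[nm]])
    tt <- rexp(n, rate = baselineRate * frail * exp(lp))
    cutoff <- if (censorRate >= 1) min(tt) / 2
      else if (censorRate <= 0) max(tt) + 1
      else unname(quantile(tt, 1 - censorRate))
    cd$time <- pmin(tt, cutoff)
    cd$event <- as.integer(tt <= cutoff)
    cd$family_id <- fam
    colData(dataset) <- cd
    metadata(dataset)$survivalTruth <-
      list(logHR = logHR, frailtyVar = frailtyVar, censorRate = censorRate,
           baselineRate = baselineRate, cutoff = cutoff, seed = seed)
    dataset
  })
}
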