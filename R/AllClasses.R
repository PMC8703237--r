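#' Metabolite panel with class annotations
#'
#' The named marker set that defines the feature space of all surrogate
#' models. Every marker carries exactly one biochemical class label
#' (amino acids, glycolysis-related metabolites, ketone bodies, fluid
#' balance, inflammation, fatty acids, lipoprotein lipids), and the panel
#' records the markers excluded for poor detection so that
#' [selectPanel()] can apply the exclusion declaratively.
#'
#' @slot markers character vector of unique marker names (panel order).
#' @slot classes character vector, one class label per marker (named by marker).
#' @slot exclusions character vector of marker names to drop at selection time.
#' @seealso [defaultPanel()], [selectPanel()]
#' @export
setClass("MetabolitePanel",
  slots = c(markers = "character", classes = "character",
            exclusions = "character"))

#' @rdname MetabolitePanel-class
#' @export
panelClassLevels <- function() {
  c("amino acids", "glycolysis-related", "ketone bodies", "fluid balance",
    "inflammation", "fatty acids", "lipoprotein lipids")
}

setValidity("MetabolitePanel", function(object) {
  msg <- character()
  if (anyDuplicated(object@markers))
    msg <- c(msg, "marker names must be unique")
  if (length(object@classes) != length(object@markers))
    msg <- c(msg, "need exactly one class label per marker")
  if (!all(object@classes %in% panelClassLevels()))
    msg <- c(msg, sprintf("unknown class label(s): %s",
                          paste(setdiff(object@classes, panelClassLevels()),
                                collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Multi-cohort metabolomics dataset
#'
#' A [SummarizedExperiment::SummarizedExperiment] specialisation holding the
#' concentration matrix (markers in rows, samples in columns, assay
#' \code{"conc"}; after QC additionally assay \code{"scaled"}) together with
#' per-sample metadata in \code{colData}: at minimum \code{sample_id} and
#' \code{cohort}, and optionally sex, age, raw clinical variables, derived
#' binary phenotypes, \code{family_id} and survival follow-up
#' (\code{time}, \code{event}).
#'
#' @seealso [simulateCohorts()], [readDataset()], [writeDataset()]
#' @export
setClass("CohortExperiment", contains = "SummarizedExperiment")

setValidity("CohortExperiment", function(object) {
  msg <- character()
  if (!"conc" %in% names(assays(object)))
    msg <- c(msg, "assay 'conc' (concentration matrix) is required")
  cd <- colData(object)
  for (col in c("sample_id", "cohort"))
    if (!col %in% names(cd)) msg <- c(msg, sprintf("colData column '%s' is required", col))
  if ("sample_id" %in% names(cd) && anyDuplicated(cd$sample_id))
    msg <- c(msg, "sample_id must be unique")
  if (length(msg)) msg else TRUE
})

#' Planted ground truth of a synthetic multi-cohort dataset
#'
#' Everything needed to recompute any planted quantity of a
#' [simulateCohorts()] run: factor loadings and noise scales on the log
#' scale, per-cohort batch offsets, the phenotype table with liability
#' separations and their binormal oracle AUCs, the realized per-sample
#' liabilities, realized per-cohort prevalences, and the seed.
#'
#' @slot loadings matrix (markers x latent factors) of log-scale loadings.
#' @slot noiseSD numeric, per-marker idiosyncratic log-scale noise SD.
#' @slot cohortOffsets matrix (cohorts x markers) of additive log-scale batch
#'   offsets.
#' @slot cohortGains matrix (cohorts x markers) of multiplicative log-scale
#'   batch gains (sensitivity distortions; 1 = none).
#' @slot phenotypes data.frame with columns \code{name}, \code{prevalence},
#'   \code{d} (standardized liability separation), \code{oracleAUC}
#'   (\eqn{\Phi(d/\sqrt 2)}), \code{sexLinked}.
#' @slot liabilityWeights list of per-phenotype marker weight vectors.
#' @slot liabilities matrix (samples x phenotypes) of true standardized
#'   metabolite-linked liabilities.
#' @slot realizedPrevalence data.frame of per-cohort realized prevalences.
#' @slot seed integer seed that fully determines the dataset.
#' @export
setClass("GenerativeTruth",
  slots = c(loadings = "matrix", noiseSD = "numeric", cohortOffsets = "matrix",
            cohortGains = "matrix",
            phenotypes = "data.frame", liabilityWeights = "list",
            liabilities = "matrix", realizedPrevalence = "data.frame",
            seed = "integer"))

#' Quality-control report
#'
#' Counts and identities of the samples removed by each filter rule, the
#' number of residual cells imputed, and the per-marker scaling parameters
#' established by [zScale()] (reused when projecting new data).
#'
#' @slot nRemovedMissing,nRemovedZero,nRemovedOutlier integer removal counts,
#'   in filter order (missing, zero, >5 SD).
#' @slot removed list of character sample-id vectors per rule.
#' @slot nCellsImputed integer; \code{imputedFraction} is this count divided
#'   by retained samples times retained markers.
#' @slot imputedFraction numeric.
#' @slot center,scale named numeric per-marker scaling parameters (empty
#'   until scaling has run).
#' @export
setClass("QCReport",
  slots = c(nRemovedMissing = "integer", nRemovedZero = "integer",
            nRemovedOutlier = "integer", removed = "list",
            nCellsImputed = "integer", imputedFraction = "numeric",
            center = "numeric", scale = "numeric"))

#' Penalized-logistic metabolic surrogate model
#'
#' A deployable predictor for one dichotomous clinical variable: the
#' intercept and (sparse) coefficient vector of an elastic-net logistic
#' regression over the metabolite panel, the penalty mixing parameter and
#' selected penalty weight, the per-marker scaling parameters with which the
#' training matrix was standardized, and training metadata. The prediction
#' \eqn{\pi = 1/(1 + e^{-(\beta_0 + \beta^T m)})} is the surrogate value: an
#' uncalibrated posterior probability of the "at risk" label.
#'
#' @slot phenotype name of the modelled clinical variable.
#' @slot intercept \eqn{\beta_0}.
#' @slot beta named coefficient vector over the panel (zeros retained).
#' @slot alpha elastic-net mixing parameter in \[0, 1\].
#' @slot lambda selected penalty weight (> 0).
#' @slot center,scale named per-marker scaling parameters (empty if the
#'   model was trained on pre-scaled data without recorded parameters).
#' @slot metadata list: n, prevalence, seed, lambda path diagnostics, date.
#' @seealso [trainSurrogate()], [predictSurrogate()]
#' @export
setClass("SurrogateModel",
  slots = c(phenotype = "character", intercept = "numeric", beta = "numeric",
            alpha = "numeric", lambda = "numeric", center = "numeric",
            scale = "numeric", metadata = "list"))

setValidity("SurrogateModel", function(object) {
  msg <- character()
  if (length(object@alpha) != 1 || object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must be a single value in [0, 1]")
  if (length(object@lambda) != 1 || object@lambda <= 0)
    msg <- c(msg, "lambda must be a single positive value")
  if (is.null(names(object@beta)))
    msg <- c(msg, "beta must be named by marker")
  if (length(msg)) msg else TRUE
})

#' Surrogate evaluation report
#'
#' Held-out discrimination performance of a surrogate, either from repeated
#' outer 5-fold cross-validation (\code{mode = "cv"}) or from
#' leave-one-biobank-out validation (\code{mode = "lobov"}), where each
#' biobank's AUC is weighted by its held-out sample count.
#'
#' @slot phenotype evaluated clinical variable.
#' @slot mode "cv" or "lobov".
#' @slot folds data.frame of per-fold (or per-held-out-cohort) AUCs with
#'   weights.
#' @slot meanAUC unweighted mean AUC across folds.
#' @slot weightedAUC weight-averaged AUC (equals \code{meanAUC} for CV).
#' @slot aucThreshold accuracy criterion (default 0.7) used for \code{pass}.
#' @slot pass logical, \code{weightedAUC > aucThreshold}.
#' @slot metadata list of settings and seeds.
#' @export
setClass("EvaluationReport",
  slots = c(phenotype = "character", mode = "character", folds = "data.frame",
            meanAUC = "numeric", weightedAUC = "numeric",
            aucThreshold = "numeric", pass = "logical", metadata = "list"))

#' Metabolome-wide association result
#'
#' Per-marker association estimates of a metabolome-wide association study
#' (one linear model per RIN-transformed marker, phenotype as predictor),
#' with the effective number of tests used for Bonferroni correction.
#'
#' @slot table data.frame: marker, beta, se, t, p, significant.
#' @slot kEff effective number of tests (principal components explaining the
#'   configured variance fraction).
#' @slot threshold significance threshold 0.05 / kEff.
#' @slot phenotype,covariates names of the tested phenotype and adjustments.
#' @slot n number of complete samples analysed.
#' @export
setClass("MetaboWASResult",
  slots = c(table = "data.frame", kEff = "integer", threshold = "numeric",
            phenotype = "character", covariates = "character", n = "integer"))
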