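#' Default pipeline configuration
#'
#' Stage toggles and parameters of [runPipeline()] at the desk-scale demo
#' configuration: 10 cohorts of 500 samples, the four default planted
#' phenotypes, modest artifact rates, full double 5-fold cross-validation,
#' leave-one-biobank-out validation, a MetaboWAS of the strong phenotype
#' adjusted for age and sex, and a clustered mortality analysis driven by
#' two planted log hazard ratios. Override any element through the
#' \code{config} argument of [runPipeline()].
#'
#' @return Nested list of stage settings.
#' @export
defaultPipelineConfig <- function() {
  list(
    stages = c("simulate", "qc", "derive", "evaluate", "project",
               "metabowas", "survival"),
    simulate = list(nCohorts = 10, cohortSizes = 500,
                    cohortShiftSD = 0.3,
                    missingRate = 5e-4, zeroRate = 5e-4, outlierRate = 5e-4),
    qc = list(maxMissing = 0, zeroForbidden = TRUE, sdLimit = 5),
    evaluate = list(phenotypes = c("strong_signal", "moderate_signal",
                                   "weak_signal", "null_signal"),
                    alpha = 0.5, nFoldsOuter = 5, nRepeatsOuter = 5,
                    nFoldsInner = 5, nRepeatsInner = 5, lobov = TRUE),
    metabowas = list(phenotype = "strong_signal",
                     covariates = c("age", "sex"), varThreshold = 0.99),
    survival = list(logHR = c(strong_signal = log(2),
                              moderate_signal = log(1.5)),
                    censorRate = 0.2, frailtyVar = 0.5))
}

#' Run the end-to-end surrogate workflow
#'
#' Executes the toggled stages in order — simulate, QC, clinical
#' derivation, surrogate training/evaluation (CV and LOBOV), projection,
#' MetaboWAS, survival association — writing every artifact into
#' \code{outDir} together with a manifest (MD5 hash, stage and config
#' snapshot, stage seeds, package version) so that identical config and
#' seed reproduce identical artifact hashes. Every stochastic stage
#' derives its seed deterministically from the global seed and the stage
#' name.
#'
#' @param outDir output directory (created if needed).
#' @param seed global integer seed.
#' @param config partial override of [defaultPipelineConfig()] (merged
#'   recursively).
#' @return Invisibly, a list with the key in-memory results (dataset,
#'   truth, QC report, models, evaluation reports, MetaboWAS result,
#'   survival tables) and the manifest.
#' @export
runPipeline <- function(outDir, seed = 1, config = list()) {
  cfg <- modifyList(defaultPipelineConfig(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  logline <- function(stage, ...)
    message(sprintf("[%s] %s", stage, sprintf(...)))
  keep <- function(path) { artifacts[[length(artifacts) + 1L]] <<- path; path }

  # -- simulate -------------------------------------------------------------
  if (!"simulate" %in% cfg$stages)
    stop("this driver generates its inputs; enable the 'simulate' stage",
         call. = FALSE)
  sc <- cfg$simulate
  sim <- simulateCohorts(nCohorts = sc$nCohorts,
                         cohortSizes = sc$cohortSizes,
                         cohortShiftSD = sc$cohortShiftSD,
                         seed = stageSeed(seed, "simulate"))
  ds <- injectArtifacts(sim$dataset, missingRate = sc$missingRate,
                        zeroRate = sc$zeroRate,
                        outlierRate = sc$outlierRate,
                        seed = stageSeed(seed, "artifacts"))
  logline("simulate", "%d samples x %d markers in %d cohorts",
          ncol(ds), nrow(ds), sc$nCohorts)
  writeDataset(ds, keep(file.path(outDir, "dataset.tsv")))
  jsonlite::write_json(
    list(phenotypes = truthTable(sim$truth), seed = sim$truth@seed,
         realizedPrevalence = sim$truth@realizedPrevalence),
    keep(file.path(outDir, "truth.json")),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")

  # -- qc -------------------------------------------------------------------
  qc <- qcPreprocess(ds, maxMissing = cfg$qc$maxMissing,
                     zeroForbidden = cfg$qc$zeroForbidden,
                     sdLimit = cfg$qc$sdLimit)
  dsq <- qc$dataset
  logline("qc", "removed %d/%d/%d (missing/zero/outlier), kept %d samples",
          qc$report@nRemovedMissing, qc$report@nRemovedZero,
          qc$report@nRemovedOutlier, ncol(dsq))
  jsonlite::write_json(
    list(nRemovedMissing = qc$report@nRemovedMissing,
         nRemovedZero = qc$report@nRemovedZero,
         nRemovedOutlier = qc$report@nRemovedOutlier,
         nCellsImputed = qc$report@nCellsImputed,
         imputedFraction = qc$report@imputedFraction,
         removed = qc$report@removed),
    keep(file.path(outDir, "qc_report.json")), auto_unbox = TRUE,
    digits = NA)

  # -- derive ---------------------------------------------------------------
  derived <- NULL
  if ("derive" %in% cfg$stages) {
    derived <- deriveClinicalVariables(colData(dsq))
    write.table(cbind(sample_id = colData(dsq)$sample_id, derived),
                keep(file.path(outDir, "clinical_derived.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    logline("derive", "%d binary clinical variables derived", ncol(derived))
  }

  # -- train / evaluate -----------------------------------------------------
  X <- scaledMatrix(dsq)
  ev <- cfg$evaluate
  models <- list(); cvReports <- list(); lobovReports <- list()
  modelDir <- file.path(outDir, "models")
  dir.create(modelDir, showWarnings = FALSE)
  for (ph in ev$phenotypes) {
    y <- colData(dsq)[[ph]]
    fit <- trainSurrogate(X, y, alpha = ev$alpha, nFolds = ev$nFoldsInner,
                          nRepeats = ev$nRepeatsInner, phenotype = ph,
                          center = qc$report@center,
                          scale = qc$report@scale,
                          seed = stageSeed(seed, paste0("train.", ph)))
    models[[ph]] <- fit
    writeSurrogateModel(fit, keep(file.path(modelDir,
                                            paste0(ph, ".json"))))
    if ("evaluate" %in% cfg$stages) {
      cvReports[[ph]] <- evaluateCV(
        X, y, alpha = ev$alpha, nFoldsOuter = ev$nFoldsOuter,
        nRepeatsOuter = ev$nRepeatsOuter, nFoldsInner = ev$nFoldsInner,
        nRepeatsInner = ev$nRepeatsInner, phenotype = ph,
        seed = stageSeed(seed, paste0("cv.", ph)))
      if (isTRUE(ev$lobov))
        lobovReports[[ph]] <- evaluateLOBOV(
          X, y, cohorts(dsq), alpha = ev$alpha,
          nFoldsInner = ev$nFoldsInner, nRepeatsInner = ev$nRepeatsInner,
          phenotype = ph, seed = stageSeed(seed, paste0("lobov.", ph)))
      logline("evaluate", "%s: CV AUC %.3f%s", ph,
              cvReports[[ph]]@meanAUC,
              if (isTRUE(ev$lobov))
                sprintf(", LOBOV AUC %.3f",
                        lobovReports[[ph]]@weightedAUC) else "")
    }
  }
  if (length(cvReports)) {
    evTab <- do.call(rbind, lapply(names(cvReports), function(ph) {
      data.frame(phenotype = ph, cvMeanAUC = cvReports[[ph]]@meanAUC,
                 lobovWeightedAUC = if (ph %in% names(lobovReports))
                   lobovReports[[ph]]@weightedAUC else NA_real_,
                 pass = cvReports[[ph]]@pass)
    }))
    write.table(evTab, keep(file.path(outDir, "evaluation.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # -- project --------------------------------------------------------------
  surr <- vapply(models, function(m) predictSurrogate(m, X, scaled = TRUE),
                 numeric(nrow(X)))
  colnames(surr) <- paste0("surr_", names(models))
  if ("project" %in% cfg$stages) {
    out <- data.frame(sample_id = colData(dsq)$sample_id, surr)
    write.table(out, keep(file.path(outDir, "surrogates.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    logline("project", "projected %d surrogates onto %d samples",
            ncol(surr), nrow(surr))
  }

  # -- metabowas ------------------------------------------------------------
  mwas <- NULL
  if ("metabowas" %in% cfg$stages) {
    mw <- cfg$metabowas
    covs <- as.data.frame(colData(dsq)[, mw$covariates, drop = FALSE])
    mwas <- runMetaboWAS(concentrations(dsq),
                         colData(dsq)[[mw$phenotype]], covariates = covs,
                         varThreshold = mw$varThreshold)
    write.table(mwas@table, keep(file.path(outDir, "metabowas.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(kEff = mwas@kEff, threshold = mwas@threshold,
           nSignificant = sum(mwas@table$significant), n = mwas@n),
      keep(file.path(outDir, "metabowas_summary.json")),
      auto_unbox = TRUE, digits = NA)
    logline("metabowas", "k_eff = %d, %d significant markers", mwas@kEff,
            sum(mwas@table$significant))
  }

  # -- survival -------------------------------------------------------------
  surv <- NULL; stepw <- NULL
  if ("survival" %in% cfg$stages) {
    sv <- cfg$survival
    dsS <- plantSurvival(dsq, logHR = sv$logHR,
                         censorRate = sv$censorRate,
                         frailtyVar = sv$frailtyVar,
                         seed = stageSeed(seed, "survival"))
    sdat <- cbind(as.data.frame(colData(dsS)), surr)
    # intercept-only (fully shrunk) models yield a constant posterior and
    # carry no testable signal
    usable <- colnames(surr)[apply(surr, 2, sd) > 0]
    surv <- surrogateMortality(sdat, surrogates = usable)
    write.table(surv, keep(file.path(outDir, "survival_associations.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    stepw <- stepwiseCox(sdat, candidates = usable,
                         fixed = c("age", "sex"))
    jsonlite::write_json(
      list(trace = stepw$trace, selected = stepw$selected,
           summary = stepw$summary),
      keep(file.path(outDir, "stepwise_trace.json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    logline("survival", "%d/%d associations FDR-significant; %d terms selected",
            sum(surv$significant), nrow(surv), length(stepw$selected))
  }

  # -- manifest -------------------------------------------------------------
  manifest <- list(
    package = "metaboSurrogates",
    version = as.character(utils::packageVersion("metaboSurrogates")),
    seed = seed,
    stageSeeds = setNames(
      lapply(c("simulate", "artifacts", "survival"), stageSeed, seed = seed),
      c("simulate", "artifacts", "survival")),
    config = rapply(cfg, unclass, how = "replace"),
    files = lapply(artifacts, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dataset = dsq, truth = sim$truth, qcReport = qc$report,
                 derived = derived, models = models, cv = cvReports,
                 lobov = lobovReports, surrogates = surr, metabowas = mwas,
                 survival = surv, stepwise = stepw, manifest = manifest))
}
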