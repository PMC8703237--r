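#' @name accessors
#' @title Accessors for metaboSurrogates classes
#' @param x,object an object of the documented class.
#' @param ... passed to methods.
#' @description Accessor generics: \code{markers()} and \code{markerClasses()}
#'   return the marker names and their biochemical class labels;
#'   \code{exclusions()} the panel's exclusion list; \code{concentrations()}
#'   the samples-by-markers concentration matrix; \code{scaledMatrix()} the
#'   samples-by-markers z-scaled matrix (after QC); \code{cohorts()} the
#'   per-sample cohort labels; \code{truthTable()} the planted-phenotype
#'   table of a [GenerativeTruth-class]; \code{oracleAUC()} its named vector
#'   of planted oracle AUCs.
NULL

#' @rdname accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))
#' @rdname accessors
#' @export
setGeneric("markerClasses", function(x) standardGeneric("markerClasses"))
#' @rdname accessors
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))
#' @rdname accessors
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))
#' @rdname accessors
#' @export
setGeneric("scaledMatrix", function(x) standardGeneric("scaledMatrix"))
#' @rdname accessors
#' @export
setGeneric("cohorts", function(x) standardGeneric("cohorts"))
#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setGeneric("oracleAUC", function(x) standardGeneric("oracleAUC"))

#' @rdname accessors
setMethod("markers", "MetabolitePanel", function(x) x@markers)
#' @rdname accessors
setMethod("markerClasses", "MetabolitePanel",
          function(x) setNames(x@classes, x@markers))
#' @rdname accessors
setMethod("exclusions", "MetabolitePanel", function(x) x@exclusions)

#' @rdname accessors
setMethod("markers", "CohortExperiment", function(x) rownames(x))
#' @rdname accessors
setMethod("concentrations", "CohortExperiment",
          function(x) t(assay(x, "conc")))
#' @rdname accessors
setMethod("scaledMatrix", "CohortExperiment", function(x) {
  if (!"scaled" %in% names(assays(x)))
    stop("no 'scaled' assay; run qcPreprocess() first", call. = FALSE)
  t(assay(x, "scaled"))
})
#' @rdname accessors
setMethod("cohorts", "CohortExperiment",
          function(x) as.character(colData(x)$cohort))

#' @rdname accessors
setMethod("truthTable", "GenerativeTruth", function(x) x@phenotypes)
#' @rdname accessors
setMethod("oracleAUC", "GenerativeTruth",
          function(x) setNames(x@phenotypes$oracleAUC, x@phenotypes$name))

setMethod("show", "MetabolitePanel", function(object) {
  kept <- setdiff(object@markers, object@exclusions)
  cat(sprintf("MetabolitePanel: %d markers (%d retained, %d excluded)\n",
              length(object@markers), length(kept), length(object@exclusions)))
  tab <- table(object@classes[object@markers %in% kept])
  for (cl in names(tab)) cat(sprintf("  %-22s %d\n", cl, tab[[cl]]))
  if (length(object@exclusions))
    cat("  excluded:", paste(object@exclusions, collapse = ", "), "\n")
})

setMethod("show", "CohortExperiment", function(object) {
  cat(sprintf("CohortExperiment: %d markers x %d samples, %d cohort(s)\n",
              nrow(object), ncol(object),
              length(unique(colData(object)$cohort))))
  callNextMethod()
})

setMethod("show", "GenerativeTruth", function(object) {
  cat(sprintf("GenerativeTruth: %d markers, %d cohorts, %d planted phenotype(s), seed %d\n",
              nrow(object@loadings), nrow(object@cohortOffsets),
              nrow(object@phenotypes), object@seed))
  print(object@phenotypes, row.names = FALSE)
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport\n")
  cat(sprintf("  removed: %d missing-cell, %d zero-cell, %d >5 SD outlier\n",
              object@nRemovedMissing, object@nRemovedZero,
              object@nRemovedOutlier))
  cat(sprintf("  imputed cells: %d (%.4f%% of retained cells)\n",
              object@nCellsImputed, 100 * object@imputedFraction))
  if (length(object@center))
    cat(sprintf("  scaling parameters stored for %d markers\n",
                length(object@center)))
})

setMethod("show", "SurrogateModel", function(object) {
  nz <- sum(object@beta != 0)
  cat(sprintf("SurrogateModel '%s': %d/%d nonzero coefficients, alpha = %.2f, lambda = %.4g\n",
              object@phenotype, nz, length(object@beta), object@alpha,
              object@lambda))
  if (!is.null(object@metadata$n))
    cat(sprintf("  trained on n = %d (prevalence %.3f)\n",
                object@metadata$n, object@metadata$prevalence))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport '%s' [%s]: mean AUC = %.3f, weighted AUC = %.3f (%s at AUC > %.2f)\n",
              object@phenotype, object@mode, object@meanAUC,
              object@weightedAUC, if (object@pass) "PASS" else "FAIL",
              object@aucThreshold))
  cat(sprintf("  %d evaluation folds\n", nrow(object@folds)))
})

setMethod("show", "MetaboWASResult", function(object) {
  cat(sprintf("MetaboWASResult: %s ~ %s, n = %d\n", "marker",
              paste(c(object@phenotype, object@covariates), collapse = " + "),
              object@n))
  cat(sprintf("  k_eff = %d, threshold = %.3g, significant markers: %d/%d\n",
              object@kEff, object@threshold, sum(object@table$significant),
              nrow(object@table)))
})

#' Extract coefficients from a surrogate model
#'
#' @param object a [SurrogateModel-class].
#' @param ... ignored.
#' @return Named numeric vector: intercept followed by the panel
#'   coefficients.
#' @export
setMethod("coef", "SurrogateModel", function(object, ...) {
  c("(Intercept)" = object@intercept, object@beta)
})
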