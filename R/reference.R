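#' Reference surrogate-model training summary
#'
#' Per-phenotype summary of the original large-scale training of the 20
#' surrogate models on the multi-biobank NMR resource (~26,000 samples,
#' 28 cohorts): number of samples and cohorts contributing to each
#' model, number of positive labels, prevalence (percent), and the mean
#' 5-fold cross-validated and size-weighted leave-one-biobank-out AUCs.
#' The individual-level data behind these numbers are access-restricted;
#' the table ships so that derived quantities (prevalences, accuracy
#' rankings, the AUC > 0.7 pass criterion) can be recomputed and checked
#' without it.
#'
#' @return data.frame with columns \code{phenotype}, \code{n_samples},
#'   \code{n_cohorts}, \code{n_true}, \code{prevalence_pct},
#'   \code{auc_cv}, \code{auc_lobov}.
#' @export
referenceModelSummary <- function() {
  f <- system.file("extdata", "reference_model_summary.tsv",
                   package = "metaboSurrogates")
  read.delim(f, sep = "\t", stringsAsFactors = FALSE)
}
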